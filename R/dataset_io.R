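#' Write a synthetic dataset to disk
#'
#' Writes one multi-page grayscale TIFF per channel (16-bit; intensity counts
#' are stored exactly as integer sample values) and one 8-bit {0,255} TIFF
#' per ground-truth mask, plus `meta.json` (shape, voxel size, channel list)
#' and `truth.json` (nodes, segments with paths/radii/flags, nuclei truth,
#' seed, parameters). Voxel size is also recorded in the TIFF resolution tags
#' (pixels per centimetre in xy).
#'
#' @param ds a `synthetic_dataset`.
#' @param dir_path output directory (created if missing).
#' @return `dir_path`, invisibly.
#' @export
write_dataset <- function(ds, dir_path) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  sp <- ds$params$voxel_size_um
  res_ppcm <- c(1e4 / sp[3], 1e4 / sp[2]) # x, y pixels per cm

  write_stack <- function(grid, path, bits) {
    v <- vg_values(grid)
    pages <- lapply(seq_len(dim(v)[1]), function(z) {
      m <- v[z, , ]
      if (bits == 16L) m / 65535 else (m != 0) * 1.0
    })
    tiff::writeTIFF(pages, path, bits.per.sample = bits,
                    compression = "none", reduce = FALSE)
  }

  for (nm in names(ds$channels))
    write_stack(ds$channels[[nm]], file.path(dir_path, paste0(nm, ".tif")), 16L)
  for (nm in names(ds$masks))
    write_stack(ds$masks[[nm]], file.path(dir_path, paste0("mask_", nm, ".tif")), 8L)

  shp <- dim(vg_values(ds$channels[[1]]))
  meta <- list(shape = shp, voxel_size_um = sp,
               channels = names(ds$channels), masks = names(ds$masks),
               resolution_ppcm_xy = res_ppcm, bit_max = 4095)
  jsonlite::write_json(meta, file.path(dir_path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)

  truth <- list(
    seed = ds$seed,
    domain_um = ds$truth$domain_um,
    nodes = ds$truth$nodes,
    segments = lapply(ds$truth$segments, function(s) list(
      id = s$id, from = s$from, to = s$to,
      path_um = unname(as.matrix(s$path_um)), radius_um = s$radius_um,
      is_empty_sleeve = s$is_empty_sleeve, is_perfused = s$is_perfused)),
    nuclei_truth = ds$nuclei_truth,
    params = ds$params)
  jsonlite::write_json(truth, file.path(dir_path, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir_path)
}

#' Read a synthetic dataset written by [write_dataset()]
#'
#' Inverse of [write_dataset()]: `read_dataset(write_dataset(ds, d))` equals
#' `ds` on channel values, voxel sizes and truth. A missing channel file or a
#' shape mismatch across channels raises an error naming the channel.
#'
#' @param dir_path dataset directory.
#' @return a `synthetic_dataset`.
#' @export
read_dataset <- function(dir_path) {
  meta_path <- file.path(dir_path, "meta.json")
  if (!file.exists(meta_path)) stop("no meta.json in ", dir_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  shp <- as.integer(meta$shape)
  sp <- as.numeric(meta$voxel_size_um)

  read_stack <- function(path, nm, bits) {
    if (!file.exists(path)) stop("missing channel file for '", nm, "'")
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != shp[1] || any(dim(pages[[1]]) != shp[2:3]))
      stop("shape mismatch for channel '", nm, "'")
    v <- array(0, shp)
    for (z in seq_along(pages))
      v[z, , ] <- if (bits == 16L) round(pages[[z]] * 65535) else pages[[z]] != 0
    v
  }

  channels <- lapply(meta$channels, function(nm)
    voxel_grid(read_stack(file.path(dir_path, paste0(nm, ".tif")), nm, 16L),
               sp, nm))
  names(channels) <- meta$channels
  masks <- lapply(meta$masks, function(nm)
    voxel_grid(read_stack(file.path(dir_path, paste0("mask_", nm, ".tif")),
                          nm, 8L) != 0, sp, nm))
  names(masks) <- meta$masks

  tr <- jsonlite::read_json(file.path(dir_path, "truth.json"),
                            simplifyVector = TRUE)
  segdf <- tr$segments # data.frame with a list column for the paths
  as_path <- function(p) {
    if (is.matrix(p)) return(unname(p))
    matrix(unlist(p), ncol = 3, byrow = TRUE)
  }
  n_seg <- if (is.data.frame(segdf)) nrow(segdf) else length(segdf)
  segments <- lapply(seq_len(n_seg), function(i) {
    s <- if (is.data.frame(segdf)) lapply(segdf, `[[`, i) else segdf[[i]]
    list(id = as.integer(s$id),
         from = as.integer(s$from), to = as.integer(s$to),
         path_um = as_path(s$path_um),
         radius_um = as.numeric(s$radius_um),
         is_empty_sleeve = as.logical(s$is_empty_sleeve),
         is_perfused = as.logical(s$is_perfused))
  })
  truth <- structure(list(nodes = as.data.frame(tr$nodes),
                          segments = segments,
                          domain_um = as.numeric(tr$domain_um),
                          seed = as.integer(tr$seed)),
                     class = "vascular_graph_truth")
  nuc <- tr$nuclei_truth
  nuc <- if (is.null(nuc) || length(nuc) == 0) matrix(numeric(0), 0, 3)
         else matrix(as.numeric(unlist(nuc)), ncol = 3)

  structure(list(channels = channels, masks = masks, truth = truth,
                 nuclei_truth = nuc, seed = as.integer(tr$seed),
                 params = tr$params),
            class = "synthetic_dataset")
}
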