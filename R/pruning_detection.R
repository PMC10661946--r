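#' Parameters for empty-sleeve detection
#'
#' An empty sleeve is a basement-membrane (COL IV positive) tube lacking
#' endothelium (ICAM2 negative) -- the histological hallmark of a capillary
#' pruning event. Candidates are connected components of the basement
#' membrane outside a dilated endothelial mask; the geometric filters below
#' define which candidates qualify as capillary-scale sleeves.
#'
#' @param ec_dilation_um dilation radius applied to the endothelial mask
#'   before subtraction, absorbing registration slack and the
#'   membrane-to-lumen offset.
#' @param min_length_um minimum principal-axis extent of a sleeve.
#' @param max_diameter_um maximum thickness, measured as the maximal
#'   inscribed-sphere diameter of the component; rejects bulky non-tubular
#'   debris.
#' @param require_bridging keep only sleeves whose two principal-axis
#'   extremities lie close to the endothelial mask, i.e. remnants bridging
#'   two surviving vessels.
#' @param min_elongation minimum ratio of principal to secondary extent.
#' @param bridging_tol_um extra slack (um) on top of `ec_dilation_um` when
#'   testing extremity contact (voxels surviving the subtraction are
#'   necessarily farther than `ec_dilation_um` from the endothelium).
#' @return a `sleeve_params` list.
#' @export
sleeve_params <- function(ec_dilation_um = 2, min_length_um = 5,
                          max_diameter_um = 10, require_bridging = TRUE,
                          min_elongation = 1.5, bridging_tol_um = 3) {
  stopifnot(ec_dilation_um >= 0, min_length_um > 0, max_diameter_um > 0,
            min_elongation >= 1)
  structure(list(ec_dilation_um = ec_dilation_um,
                 min_length_um = min_length_um,
                 max_diameter_um = max_diameter_um,
                 require_bridging = isTRUE(require_bridging),
                 min_elongation = min_elongation,
                 bridging_tol_um = bridging_tol_um),
            class = "sleeve_params")
}

#' Detect empty basement-membrane sleeves (candidate pruning events)
#'
#' Computes the 26-connected components of
#' `bm_mask AND NOT dilate(ec_mask, ec_dilation_um)` and keeps those that
#' look like capillary-scale tubes: principal-axis extent at least
#' `min_length_um`, maximal inscribed-sphere diameter at most
#' `max_diameter_um`, elongation (principal / secondary extent) at least
#' `min_elongation`, and -- when `require_bridging` -- both extremities in
#' contact with the endothelial mask. Events are ordered deterministically
#' by centroid `(z, y, x)`.
#'
#' @param bm_mask basement-membrane (COL IV) binary `voxel_grid`.
#' @param ec_mask endothelium (ICAM2) binary `voxel_grid`, same geometry.
#' @param params a [sleeve_params()] object.
#' @return a `sleeve_events` object: a data.frame with one row per event
#'   (centroid um, length, diameters, elongation, bridging flag, voxel
#'   count) and the per-event voxel indices in `attr(, "voxels")`.
#' @export
detect_empty_sleeves <- function(bm_mask, ec_mask, params = sleeve_params()) {
  stopifnot(inherits(params, "sleeve_params"))
  bm <- vg_mask(bm_mask)
  ec <- vg_mask(ec_mask)
  check_same_geometry(bm_mask, ec_mask, "bm and ec masks")
  sp <- vg_spacing(bm_mask, vg_spacing(ec_mask))

  d_ec <- if (any(ec)) distance_transform_um(ec, sp) else
    array(Inf, dim(ec))
  cand <- bm & !(d_ec <= params$ec_dilation_um)
  empty <- sleeve_events_df(numeric(0))
  if (!any(cand)) return(empty)

  lab <- array(cpp_label26(as.logical(cand), dim(cand)), dim(cand))
  depth <- interior_depth_um(cand, sp)
  ncomp <- max(lab)

  rows <- list(); voxsets <- list()
  for (cc in seq_len(ncomp)) {
    vox <- which(lab == cc)
    co_um <- voxel_to_um(arrayInd(vox, dim(cand)), sp)
    centroid <- colMeans(co_um)
    if (nrow(co_um) >= 2) {
      pc <- prcomp(co_um, center = TRUE, scale. = FALSE)
      exts <- apply(pc$x, 2, function(col) diff(range(col)))
      # PCA orders axes by variance; extents can swap for compact shapes
      main_axis <- which.max(exts)
      proj1 <- pc$x[, main_axis]
      ext1 <- exts[main_axis]
      ext2 <- if (length(exts) >= 2) max(exts[-main_axis]) else 0
    } else {
      proj1 <- 0; ext1 <- 0; ext2 <- 0
    }
    len <- ext1
    elong <- ext1 / max(ext2, min(sp))
    mean_diam <- 2 * mean(depth[vox])
    max_insc <- 2 * max(depth[vox])
    if (len < params$min_length_um) next
    if (max_insc > params$max_diameter_um) next
    if (elong < params$min_elongation) next
    i_lo <- which.min(proj1); i_hi <- which.max(proj1)
    reach <- params$ec_dilation_um + params$bridging_tol_um
    touches <- d_ec[vox[i_lo]] <= reach && d_ec[vox[i_hi]] <= reach
    if (params$require_bridging && !touches) next
    rows[[length(rows) + 1L]] <- data.frame(
      centroid_z_um = centroid[1], centroid_y_um = centroid[2],
      centroid_x_um = centroid[3], length_um = len,
      mean_diameter_um = mean_diam, max_inscribed_diameter_um = max_insc,
      elongation = elong, touches_ec_both_ends = touches,
      n_voxels = length(vox))
    voxsets[[length(voxsets) + 1L]] <- vox
  }
  if (!length(rows)) return(empty)
  df <- do.call(rbind, rows)
  ord <- order(df$centroid_z_um, df$centroid_y_um, df$centroid_x_um)
  df <- df[ord, , drop = FALSE]
  df <- cbind(id = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  structure(df, voxels = voxsets[ord], class = c("sleeve_events", "data.frame"))
}

sleeve_events_df <- function(x) {
  structure(data.frame(id = integer(0), centroid_z_um = numeric(0),
                       centroid_y_um = numeric(0), centroid_x_um = numeric(0),
                       length_um = numeric(0), mean_diameter_um = numeric(0),
                       max_inscribed_diameter_um = numeric(0),
                       elongation = numeric(0),
                       touches_ec_both_ends = logical(0),
                       n_voxels = integer(0)),
            voxels = list(), class = c("sleeve_events", "data.frame"))
}

#' Pruning-event density per cubic millimetre
#'
#' @param events a `sleeve_events` object, or an event count.
#' @param voi_volume_um3 analysed tissue volume in cubic micrometres.
#' @return events per mm^3 (`1 mm^3 = 1e9 um^3`).
#' @export
pruning_density <- function(events, voi_volume_um3) {
  stopifnot(voi_volume_um3 > 0)
  n <- if (inherits(events, "data.frame")) nrow(events) else as.numeric(events)
  n / (voi_volume_um3 / 1e9)
}

#' Pruning events as a percentage of vascular segments
#'
#' In the postnatal heart roughly 100-150 sleeves coexist with 2,000-3,000
#' segments per volume of interest, i.e. about 4%.
#'
#' @param n_events number of detected sleeves.
#' @param n_segments number of vascular segments in the same volume.
#' @return `100 * n_events / n_segments`.
#' @export
pruning_segment_ratio <- function(n_events, n_segments) {
  if (n_segments <= 0) stop("undefined ratio: zero segments")
  100 * n_events / n_segments
}
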