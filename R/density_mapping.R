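#' Maximum intensity projection over a few z-planes
#'
#' Per-pixel maximum over `n_planes` consecutive z-sections starting at
#' `start_plane`. With 2 um sections, three planes span a 6 um slab -- the
#' projection used for endothelial density maps.
#'
#' @param volume an intensity `voxel_grid`.
#' @param n_planes number of planes to project.
#' @param span_um expected physical span; a mismatch with
#'   `n_planes * dz` raises a warning, not an error.
#' @param start_plane 1-based first plane.
#' @return a `plane_image`: 2D matrix `(y, x)` plus its pixel size in um.
#' @export
mip_over_planes <- function(volume, n_planes = 3, span_um = 6,
                            start_plane = 1) {
  v <- vg_values(volume)
  sp <- vg_spacing(volume)
  nz <- dim(v)[1]
  if (start_plane < 1 || start_plane + n_planes - 1 > nz)
    stop("requested planes fall outside the volume")
  if (abs(n_planes * sp[1] - span_um) > 1e-6)
    warning(sprintf("%d planes at dz = %.2f um span %.1f um, not %.1f um",
                    n_planes, sp[1], n_planes * sp[1], span_um))
  planes <- v[start_plane:(start_plane + n_planes - 1), , , drop = FALSE]
  img <- apply(planes, c(2, 3), max)
  structure(list(values = img, pixel_size_um = sp[2:3]),
            class = "plane_image")
}

#' Segment endothelial nuclei in a 2D projection
#'
#' The density-map macro: a mean intensity filter (disc of radius
#' `mean_filter_radius_um`), a global Otsu threshold, and a watershed split
#' of touching nuclei seeded from the internal distance transform.
#' Fragments below `min_area_um2` are merged into a touching neighbour
#' label when one exists, otherwise dropped.
#'
#' @param image a `plane_image` from [mip_over_planes()], or a matrix (then
#'   supply `pixel_size_um`).
#' @param mean_filter_radius_um mean-filter disc radius in um.
#' @param min_area_um2 minimum nucleus area kept.
#' @param pixel_size_um `(dy, dx)` for bare matrices.
#' @param watershed_tolerance intensity tolerance of the watershed split
#'   (in distance-map units, i.e. pixels).
#' @return data.frame of detections: `id`, `y_um`, `x_um`, `area_um2`.
#' @export
segment_nuclei <- function(image, mean_filter_radius_um = 2,
                           min_area_um2 = 8, pixel_size_um = NULL,
                           watershed_tolerance = 0.2) {
  if (inherits(image, "plane_image")) {
    img <- image$values
    px <- image$pixel_size_um
  } else {
    img <- image
    px <- if (is.null(pixel_size_um)) c(1, 1) else as.numeric(pixel_size_um)
  }
  empty <- data.frame(id = integer(0), y_um = numeric(0), x_um = numeric(0),
                      area_um2 = numeric(0))
  if (diff(range(img)) == 0) return(empty)

  r_px <- max(1L, round(mean_filter_radius_um / mean(px)))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  brush <- brush / sum(brush)
  sm <- EBImage::filter2(img / max(img), brush)
  sm <- pmin(pmax(sm, 0), 1)
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  bin <- sm > thr
  if (!any(bin)) return(empty)

  dm <- EBImage::distmap(EBImage::Image(bin * 1))
  lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = watershed_tolerance))

  px_area <- prod(px)
  n_lab <- max(lab)
  if (n_lab == 0) return(empty)
  areas <- tabulate(lab[lab > 0], nbins = n_lab) * px_area

  # merge sub-threshold fragments into a touching neighbour label
  small <- which(areas > 0 & areas < min_area_um2)
  if (length(small)) {
    for (s in small) {
      sel <- lab == s
      ring <- neighbour_labels_2d(lab, sel)
      ring <- ring[ring > 0 & ring != s]
      if (length(ring)) {
        tgt <- as.integer(names(sort(table(ring), decreasing = TRUE))[1])
        lab[sel] <- tgt
      } else lab[sel] <- 0L
    }
    areas <- tabulate(lab[lab > 0], nbins = max(lab)) * px_area
  }
  keep <- which(areas >= min_area_um2)
  if (!length(keep)) return(empty)

  out <- do.call(rbind, lapply(seq_along(keep), function(i) {
    sel <- which(lab == keep[i])
    rc <- arrayInd(sel, dim(lab))
    data.frame(id = i,
               y_um = (mean(rc[, 1]) - 0.5) * px[1],
               x_um = (mean(rc[, 2]) - 0.5) * px[2],
               area_um2 = length(sel) * px_area)
  }))
  rownames(out) <- NULL
  out
}

# labels of the 8-neighbourhood ring around a selected 2D region
neighbour_labels_2d <- function(lab, sel) {
  idx <- which(sel)
  d <- dim(lab)
  rc <- arrayInd(idx, d)
  out <- integer(0)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    rr <- rc[, 1] + dy; cc <- rc[, 2] + dx
    ok <- rr >= 1 & rr <= d[1] & cc >= 1 & cc <= d[2]
    out <- c(out, lab[cbind(rr[ok], cc[ok])])
  }
  out
}

#' Neighbour counts within a fixed radius
#'
#' For each nucleus centroid, the number of other centroids within
#' `radius_um` (euclidean, ties at exactly the radius count, self excluded).
#' The relation is symmetric by construction. 32 um is the radius used for
#' endothelial density maps.
#'
#' @param centroids n x 2 matrix of um positions (or a data.frame with
#'   `y_um`, `x_um` columns as returned by [segment_nuclei()]).
#' @param radius_um neighbourhood radius.
#' @return integer vector of counts, one per centroid.
#' @export
neighbor_counts <- function(centroids, radius_um = 32) {
  stopifnot(radius_um > 0)
  if (is.data.frame(centroids))
    centroids <- as.matrix(centroids[, c("y_um", "x_um")])
  n <- nrow(centroids)
  if (n <= 1) return(integer(n))
  dmat <- as.matrix(stats::dist(centroids))
  as.integer(rowSums(dmat <= radius_um) - 1L)
}

#' Histogram and colour coding of neighbour counts
#'
#' Tabulates the distribution of the number of neighbours and assigns each
#' nucleus a colour index: its count, clipped to the palette length (index
#' `k` means `k - 1` neighbours; the last index collects all larger counts).
#'
#' @param counts integer neighbour counts from [neighbor_counts()].
#' @param palette_length number of colours available.
#' @return a `density_map` list: `histogram` (named counts over observed
#'   neighbour numbers), `color_index` (1-based, per nucleus),
#'   `palette_length`.
#' @export
density_histogram <- function(counts, palette_length = 8) {
  stopifnot(all(counts >= 0))
  h <- table(factor(counts, levels = 0:max(c(counts, 0))))
  structure(list(histogram = h,
                 color_index = pmin(as.integer(counts) + 1L,
                                    as.integer(palette_length)),
                 palette_length = as.integer(palette_length)),
            class = "density_map")
}
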