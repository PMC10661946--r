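#' Percentage of the vasculature that is perfused
#'
#' Fraction of the ICAM2-positive vasculature occupied by intravenously
#' injected isolectin B4, as a percentage. By default the IB4 mask is
#' intersected with the ICAM2 mask, so the metric reads "percentage of the
#' vasculature occupied" and is bounded by 100; `raw_ratio = TRUE` divides
#' the raw IB4 volume by the ICAM2 volume instead (which can exceed 100 when
#' the tracer signal spills beyond the lumen mask).
#'
#' @param ib4_mask perfusion-tracer mask.
#' @param icam2_mask endothelial-lumen mask, same geometry, non-empty.
#' @param raw_ratio use the unbounded area ratio.
#' @return percentage.
#' @export
perfusion_percentage <- function(ib4_mask, icam2_mask, raw_ratio = FALSE) {
  ib4 <- vg_mask(ib4_mask)
  ic <- vg_mask(icam2_mask)
  check_same_geometry(ib4_mask, icam2_mask, "IB4 and ICAM2 masks")
  n_ic <- sum(ic)
  if (n_ic == 0) stop("empty ICAM2 mask: perfusion percentage undefined")
  if (raw_ratio) 100 * sum(ib4) / n_ic else 100 * sum(ib4 & ic) / n_ic
}

#' Percentage of extravascular dextran (vascular integrity)
#'
#' Percentage of the tissue occupied by dextran signal outside the
#' vasculature: `100 * |dextran AND NOT vessel AND tissue| / |tissue|`.
#' Near-zero values indicate an intact endothelial barrier.
#'
#' @param dextran_mask dextran tracer mask.
#' @param vessel_mask vascular (ICAM2) mask.
#' @param tissue_mask tissue mask; `NULL` = whole volume.
#' @return percentage.
#' @export
extravascular_dextran_percentage <- function(dextran_mask, vessel_mask,
                                             tissue_mask = NULL) {
  dx <- vg_mask(dextran_mask)
  vs <- vg_mask(vessel_mask)
  check_same_geometry(dextran_mask, vessel_mask, "dextran and vessel masks")
  ts <- if (is.null(tissue_mask)) array(TRUE, dim(dx)) else vg_mask(tissue_mask)
  check_same_geometry(dx, ts, "dextran and tissue masks")
  nt <- sum(ts)
  if (nt == 0) stop("empty tissue mask")
  100 * sum(dx & !vs & ts) / nt
}

#' Hypoxia-probe intensity statistics
#'
#' Mean fluorescence intensity (MFI) and frequency histogram of the
#' hypoxia-probe signal over tissue-contained voxels, on the 12-bit scale
#' 0-4095 (configurable).
#'
#' @param intensity hypoxia intensity `voxel_grid`.
#' @param tissue_mask tissue mask; `NULL` = whole volume.
#' @param n_bins number of equal-width histogram bins over `[0, bit_max]`.
#' @param bit_max top of the intensity scale.
#' @return a `hypoxia_stats` list: `mfi`, `histogram` (counts summing to the
#'   number of tissue voxels), `breaks`, `bit_max`.
#' @export
hypoxia_stats <- function(intensity, tissue_mask = NULL, n_bins = 16,
                          bit_max = 4095) {
  v <- vg_values(intensity)
  if (min(v) < 0 || max(v) > bit_max)
    stop("intensities outside [0, bit_max]")
  ts <- if (is.null(tissue_mask)) array(TRUE, dim(v)) else vg_mask(tissue_mask)
  check_same_geometry(v, ts, "intensity and tissue masks")
  vals <- v[ts]
  if (!length(vals)) stop("empty tissue mask")
  breaks <- seq(0, bit_max, length.out = n_bins + 1)
  h <- hist(vals, breaks = breaks, plot = FALSE, include.lowest = TRUE,
            right = TRUE)
  structure(list(mfi = mean(vals), histogram = h$counts, breaks = breaks,
                 bit_max = bit_max),
            class = "hypoxia_stats")
}

#' @export
print.hypoxia_stats <- function(x, ...) {
  cat(sprintf("<hypoxia_stats> MFI = %.1f on 0-%d (%d bins, %d voxels)\n",
              x$mfi, x$bit_max, length(x$histogram), sum(x$histogram)))
  invisible(x)
}

#' Capillary diffusion-distance statistics
#'
#' Euclidean distance (um, anisotropy-aware) from every extravascular
#' tissue voxel to the nearest vessel voxel -- a geometric proxy for the
#' oxygen diffusion path, meaningful only under physiological perfusion.
#'
#' @param vessel_mask vessel mask (non-empty within the tissue).
#' @param tissue_mask tissue mask; `NULL` = whole volume.
#' @return list with `mean_um`, `median_um`, `p95_um`, `max_um` and the full
#'   `distances_um` vector.
#' @export
diffusion_distance_stats <- function(vessel_mask, tissue_mask = NULL) {
  vs <- vg_mask(vessel_mask)
  ts <- if (is.null(tissue_mask)) array(TRUE, dim(vs)) else vg_mask(tissue_mask)
  check_same_geometry(vs, ts, "vessel and tissue masks")
  if (!any(vs & ts)) stop("no vessels inside the tissue mask")
  d <- distance_transform_um(vessel_mask)
  dist <- d[ts & !vs]
  list(mean_um = mean(dist), median_um = median(dist),
       p95_um = unname(quantile(dist, 0.95)), max_um = max(dist),
       distances_um = dist)
}

#' PAS-positive area percentage from an RGB section
#'
#' Binarizes a 2D RGB histochemistry image by a per-channel interval rule
#' (a pixel is positive when each channel lies inside its interval) and
#' reports the positive percentage of the tissue area.
#'
#' @param rgb_image `h x w x 3` array.
#' @param threshold_rule list with `r`, `g`, `b`, each a `(lo, hi)` interval
#'   on the image's own intensity scale.
#' @param tissue_mask_2d logical `h x w` mask; `NULL` = whole image.
#' @return percentage of tissue pixels inside the rule.
#' @export
pas_area_percentage <- function(rgb_image, threshold_rule,
                                tissue_mask_2d = NULL) {
  stopifnot(length(dim(rgb_image)) == 3L, dim(rgb_image)[3] == 3L)
  ts <- if (is.null(tissue_mask_2d)) matrix(TRUE, dim(rgb_image)[1], dim(rgb_image)[2])
        else tissue_mask_2d != 0
  if (!identical(dim(ts), dim(rgb_image)[1:2]))
    stop("tissue mask and image shapes differ")
  nt <- sum(ts)
  if (nt == 0) stop("empty tissue mask")
  rule <- lapply(threshold_rule[c("r", "g", "b")], as.numeric)
  pos <- rgb_image[, , 1] >= rule$r[1] & rgb_image[, , 1] <= rule$r[2] &
         rgb_image[, , 2] >= rule$g[1] & rgb_image[, , 2] <= rule$g[2] &
         rgb_image[, , 3] >= rule$b[1] & rgb_image[, , 3] <= rule$b[2]
  100 * sum(pos & ts) / nt
}
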