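#' Box-counting fractal dimension of a 3D mask
#'
#' Counts, for each box size `r` (in voxels, grid-aligned with origin at
#' index 0), the number `N(r)` of `r x r x r` boxes containing at least one
#' foreground voxel, and estimates the fractal dimension as the negative
#' slope of the unweighted least-squares line of `log N(r)` on `log r`.
#'
#' @param mask binary `voxel_grid` or array.
#' @param box_sizes integer box sizes; default powers of 2 from 1 up to a
#'   quarter of the smallest volume dimension. At least 3 sizes spanning two
#'   doublings are required.
#' @return a `fractal_result`: `box_sizes_vox` (decreasing), `box_counts`,
#'   `fd`, `fit_r2`. A fit with `fit_r2 < 0.95` triggers a warning.
#' @export
box_count_fd <- function(mask, box_sizes = NULL) {
  m <- vg_mask(mask)
  if (!any(m)) stop("empty mask: fractal dimension is undefined")
  if (is.null(box_sizes)) {
    rmax <- max(1L, min(dim(m)) %/% 4L)
    box_sizes <- 2^(0:floor(log2(rmax)))
  }
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (length(box_sizes) < 3L || max(box_sizes) < 4L * min(box_sizes))
    stop("need at least 3 box sizes spanning two doublings")
  co <- arrayInd(which(m), dim(m)) - 1L # 0-based voxel coordinates
  counts <- vapply(box_sizes, function(r) {
    b <- co %/% r
    nb <- apply(b, 2, max) + 1
    length(unique(b[, 1] + nb[1] * (b[, 2] + nb[2] * b[, 3])))
  }, numeric(1))
  fit <- lm(log(counts) ~ log(box_sizes))
  fd <- -unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared
  if (r2 < 0.95)
    warning(sprintf("box-count fit is poor (R^2 = %.3f); fd may be unreliable", r2))
  ord <- order(box_sizes, decreasing = TRUE)
  structure(list(box_sizes_vox = box_sizes[ord], box_counts = counts[ord],
                 fd = fd, fit_r2 = r2),
            class = "fractal_result")
}

#' @export
print.fractal_result <- function(x, ...) {
  cat(sprintf("<fractal_result> fd = %.3f (R^2 = %.3f) over box sizes %s\n",
              x$fd, x$fit_r2, paste(x$box_sizes_vox, collapse = ", ")))
  invisible(x)
}

#' Gliding-box lacunarity of a 3D mask
#'
#' For each box size `r`, an `r^3` box glides with stride 1 over all fully
#' contained positions; the box mass is its foreground count and
#' `Lambda(r) = <M^2> / <M>^2 = 1 + var(M) / mean(M)^2` (population
#' moments). `Lambda = 1` exactly for translationally homogeneous masks and
#' grows with the heterogeneity of gap sizes.
#'
#' @param mask binary `voxel_grid` or array.
#' @param box_sizes integer box sizes, each at most the smallest mask
#'   dimension; default powers of 2 from 2 to half the smallest dimension.
#' @return a `lacunarity_result`: `box_sizes_vox`, `lambda_values`,
#'   `mean_lambda`.
#' @export
gliding_box_lacunarity <- function(mask, box_sizes = NULL) {
  m <- vg_mask(mask)
  if (!any(m)) stop("empty mask: lacunarity is undefined (zero mean mass)")
  dm <- dim(m)
  if (is.null(box_sizes)) {
    rmax <- max(2L, min(dm) %/% 2L)
    box_sizes <- unique(pmin(2^(1:floor(log2(rmax))), min(dm)))
  }
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (any(box_sizes > min(dm)))
    stop("box size exceeds the smallest mask dimension")
  # 3D summed-volume table, padded with a zero hyperplane
  S <- array(0, dm + 1L)
  S[-1, -1, -1] <- m + 0
  S <- aperm(apply(S, c(2, 3), cumsum), c(1, 2, 3))
  S <- aperm(apply(S, c(1, 3), cumsum), c(2, 1, 3))
  S <- aperm(apply(S, c(1, 2), cumsum), c(2, 3, 1))
  lam <- vapply(box_sizes, function(r) {
    i <- seq_len(dm[1] - r + 1L); j <- seq_len(dm[2] - r + 1L)
    k <- seq_len(dm[3] - r + 1L)
    mass <- S[i + r, j + r, k + r, drop = FALSE] -
      S[i, j + r, k + r, drop = FALSE] -
      S[i + r, j, k + r, drop = FALSE] -
      S[i + r, j + r, k, drop = FALSE] +
      S[i, j, k + r, drop = FALSE] +
      S[i, j + r, k, drop = FALSE] +
      S[i + r, j, k, drop = FALSE] -
      S[i, j, k, drop = FALSE]
    mu <- mean(mass)
    if (mu == 0) stop("zero mean box mass at r = ", r)
    mean(mass^2) / mu^2
  }, numeric(1))
  structure(list(box_sizes_vox = box_sizes, lambda_values = lam,
                 mean_lambda = mean(lam)),
            class = "lacunarity_result")
}

#' @export
print.lacunarity_result <- function(x, ...) {
  cat(sprintf("<lacunarity_result> mean Lambda = %.4f over box sizes %s\n",
              x$mean_lambda, paste(x$box_sizes_vox, collapse = ", ")))
  invisible(x)
}

#' Extract volumes of interest from a larger stack
#'
#' Crops `n_vois` boxes of the requested micrometre size (rounded to whole
#' voxels). The default emulates the five 350 x 350 x 35 um myocardial
#' volumes of interest of the acquisition this package targets. Corners are
#' either drawn seeded-random without overlap, or supplied explicitly.
#'
#' @param volume a `voxel_grid`.
#' @param n_vois number of crops.
#' @param voi_size_um crop size `(z, y, x)` in um.
#' @param strategy `"random"` (non-overlapping, seeded) or `"corners"`.
#' @param corners for `strategy = "corners"`: a list/matrix of 1-based voxel
#'   corner indices `(z, y, x)`.
#' @param seed integer seed for the random strategy.
#' @return list of `voxel_grid` crops, each with a `corner` attribute.
#' @export
extract_vois <- function(volume, n_vois = 5, voi_size_um = c(35, 350, 350),
                         strategy = c("random", "corners"), corners = NULL,
                         seed = 1L) {
  strategy <- match.arg(strategy)
  v <- vg_values(volume)
  sp <- vg_spacing(volume)
  shp <- pmax(1L, as.integer(round(voi_size_um / sp)))
  d <- dim(v)
  if (any(shp > d)) stop("VOI larger than the volume")
  maxc <- d - shp + 1L
  pick <- function(corner) {
    sub <- v[corner[1]:(corner[1] + shp[1] - 1L),
             corner[2]:(corner[2] + shp[2] - 1L),
             corner[3]:(corner[3] + shp[3] - 1L), drop = FALSE]
    g <- voxel_grid(sub, sp, channel_label(volume))
    attr(g, "corner") <- corner
    g
  }
  if (strategy == "corners") {
    if (is.null(corners)) stop("supply `corners` for strategy = 'corners'")
    if (is.matrix(corners)) corners <- asplit(corners, 1)
    return(lapply(corners[seq_len(n_vois)], function(cc) pick(as.integer(cc))))
  }
  with_seed(seed, {
    placed <- matrix(NA_integer_, 0, 3)
    out <- vector("list", n_vois)
    for (i in seq_len(n_vois)) {
      ok <- FALSE
      for (try in seq_len(2000L)) {
        corner <- vapply(1:3, function(a) sample.int(maxc[a], 1L), integer(1))
        overlap <- FALSE
        if (nrow(placed)) {
          sepd <- abs(sweep(placed, 2L, corner))
          overlap <- any(apply(sweep(sepd, 2L, shp, `<`), 1, all))
        }
        if (!overlap) { ok <- TRUE; break }
      }
      if (!ok) stop("cannot place ", n_vois, " non-overlapping VOIs")
      placed <- rbind(placed, corner)
      out[[i]] <- pick(corner)
    }
    out
  })
}

#' Across-VOI heterogeneity of a scalar readout
#'
#' Standard deviation (n-1 denominator) and coefficient of variation of a
#' per-VOI readout such as fractal dimension or lacunarity, the spread
#' statistic used to compare network heterogeneity between hearts.
#'
#' @param values numeric vector, length >= 2.
#' @return a `heterogeneity_stats` list: `per_voi_values`, `sd`, `cv`.
#' @export
heterogeneity_sd <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values")
  s <- sd(values)
  m <- mean(values)
  if (m == 0 && s > 0) stop("cv undefined: zero mean with nonzero sd")
  structure(list(per_voi_values = values, sd = s,
                 cv = if (s == 0) 0 else s / abs(m)),
            class = "heterogeneity_stats")
}
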