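# Shared fixtures, built in code and memoised across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# Level-3 Menger sponge on an 81^3 grid: a voxel survives iff at no base-3
# digit level do two or more of its coordinates have digit 1.
menger_81 <- function() memo("menger81", {
  N <- 81L
  digs <- vapply(0:(N - 1L), function(i) {
    x <- i
    vapply(1:4, function(l) { r <- x %% 3L; x <<- x %/% 3L; r }, integer(1))
  }, integer(4))
  is1 <- digs == 1L # 4 x 81
  m <- array(FALSE, c(N, N, N))
  for (i in 0:(N - 1L)) for (j in 0:(N - 1L)) {
    if (any(is1[, i + 1L] & is1[, j + 1L])) next
    kk <- which(!vapply(0:(N - 1L), function(k)
      any((is1[, i + 1L] & is1[, k + 1L]) | (is1[, j + 1L] & is1[, k + 1L])),
      logical(1)))
    m[i + 1L, j + 1L, kk] <- TRUE
  }
  m
})

# Paint a capsule set directly (test-local access to the rasterizer core).
paint_tubes <- function(dim3, spacing, paths, radii) {
  array(cardiocap3d:::cpp_paint_capsules(as.integer(dim3), spacing,
                                         paths, radii), dim3)
}

# Noise-free exact-recovery condition: sparse straight tree, isotropic 1 um.
graph_recovery_case <- function(seed) memo(paste0("gr", seed), {
  ds <- simulate_voi(seed, preset = "graph_recovery")
  mask <- ds$masks$endothelium
  g <- merge_close_junctions(
    prune_spurs(build_graph(skeletonize_mask(mask), mask), 4), 5)
  list(truth = ds$truth, graph = g,
       true_mean_diam = 2 * mean(vapply(ds$truth$segments, `[[`, numeric(1),
                                        "radius_um")))
})

# Sleeve-detection condition: 20 planted sleeves, 10% noise.
pruning_case <- function(seed, sleeve_fraction = NA) {
  key <- paste0("pr", seed, "_", sleeve_fraction)
  memo(key, suppressWarnings(
    simulate_voi(seed, preset = "pruning", sleeve_fraction = sleeve_fraction)))
}

# Greedy one-to-one matching of detections to true sleeve centroids.
sleeve_match <- function(events, truth, tol_um = 5) {
  sl <- which(vapply(truth$segments, `[[`, logical(1), "is_empty_sleeve"))
  tc <- t(vapply(truth$segments[sl], function(s) colMeans(s$path_um),
                 numeric(3)))
  det <- as.matrix(events[, c("centroid_z_um", "centroid_y_um",
                              "centroid_x_um")])
  matched <- rep(FALSE, length(sl))
  used <- rep(FALSE, nrow(det))
  for (i in seq_along(sl)) {
    if (!nrow(det)) break
    d <- sqrt(rowSums((det - matrix(tc[i, ], nrow(det), 3, byrow = TRUE))^2))
    j <- which.min(ifelse(used, Inf, d))
    if (length(j) && is.finite(d[j]) && d[j] <= tol_um) {
      matched[i] <- TRUE
      used[j] <- TRUE
    }
  }
  list(recall = mean(matched),
       precision = if (nrow(det)) sum(used) / nrow(det) else NA_real_,
       n_true = length(sl), n_det = nrow(det))
}

# Run segmentation + sleeve detection on a dataset's noisy channels.
detect_on_channels <- function(ds, seg = segmentation_params(scales_um = 1,
                                                            n_levels = 3)) {
  ec <- multiscale_multilevel_segment(ds$channels$endothelium, seg)
  bm <- multiscale_multilevel_segment(ds$channels$basement_membrane, seg)
  detect_empty_sleeves(bm, ec)
}
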