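test_that("two-valued image threshold matches the exhaustive Otsu oracle", {
  set.seed(21)
  v <- sample(c(12, 180), 400, replace = TRUE, prob = c(0.7, 0.3))
  thr <- otsu_thresholds(v, 2)
  # independent oracle: scan all candidate cuts, maximise between-class
  # variance directly
  cand <- sort(unique(v))
  crit <- vapply(cand[-length(cand)], function(t) {
    w1 <- mean(v <= t); w2 <- 1 - w1
    if (w1 == 0 || w2 == 0) return(-Inf)
    w1 * w2 * (mean(v[v <= t]) - mean(v[v > t]))^2
  }, numeric(1))
  best <- cand[which.max(crit)]
  expect_true(thr > best && thr <= min(v[v > best]))
  expect_identical(as.logical(v > thr), v == 180)
})

test_that("multi-class thresholds match a brute-force 3-class search", {
  set.seed(22)
  v <- c(rnorm(300, 50, 5), rnorm(200, 120, 6), rnorm(150, 220, 8))
  v <- pmin(pmax(round(v), 0), 255)
  thr <- otsu_thresholds(v, 3)
  u <- sort(unique(v))
  best <- -Inf; best_pair <- NULL
  for (i in seq_len(length(u) - 2)) for (j in (i + 1):(length(u) - 1)) {
    g <- cut(v, c(-Inf, u[i], u[j], Inf))
    s <- sum(tapply(v, g, length) * tapply(v, g, mean)^2, na.rm = TRUE)
    if (s > best) { best <- s; best_pair <- c(u[i], u[j]) }
  }
  expect_identical(findInterval(v, thr), findInterval(v, best_pair + 0.5))
})

test_that("degenerate inputs follow the error/warning contracts", {
  g <- voxel_grid(array(0, c(4, 8, 8)), c(1, 1, 1))
  expect_warning(m <- multiscale_multilevel_segment(g), "constant")
  expect_false(any(m$values))
  expect_error(otsu_thresholds(rep(c(1, 2), 10), 3), "distinct")
})

test_that("a noise-free cylinder is recovered almost perfectly", {
  tube <- paint_tubes(c(20, 40, 40), c(1, 1, 1),
                      list(rbind(c(10.2, 20.4, 4), c(10.2, 20.4, 36))), 3.1)
  img <- voxel_grid(array(tube * 2000 + 100, dim(tube)), c(1, 1, 1))
  m <- multiscale_multilevel_segment(img, segmentation_params(
    scales_um = 1, n_levels = 2, min_component_um3 = 10))
  jac <- sum(m$values & tube) / sum(m$values | tube)
  expect_gte(jac, 0.95)
})

test_that("raising voxel values never shrinks the mask at fixed thresholds", {
  set.seed(23)
  v <- array(runif(10 * 12 * 14, 0, 100), c(10, 12, 14))
  thr <- otsu_thresholds(v, 3)
  m1 <- cardiocap3d:::threshold_mask(v, thr, 1)
  v2 <- v; v2[3:6, 4:8, 2:9] <- v2[3:6, 4:8, 2:9] + 50
  m2 <- cardiocap3d:::threshold_mask(v2, thr, 1)
  expect_true(all(m2[m1]))
})

test_that("the multi-scale union contains every single-scale mask", {
  ds <- pruning_case(1)
  img <- ds$channels$endothelium
  u <- multiscale_multilevel_segment(img, segmentation_params(
    scales_um = c(1, 2, 4), n_levels = 3, min_component_um3 = 0))
  s1 <- multiscale_multilevel_segment(img, segmentation_params(
    scales_um = 2, n_levels = 3, min_component_um3 = 0))
  expect_true(all(u$values[s1$values]))
})

test_that("default segmentation meets the recall/false-positive bar over seeds", {
  for (seed in 1:5) {
    ds <- pruning_case(seed)
    truth <- ds$masks$endothelium$values
    m <- multiscale_multilevel_segment(ds$channels$endothelium)$values
    expect_gte(sum(m & truth) / sum(truth), 0.90)
    expect_lte(sum(m & !truth) / sum(!truth), 0.05)
  }
})

test_that("vascular volume density is the masked voxel fraction", {
  t <- array(TRUE, c(4, 4, 4))
  m <- array(FALSE, c(4, 4, 4)); m[, , 1:2] <- TRUE
  expect_equal(vascular_volume_density(m, t), 0.5)
  expect_equal(vascular_volume_density(t, t), 1)
  expect_equal(vascular_volume_density(array(FALSE, c(4, 4, 4)), t), 0)
  expect_error(vascular_volume_density(m, array(FALSE, c(4, 4, 4))),
               "empty tissue")
})
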