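test_that("box counting hits the space-filling and 1D limits", {
  cube <- array(TRUE, c(64, 64, 64))
  f <- suppressWarnings(box_count_fd(cube, c(1, 2, 4, 8, 16)))
  expect_gte(f$fd, 2.95); expect_lte(f$fd, 3.05)
  line <- array(FALSE, c(64, 5, 5)); line[, 3, 3] <- TRUE
  fl <- suppressWarnings(box_count_fd(line, c(1, 2, 4, 8, 16)))
  expect_gte(fl$fd, 0.9); expect_lte(fl$fd, 1.1)
  # counts must not decrease as boxes shrink (sizes stored decreasing)
  expect_true(all(diff(f$box_counts) >= 0))
  expect_error(box_count_fd(array(FALSE, c(8, 8, 8))), "empty")
  expect_error(box_count_fd(cube, c(4, 8)), "3 box sizes")
})

test_that("fd is invariant to translation by box multiples and to axis swap", {
  m <- menger_81()
  f0 <- suppressWarnings(box_count_fd(m, c(1, 3, 9, 27)))
  fp <- suppressWarnings(box_count_fd(aperm(m, c(3, 1, 2)), c(1, 3, 9, 27)))
  expect_equal(f0$fd, fp$fd, tolerance = 1e-12)
  pad <- array(FALSE, c(108, 108, 108))
  pad[28:108, 28:108, 28:108] <- m # shift by 27 = one box at every size
  ft <- suppressWarnings(box_count_fd(pad, c(1, 3, 9, 27)))
  expect_equal(ft$box_counts, f0$box_counts)
})

test_that("gliding-box lacunarity matches exhaustive enumeration", {
  oct <- array(FALSE, c(8, 8, 8)); oct[1:4, 1:4, 1:4] <- TRUE
  l <- gliding_box_lacunarity(oct, 4)
  mass <- c()
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    mass <- c(mass, sum(oct[i:(i + 3), j:(j + 3), k:(k + 3)]))
  expect_equal(l$lambda_values, mean(mass^2) / mean(mass)^2, tolerance = 1e-12)
  expect_equal(length(mass), 125L)
})

test_that("lacunarity is 1 for filled masks and >= 1 always", {
  filled <- array(TRUE, c(12, 12, 12))
  lf <- gliding_box_lacunarity(filled, c(2, 3, 4, 6))
  expect_true(all(abs(lf$lambda_values - 1) <= 1e-12))
  for (seed in 1:5) {
    set.seed(seed)
    m <- array(runif(12^3) < 0.4, c(12, 12, 12))
    lr <- gliding_box_lacunarity(m, c(2, 4, 6))
    expect_true(all(lr$lambda_values >= 1))
    # homogeneous random masks: Lambda decays toward 1 with box size
    expect_lt(lr$lambda_values[3], lr$lambda_values[1])
  }
  expect_error(gliding_box_lacunarity(array(FALSE, c(6, 6, 6)), 2), "empty")
  expect_error(gliding_box_lacunarity(filled, 16), "exceeds")
})

test_that("VOI extraction crops the requested micrometre geometry", {
  v <- voxel_grid(array(runif(18 * 100 * 100), c(18, 100, 100)),
                  c(2, 0.6, 0.6))
  # whole-volume VOI is the identity crop
  whole <- extract_vois(v, 1, voi_size_um = c(36, 60, 60), seed = 1)
  expect_identical(whole[[1]]$values, v$values)
  # the standard myocardial VOI at default spacing: (18, 583, 583) voxels
  big <- voxel_grid(array(FALSE, c(20, 1200, 1200)), c(2, 0.6, 0.6))
  crops <- extract_vois(big, 1, voi_size_um = c(35, 350, 350), seed = 2)
  expect_equal(dim(crops[[1]]$values), c(18L, 583L, 583L))
  # seeded corners reproduce; non-overlap holds
  c1 <- vapply(extract_vois(big, 5, c(35, 120, 120), seed = 9), attr,
               integer(3), "corner")
  c2 <- vapply(extract_vois(big, 5, c(35, 120, 120), seed = 9), attr,
               integer(3), "corner")
  expect_identical(c1, c2)
  shp <- c(18L, 200L, 200L)
  for (i in 1:4) for (j in (i + 1):5)
    expect_true(any(abs(c1[, i] - c1[, j]) >= shp))
  expect_error(extract_vois(v, 1, voi_size_um = c(100, 500, 500)), "larger")
})

test_that("heterogeneity stats follow the two-pass formulas", {
  h <- heterogeneity_sd(c(1, 3))
  expect_equal(h$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(heterogeneity_sd(rep(2.5, 4))$sd, 0)
  set.seed(31)
  x <- rnorm(5, 10, 2)
  h5 <- heterogeneity_sd(x)
  expect_equal(h5$sd, sqrt(sum((x - mean(x))^2) / 4), tolerance = 1e-12)
  expect_equal(h5$cv, h5$sd / abs(mean(x)), tolerance = 1e-12)
  expect_error(heterogeneity_sd(1), "at least 2")
  expect_error(heterogeneity_sd(c(-1, 1)), "zero mean")
})

test_that("mixing two vessel densities raises across-VOI heterogeneity", {
  # per-VOI vascular volume density from homogeneous vs mixed generators
  vvd_of <- function(target, seed) {
    ds <- suppressWarnings(simulate_voi(seed, "pruning", sleeve_fraction = 0,
      gen_args = list(domain_um = c(35, 90, 90), n_segments_target = target,
                      min_clearance_um = NULL),
      raster_args = list(voxel_size_um = c(2, 1, 1), noise_sd = 0,
                         psf_sigma_um = 0)))
    vascular_volume_density(ds$masks$endothelium)
  }
  wins <- 0
  for (seed in 1:10) {
    homo <- vapply(1:4, function(v) vvd_of(25, seed * 20 + v), numeric(1))
    mixed <- vapply(1:4, function(v)
      vvd_of(if (v %% 2) 10 else 40, seed * 20 + v), numeric(1))
    wins <- wins + (heterogeneity_sd(mixed)$sd > heterogeneity_sd(homo)$sd)
  }
  expect_gte(wins, 8)
})
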