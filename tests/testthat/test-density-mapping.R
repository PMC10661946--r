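test_that("MIP takes per-pixel maxima over the selected planes", {
  v <- array(0, c(6, 8, 8))
  v[2, 3, 4] <- 500; v[4, 3, 4] <- 900; v[6, 3, 4] <- 2000
  g <- voxel_grid(v, c(2, 1, 1))
  m <- mip_over_planes(g, n_planes = 3, span_um = 6, start_plane = 2)
  expect_equal(m$values[3, 4], 900) # plane 6 not in the window
  expect_equal(mip_over_planes(g, 1, span_um = 2, start_plane = 4)$values,
               v[4, , ])
  cst <- voxel_grid(array(7, c(4, 5, 5)), c(2, 1, 1))
  expect_true(all(mip_over_planes(cst, 2, 4)$values == 7))
  expect_error(mip_over_planes(g, 4, 8, start_plane = 5), "outside")
  expect_warning(mip_over_planes(g, 2, span_um = 6), "span")
})

test_that("nucleus segmentation detects disjoint and touching nuclei", {
  img <- matrix(0, 80, 80)
  for (cc in list(c(20, 20), c(20, 60))) # disjoint discs
    for (i in 1:80) for (j in 1:80)
      if ((i - cc[1])^2 + (j - cc[2])^2 <= 36) img[i, j] <- 3000
  d1 <- segment_nuclei(structure(list(values = img, pixel_size_um = c(1, 1)),
                                 class = "plane_image"))
  expect_equal(nrow(d1), 2L)
  expect_lt(min(abs(d1$x_um - 20), abs(d1$x_um - 60)), 2)

  # overlapping discs, centres 1.5 radii apart: watershed must split them
  img2 <- matrix(0, 80, 80)
  for (cy in c(30, 39))
    for (i in 1:80) for (j in 1:80)
      if ((i - cy)^2 + (j - 40)^2 <= 36) img2[i, j] <- 3000
  d2 <- segment_nuclei(structure(list(values = img2, pixel_size_um = c(1, 1)),
                                 class = "plane_image"))
  expect_equal(nrow(d2), 2L)

  blank <- segment_nuclei(structure(list(values = matrix(0, 40, 40),
                                         pixel_size_um = c(1, 1)),
                                    class = "plane_image"))
  expect_equal(nrow(blank), 0L)
})

test_that("neighbour counts match the O(n^2) oracle and are symmetric", {
  set.seed(41)
  pts <- cbind(runif(500, 0, 300), runif(500, 0, 300))
  nc <- neighbor_counts(pts, 32)
  adj <- matrix(FALSE, 500, 500)
  for (i in 1:499) for (j in (i + 1):500) {
    d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    adj[i, j] <- adj[j, i] <- d <= 32
  }
  expect_identical(nc, as.integer(rowSums(adj)))
  expect_identical(adj, t(adj))
  # three collinear points at 20 um spacing, radius 32
  expect_identical(neighbor_counts(cbind(c(0, 20, 40), 0), 32), c(1L, 2L, 1L))
  expect_identical(neighbor_counts(cbind(5, 5), 32), 0L)
})

test_that("random points match the Poisson neighbour expectation", {
  lambda <- 0.004 # points per um^2
  r <- 32
  means <- vapply(1:5, function(seed) {
    set.seed(seed)
    n <- rpois(1, lambda * 500^2)
    pts <- cbind(runif(n, 0, 500), runif(n, 0, 500))
    inner <- pts[, 1] > r & pts[, 1] < 500 - r & pts[, 2] > r & pts[, 2] < 500 - r
    mean(neighbor_counts(pts, r)[inner])
  }, numeric(1))
  expected <- lambda * pi * r^2
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - expected), 3 * se + 0.2)
})

test_that("histogram conserves counts and colour indices clip", {
  counts <- c(0L, 1L, 1L, 2L)
  dm <- density_histogram(counts, palette_length = 3)
  expect_equal(as.integer(dm$histogram), c(1L, 2L, 1L))
  expect_equal(sum(dm$histogram), length(counts))
  expect_equal(dm$color_index, c(1L, 2L, 2L, 3L))
  big <- density_histogram(c(0L, 9L), palette_length = 4)
  expect_equal(max(big$color_index), 4L)
  same <- density_histogram(rep(3L, 6))
  expect_equal(sum(same$histogram > 0), 1L)
})

test_that("dense regions show higher neighbour counts than sparse ones", {
  wins <- 0
  for (seed in 1:10) {
    set.seed(seed)
    dense <- cbind(runif(60, 0, 180), runif(60, 0, 180))
    sparse <- cbind(runif(15, 0, 180), runif(15, 220, 400))
    pts <- rbind(dense, sparse)
    nc <- neighbor_counts(pts, 32)
    wins <- wins + (mean(nc[1:60]) > mean(nc[61:75]))
  }
  expect_equal(wins, 10)
})
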