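mk <- function(a) voxel_grid(a, c(1, 1, 1))

test_that("perfusion percentage handles the boundary cases exactly", {
  ic <- array(FALSE, c(4, 6, 6)); ic[2:3, 2:5, 2:5] <- TRUE
  full <- array(TRUE, c(4, 6, 6))
  none <- array(FALSE, c(4, 6, 6))
  half <- ic; half[2, , ] <- FALSE # exactly half the icam2 voxels
  expect_equal(perfusion_percentage(mk(full), mk(ic)), 100)
  expect_equal(perfusion_percentage(mk(none), mk(ic)), 0)
  expect_equal(perfusion_percentage(mk(half), mk(ic)), 50)
  expect_error(perfusion_percentage(mk(full), mk(none)), "empty ICAM2")
  # raw ratio may exceed 100; bounded form cannot
  expect_gt(perfusion_percentage(mk(full), mk(ic), raw_ratio = TRUE), 100)
})

test_that("perfusion is monotone in IB4 and ignores voxels outside ICAM2", {
  set.seed(51)
  ic <- array(runif(6^3) < 0.3, c(6, 6, 6))
  ib1 <- ic & array(runif(6^3) < 0.5, c(6, 6, 6))
  ib2 <- ib1 | (ic & array(runif(6^3) < 0.5, c(6, 6, 6)))
  expect_lte(perfusion_percentage(mk(ib1), mk(ic)),
             perfusion_percentage(mk(ib2), mk(ic)))
  outside <- ib1 | !ic
  expect_equal(perfusion_percentage(mk(outside), mk(ic)),
               perfusion_percentage(mk(ib1), mk(ic)))
})

test_that("extravascular dextran percentage is exact on planted leaks", {
  ds <- suppressWarnings(simulate_voi(5, "graph_recovery",
    raster_args = list(n_leak_blobs = 3, leak_radius_um = 4)))
  dx <- ds$masks$dextran; vs <- ds$masks$endothelium
  leak <- ds$masks$leak$values
  expect_gt(sum(leak), 0)
  got <- extravascular_dextran_percentage(dx, vs)
  expect_equal(got, 100 * sum(leak) / length(leak), tolerance = 1e-12)
  # intact barrier: dextran confined to vessels
  expect_equal(extravascular_dextran_percentage(vs, vs), 0)
})

test_that("hypoxia statistics conserve voxels and track the decay length", {
  c1 <- voxel_grid(array(1500, c(4, 4, 4)), c(1, 1, 1))
  h <- hypoxia_stats(c1, n_bins = 8)
  expect_equal(h$mfi, 1500)
  expect_equal(sum(h$histogram), 64)
  expect_equal(sum(h$histogram > 0), 1L)
  vm <- array(FALSE, c(6, 20, 20)); vm[3, 10, 10] <- TRUE
  f_short <- make_hypoxia_field(mk(vm), decay_length_um = 5)
  f_long <- make_hypoxia_field(mk(vm), decay_length_um = 20)
  expect_gt(hypoxia_stats(f_short)$mfi, hypoxia_stats(f_long)$mfi)
  expect_error(hypoxia_stats(c1, tissue_mask = array(FALSE, c(4, 4, 4))),
               "empty tissue")
})

test_that("diffusion distances equal brute force on a 20^3 fixture", {
  set.seed(52)
  vm <- array(runif(8000) < 0.01, c(20, 20, 20)); vm[1, 1, 1] <- TRUE
  sp <- c(1.5, 0.8, 0.8)
  st <- diffusion_distance_stats(voxel_grid(vm, sp))
  co <- arrayInd(which(vm), dim(vm))
  ex <- arrayInd(which(!vm), dim(vm))
  bf <- vapply(seq_len(nrow(ex)), function(i)
    min(sqrt(colSums((t(co) * sp - ex[i, ] * sp)^2))), numeric(1))
  expect_equal(sort(st$distances_um), sort(bf), tolerance = 1e-12)
  expect_equal(st$max_um, max(bf))
  # single vessel plane at z=1, isotropic: distance at plane k is k-1
  pl <- array(FALSE, c(5, 4, 4)); pl[1, , ] <- TRUE
  d <- diffusion_distance_stats(voxel_grid(pl, c(1, 1, 1)))
  expect_equal(sort(unique(d$distances_um)), 1:4)
  expect_error(diffusion_distance_stats(mk(array(FALSE, c(3, 3, 3)))),
               "no vessels")
})

test_that("adding vessels strictly shrinks mean diffusion distance", {
  vm1 <- array(FALSE, c(8, 16, 16)); vm1[4, 8, 4] <- TRUE
  vm2 <- vm1; vm2[4, 8, 13] <- TRUE
  expect_gt(diffusion_distance_stats(mk(vm1))$mean_um,
            diffusion_distance_stats(mk(vm2))$mean_um)
})

test_that("PAS area percentage follows the RGB interval rule", {
  img <- array(0, c(20, 20, 3))
  rule <- list(r = c(120, 200), g = c(0, 90), b = c(100, 255))
  img[, , 1] <- 150; img[, , 2] <- 50; img[, , 3] <- 180 # all positive
  expect_equal(pas_area_percentage(img, rule), 100)
  img[, , 2] <- 200 # g outside the interval
  expect_equal(pas_area_percentage(img, rule), 0)
  # plant exactly 30% positive pixels
  set.seed(53)
  img[, , 2] <- 200
  pos <- sample(400, 120)
  g_ch <- img[, , 2]; g_ch[pos] <- 40; img[, , 2] <- g_ch
  expect_equal(pas_area_percentage(img, rule), 30)
  expect_error(pas_area_percentage(img, rule, matrix(FALSE, 20, 20)),
               "empty tissue")
})
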