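test_that("identical masks yield zero events", {
  ds <- pruning_case(1)
  bm <- ds$masks$basement_membrane
  expect_equal(nrow(detect_empty_sleeves(bm, bm)), 0L)
})

test_that("a bulky blob is rejected by the diameter filter", {
  dims <- c(31, 41, 41)
  blob <- paint_tubes(dims, c(1, 1, 1),
                      list(matrix(c(15.2, 20.2, 20.2), 1)), 10) # 20 um sphere
  ec <- array(FALSE, dims); ec[2, 2, 2] <- TRUE # far away
  ev <- detect_empty_sleeves(voxel_grid(blob, c(1, 1, 1)),
                             voxel_grid(ec, c(1, 1, 1)),
                             sleeve_params(require_bridging = FALSE,
                                           min_elongation = 1))
  expect_equal(nrow(ev), 0L)
  # same blob passes once the diameter cap is lifted
  ev2 <- detect_empty_sleeves(voxel_grid(blob, c(1, 1, 1)),
                              voxel_grid(ec, c(1, 1, 1)),
                              sleeve_params(require_bridging = FALSE,
                                            min_elongation = 1,
                                            max_diameter_um = 50,
                                            min_length_um = 3))
  expect_equal(nrow(ev2), 1L)
})

test_that("growing the endothelial dilation never adds events", {
  ds <- pruning_case(2)
  bm <- ds$masks$basement_membrane; ec <- ds$masks$endothelium
  n <- vapply(c(1, 2, 3, 4), function(r)
    nrow(detect_empty_sleeves(bm, ec, sleeve_params(ec_dilation_um = r))),
    numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("event ordering is deterministic and voxel sets stay disjoint", {
  ds <- pruning_case(1)
  ev <- detect_empty_sleeves(ds$masks$basement_membrane,
                             ds$masks$endothelium)
  expect_gt(nrow(ev), 0)
  ord <- order(ev$centroid_z_um, ev$centroid_y_um, ev$centroid_x_um)
  expect_identical(ord, seq_len(nrow(ev)))
  vox <- attr(ev, "voxels")
  expect_equal(length(unlist(vox)), length(unique(unlist(vox))))
  ev2 <- detect_empty_sleeves(ds$masks$basement_membrane,
                              ds$masks$endothelium)
  expect_identical(ev$centroid_x_um, ev2$centroid_x_um)
})

test_that("shape mismatch raises an error", {
  a <- voxel_grid(array(FALSE, c(3, 3, 3)), c(1, 1, 1))
  b <- voxel_grid(array(FALSE, c(3, 3, 4)), c(1, 1, 1))
  expect_error(detect_empty_sleeves(a, b), "shape")
})

test_that("pruning density and segment ratio convert units correctly", {
  expect_equal(pruning_density(0, 1e9), 0)
  expect_equal(pruning_density(1, 1e9), 1)
  expect_equal(pruning_density(129, 0.004287 * 1e9), 129 / 0.004287)
  expect_equal(pruning_segment_ratio(100, 2500), 4)
  expect_equal(pruning_segment_ratio(0, 1234), 0)
  expect_equal(pruning_segment_ratio(77, 77), 100)
  expect_error(pruning_segment_ratio(1, 0), "zero segments")
})
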