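# Tube fixtures are centred off the half-grid so each tube has a unique
# medial fibre (centre-symmetric even-width tubes have no single medial
# voxel line and thin ambiguously).

test_that("a straight cylinder skeletonizes to one axial chain", {
  tube <- paint_tubes(c(11, 11, 44), c(1, 1, 1),
                      list(rbind(c(5.2, 5.2, 3), c(5.2, 5.2, 41))), 3)
  sk <- skeletonize_mask(voxel_grid(tube, c(1, 1, 1)))
  expect_true(all(tube[sk$values])) # skeleton inside the mask
  g <- build_graph(sk, voxel_grid(tube, c(1, 1, 1)))
  expect_equal(nrow(g$segments), 1L)
  expect_equal(sort(g$nodes$degree), c(1L, 1L))
  expect_lt(abs(g$segments$tortuosity - 1), 0.05)
  expect_lt(abs(g$segments$mean_diameter_um - 6), sqrt(3))
})

test_that("empty and disjoint masks keep their component structure", {
  e <- voxel_grid(array(FALSE, c(4, 4, 4)), c(1, 1, 1))
  expect_equal(sum(skeletonize_mask(e)$values), 0)
  two <- paint_tubes(c(11, 30, 30), c(1, 1, 1),
                     list(rbind(c(5.2, 6.2, 3), c(5.2, 6.2, 27)),
                          rbind(c(5.2, 22.2, 3), c(5.2, 22.2, 27))),
                     c(2.4, 2.4))
  sk <- skeletonize_mask(voxel_grid(two, c(1, 1, 1)))
  expect_equal(max(label_components(sk$values)), 2L)
})

test_that("Y and X junctions give the expected segments and node degrees", {
  dims <- c(21, 41, 41)
  yt <- paint_tubes(dims, c(1, 1, 1),
                    list(rbind(c(10.2, 20.2, 2), c(10.2, 20.2, 20.2)),
                         rbind(c(10.2, 20.2, 20.2), c(10.2, 5, 38)),
                         rbind(c(10.2, 20.2, 20.2), c(10.2, 35, 38))),
                    rep(3, 3))
  gy <- merge_close_junctions(prune_spurs(
    build_graph(skeletonize_mask(voxel_grid(yt, c(1, 1, 1))),
                voxel_grid(yt, c(1, 1, 1))), 4), 5)
  expect_equal(nrow(gy$segments), 3L)
  expect_equal(sum(gy$nodes$degree == 3), 1L) # one bifurcation
  expect_equal(sum(gy$nodes$degree == 1), 3L)

  xt <- paint_tubes(dims, c(1, 1, 1),
                    list(rbind(c(10.2, 20.2, 20.2), c(10.2, 4, 4)),
                         rbind(c(10.2, 20.2, 20.2), c(10.2, 4, 36)),
                         rbind(c(10.2, 20.2, 20.2), c(10.2, 36, 4)),
                         rbind(c(10.2, 20.2, 20.2), c(10.2, 36, 36))),
                    rep(2.6, 4))
  gx <- merge_close_junctions(prune_spurs(
    build_graph(skeletonize_mask(voxel_grid(xt, c(1, 1, 1))),
                voxel_grid(xt, c(1, 1, 1))), 4), 5)
  expect_equal(nrow(gx$segments), 4L)
  expect_equal(sum(gx$nodes$degree == 4), 1L) # one trifurcation
  expect_equal(sum(gx$nodes$degree == 1), 4L)
})

test_that("a skeleton voxel outside the mask is a consistency error", {
  m <- array(FALSE, c(4, 4, 4)); m[2, 2, 2] <- TRUE
  sk <- array(FALSE, c(4, 4, 4)); sk[3, 3, 3] <- TRUE
  expect_error(build_graph(voxel_grid(sk, c(1, 1, 1)),
                           voxel_grid(m, c(1, 1, 1))), "consistency")
})

test_that("degree sum equals twice the segment count on random trees", {
  for (seed in 1:3) {
    g <- graph_recovery_case(seed)$graph
    expect_equal(sum(g$nodes$degree), 2L * nrow(g$segments))
    expect_true(all(g$segments$tortuosity >= 1 - 1e-9))
    expect_true(all(g$segments$chord_um > 0))
  }
})

test_that("spur pruning removes short terminal twigs and is idempotent", {
  # long tube with a 3 um side twig
  dims <- c(15, 21, 50)
  tube <- paint_tubes(dims, c(1, 1, 1),
                      list(rbind(c(7.2, 10.2, 3), c(7.2, 10.2, 46)),
                           rbind(c(7.2, 10.2, 25.2), c(7.2, 16.2, 25.2))),
                      c(2.6, 1.6))
  g0 <- build_graph(skeletonize_mask(voxel_grid(tube, c(1, 1, 1))),
                    voxel_grid(tube, c(1, 1, 1)))
  g1 <- prune_spurs(g0, 5)
  expect_equal(nrow(g1$segments), 1L)
  expect_equal(sort(g1$nodes$degree), c(1L, 1L))
  # identity at threshold 0 and idempotence at the fixpoint
  expect_equal(nrow(prune_spurs(g0, 0)$segments), nrow(g0$segments))
  g2 <- prune_spurs(g1, 5)
  expect_equal(g2$segments$length_um, g1$segments$length_um)
})

test_that("network metrics aggregate counts, ratios and histograms", {
  g <- graph_recovery_case(1)$graph
  ds <- simulate_voi(1, preset = "graph_recovery")
  met <- compute_metrics(g, mask = ds$masks$endothelium, nuclei_count = 30)
  expect_equal(met$n_segments, nrow(g$segments))
  expect_equal(met$n_branching_nodes, sum(g$nodes$degree >= 3))
  expect_equal(met$n_bifurcations + met$n_trifurcations,
               sum(g$nodes$degree %in% c(3, 4)))
  expect_equal(sum(met$diameter_histogram), met$n_segments)
  expect_equal(met$ec_per_vascular_length,
               30 / g$total_skeleton_length_um)
  # 6 nuclei over 300 um -> 0.02 per um
  fake <- g; fake$total_skeleton_length_um <- 300
  expect_equal(compute_metrics(fake, nuclei_count = 6)$ec_per_vascular_length,
               0.02)
  # all diameters in one bin
  expect_equal(unname(table(cut(rep(6, 5), c(0, 3, 5, 8, 12, Inf),
                                right = FALSE))[3]), 5L)
  empty <- cardiocap3d:::graph_from_voxels(integer(0), c(2L, 2L, 2L),
                                           c(1, 1, 1), numeric(0))
  expect_error(compute_metrics(empty, nuclei_count = 3), "undefined ratio")
})
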