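#' Generate a random 3D vascular network with ground truth
#'
#' Grows a connected capillary-scale network inside a box by iterative
#' midpoint sprouting: starting from a single segment, the generator either
#' splits an existing segment at its midpoint and sprouts a new branch from
#' the split point (creating a degree-3 bifurcation node) or sprouts from an
#' existing degree-3 node (creating a degree-4 trifurcation node). New
#' endpoints are rejected until they respect a minimum node separation, which
#' also bounds how tightly the network can be packed. Segment centrelines are
#' jittered polylines; `tortuosity_amplitude = 0` gives exactly straight
#' segments.
#'
#' The defaults emulate a left-ventricular free-wall volume of interest:
#' a 350 x 350 x 35 um box holds on the order of 2,000-3,000 capillary
#' segments with radii of a few micrometres.
#'
#' @param domain_um box size `(z, y, x)` in micrometres.
#' @param n_segments_target number of segments to aim for; the realised count
#'   is within +-10% of this (in practice `target` or `target + 1`).
#' @param radius_dist `(mean, sd)` in um of the per-segment radius
#'   distribution (gaussian, truncated to stay positive).
#' @param tortuosity_amplitude lateral jitter amplitude in um applied to
#'   interior path points; 0 gives straight chords.
#' @param segment_length_um `(min, max)` of sprout lengths in um.
#' @param min_separation_um minimum distance between network nodes; doubles
#'   as the packing limit (an impossible target density raises an error).
#' @param min_clearance_um optional minimum distance between a new sprout and
#'   all non-incident existing segments. Off (`NULL`) by default; set it when
#'   the downstream analysis requires tubes that never merge (e.g. exact
#'   graph-recovery experiments).
#' @param p_trifurcation probability that a growth step sprouts from an
#'   existing bifurcation, upgrading it to a trifurcation.
#' @param split_band `(lo, hi)` band of relative positions along a chord
#'   where splits may land; narrowing it toward the middle (e.g.
#'   `c(0.4, 0.6)`) keeps internal segments from becoming much shorter than
#'   the sprout lengths.
#' @param min_branch_angle_deg minimum angle between a new sprout and every
#'   segment already incident at its anchor node. Shallow angles make the
#'   rendered tubes of sibling branches merge far beyond the junction, so
#'   raise this (e.g. to 45) when downstream analyses need crisp junctions.
#' @param z_anisotropy factor in `(0, 1]` scaling the z component of sprout
#'   directions before normalisation; values below 1 keep the network mostly
#'   in-plane, as in capillaries of a thin physical section, and stop long
#'   sprouts from being clamped against the slab faces.
#' @param margin_um empty border kept around the network.
#' @param seed integer seed; one stream drives all draws.
#' @return A `vascular_graph_truth`: `nodes` (id, position um, degree),
#'   `segments` (a list: id, `path_um` matrix, `radius_um`,
#'   `is_empty_sleeve`, `is_perfused`), `domain_um`, `seed`.
#' @export
generate_vascular_tree <- function(domain_um, n_segments_target,
                                   radius_dist = c(2, 0.3),
                                   tortuosity_amplitude = 1,
                                   segment_length_um = c(15, 40),
                                   min_separation_um = 4,
                                   min_clearance_um = NULL,
                                   p_trifurcation = 0.12,
                                   split_band = c(0, 1),
                                   min_branch_angle_deg = 30,
                                   z_anisotropy = 1,
                                   margin_um = 3,
                                   seed = 1L) {
  domain_um <- as.numeric(domain_um)
  stopifnot(length(domain_um) == 3L, all(domain_um > 0),
            n_segments_target >= 1, radius_dist[1] > 0)
  # packing feasibility: each node needs an exclusion ball of radius
  # min_separation_um / 2
  ball <- (4 / 3) * pi * (min_separation_um / 2)^3
  if ((n_segments_target + 2) * ball > prod(domain_um))
    stop("capacity error: target segment density exceeds domain capacity ",
         "at the requested minimum node separation")
  if (any(domain_um <= 2 * margin_um))
    margin_um <- min(domain_um) / 4

  with_seed(seed, {
    lo <- rep(margin_um, 3)
    hi <- domain_um - margin_um
    nmax <- 2L * n_segments_target + 10L
    pos <- matrix(NA_real_, nmax, 3)
    deg <- integer(nmax)
    segs <- matrix(NA_integer_, n_segments_target + 2L, 2)
    nn <- 0L; ns <- 0L

    rand_point <- function() lo + runif(3) * (hi - lo)
    rand_dir <- function() {
      repeat {
        v <- rnorm(3)
        v[1] <- v[1] * z_anisotropy
        n2 <- sqrt(sum(v^2))
        if (n2 > 1e-9) return(v / n2)
      }
    }
    min_node_dist <- function(p, exclude = integer(0)) {
      if (nn == 0L) return(Inf)
      keep <- setdiff(seq_len(nn), exclude)
      if (!length(keep)) return(Inf)
      d2 <- (pos[keep, 1] - p[1])^2 + (pos[keep, 2] - p[2])^2 +
        (pos[keep, 3] - p[3])^2
      sqrt(min(d2))
    }
    clearance_ok <- function(a, b, exclude_segs) {
      if (is.null(min_clearance_um) || ns == 0L) return(TRUE)
      for (s in setdiff(seq_len(ns), exclude_segs)) {
        e <- segs[s, ]
        if (segment_segment_distance(a, b, pos[e[1], ], pos[e[2], ]) <
            min_clearance_um) return(FALSE)
      }
      TRUE
    }
    sprout_point <- function(anchor) {
      d <- rand_dir()
      len <- runif(1, segment_length_um[1], segment_length_um[2])
      pmin(pmax(anchor + len * d, lo), hi)
    }
    cos_max <- cos(min_branch_angle_deg * pi / 180)
    angle_ok <- function(anchor, tip, incident_dirs) {
      d <- tip - anchor
      nd <- sqrt(sum(d^2))
      if (nd < 1e-9) return(FALSE)
      d <- d / nd
      for (u in incident_dirs) if (sum(d * u) > cos_max) return(FALSE)
      TRUE
    }

    # initial segment; must itself be splittable (chord >= 2 x separation)
    # or growth could never start
    failures <- 0L
    repeat {
      a <- rand_point()
      b <- sprout_point(a)
      if (sqrt(sum((a - b)^2)) >= 2 * min_separation_um) break
      failures <- failures + 1L
      if (failures > 1000L)
        stop("capacity error: cannot place a splittable initial segment ",
             "(segment lengths too short for the requested node separation)")
    }
    pos[1, ] <- a; pos[2, ] <- b
    deg[1:2] <- 1L; nn <- 2L
    segs[1, ] <- c(1L, 2L); ns <- 1L

    # each growth round tries one action (segment split or trifurcation
    # sprout) with a bounded number of direction redraws; a long run of
    # completely failed rounds means the domain cannot hold the target
    try_tri <- function() {
      tri_nodes <- which(deg[seq_len(nn)] == 3L)
      if (!length(tri_nodes)) return(FALSE)
      anchor_id <- tri_nodes[sample.int(length(tri_nodes), 1L)]
      inc <- which(segs[seq_len(ns), 1] == anchor_id |
                   segs[seq_len(ns), 2] == anchor_id)
      inc_dirs <- lapply(inc, function(s) {
        other <- setdiff(segs[s, ], anchor_id)[1]
        u <- pos[other, ] - pos[anchor_id, ]
        u / sqrt(sum(u^2))
      })
      for (try in 1:20) {
        tip <- sprout_point(pos[anchor_id, ])
        if (angle_ok(pos[anchor_id, ], tip, inc_dirs) &&
            min_node_dist(tip) >= min_separation_um &&
            clearance_ok(pos[anchor_id, ], tip, inc)) {
          nn <<- nn + 1L; pos[nn, ] <<- tip; deg[nn] <<- 1L
          ns <<- ns + 1L; segs[ns, ] <<- c(anchor_id, nn)
          deg[anchor_id] <<- 4L
          return(TRUE)
        }
      }
      FALSE
    }
    try_split <- function() {
      chords <- sqrt(rowSums((pos[segs[seq_len(ns), 1], , drop = FALSE] -
                              pos[segs[seq_len(ns), 2], , drop = FALSE])^2))
      splittable <- which(chords >= 2 * min_separation_um)
      if (!length(splittable)) return(FALSE)
      for (try in 1:20) {
        s <- splittable[sample.int(length(splittable), 1L)]
        e <- segs[s, ]
        # random split position keeping both sub-chords >= the separation
        f <- min_separation_um / chords[s]
        band <- c(max(f, split_band[1]), min(1 - f, split_band[2]))
        if (band[1] > band[2]) band <- c(f, 1 - f)
        t <- runif(1, band[1], band[2])
        mid <- pos[e[1], ] + t * (pos[e[2], ] - pos[e[1], ])
        if (min_node_dist(mid, exclude = e) < min_separation_um) next
        u <- pos[e[2], ] - pos[e[1], ]
        u <- u / sqrt(sum(u^2))
        tip <- sprout_point(mid)
        if (angle_ok(mid, tip, list(u, -u)) &&
            min_node_dist(tip) >= min_separation_um &&
            sqrt(sum((mid - tip)^2)) >= min_separation_um &&
            clearance_ok(mid, tip, s)) {
          nn <<- nn + 1L; pos[nn, ] <<- mid; deg[nn] <<- 3L
          mid_id <- nn
          nn <<- nn + 1L; pos[nn, ] <<- tip; deg[nn] <<- 1L
          segs[s, ] <<- c(e[1], mid_id)
          ns <<- ns + 1L; segs[ns, ] <<- c(mid_id, e[2])
          ns <<- ns + 1L; segs[ns, ] <<- c(mid_id, nn)
          return(TRUE)
        }
      }
      FALSE
    }
    fail_rounds <- 0L
    while (ns < n_segments_target) {
      if (fail_rounds > 200L)
        stop("capacity error: target density exceeds domain capacity ",
             "(node placement kept failing the separation constraint)")
      want_tri <- runif(1) < p_trifurcation && ns + 1L <= n_segments_target
      ok <- if (want_tri) { try_tri() || try_split() }
            else { try_split() || try_tri() }
      fail_rounds <- if (ok) 0L else fail_rounds + 1L
    }

    pos <- pos[seq_len(nn), , drop = FALSE]
    segs <- segs[seq_len(ns), , drop = FALSE]

    radii <- rnorm(ns, radius_dist[1], radius_dist[2])
    rmin <- max(0.25 * radius_dist[1], radius_dist[1] - 3 * radius_dist[2])
    radii <- pmin(pmax(radii, rmin), radius_dist[1] + 3 * radius_dist[2])

    segments <- vector("list", ns)
    for (s in seq_len(ns)) {
      a <- pos[segs[s, 1], ]; b <- pos[segs[s, 2], ]
      segments[[s]] <- list(
        id = s, from = segs[s, 1], to = segs[s, 2],
        path_um = jitter_path(a, b, tortuosity_amplitude, domain_um),
        radius_um = radii[s],
        is_empty_sleeve = FALSE, is_perfused = TRUE)
    }

    deg_final <- tabulate(as.vector(segs), nbins = nn)
    nodes <- data.frame(id = seq_len(nn), z = pos[, 1], y = pos[, 2],
                        x = pos[, 3], degree = as.integer(deg_final))
    structure(list(nodes = nodes, segments = segments,
                   domain_um = domain_um, seed = seed),
              class = "vascular_graph_truth")
  })
}

# Closest distance between 3D segments [a1,b1] and [a2,b2].
segment_segment_distance <- function(a1, b1, a2, b2) {
  d1 <- b1 - a1; d2 <- b2 - a2; r <- a1 - a2
  aa <- sum(d1 * d1); ee <- sum(d2 * d2); ff <- sum(d2 * r)
  if (aa < 1e-12 && ee < 1e-12) return(sqrt(sum(r * r)))
  if (aa < 1e-12) {
    s <- 0; t <- min(1, max(0, ff / ee))
  } else {
    cc <- sum(d1 * r)
    if (ee < 1e-12) {
      t <- 0; s <- min(1, max(0, -cc / aa))
    } else {
      bb <- sum(d1 * d2)
      den <- aa * ee - bb * bb
      s <- if (den > 1e-12) min(1, max(0, (bb * ff - cc * ee) / den)) else 0
      t <- (bb * s + ff) / ee
      if (t < 0) { t <- 0; s <- min(1, max(0, -cc / aa)) }
      else if (t > 1) { t <- 1; s <- min(1, max(0, (bb - cc) / aa)) }
    }
  }
  p1 <- a1 + s * d1; p2 <- a2 + t * d2
  sqrt(sum((p1 - p2)^2))
}

# Subdivide the chord a->b and add a smooth sinusoidal lateral arc of the
# given amplitude in a random plane containing the chord. Endpoints are
# always exact; amplitude 0 keeps all points collinear.
jitter_path <- function(a, b, amplitude, domain_um, step_um = 8) {
  chord <- sqrt(sum((b - a)^2))
  nsub <- max(1L, as.integer(ceiling(chord / step_um)))
  if (amplitude > 0 && nsub < 2L) nsub <- 2L
  tt <- seq(0, 1, length.out = nsub + 1L)
  path <- outer(rep(1, nsub + 1L), a) + outer(tt, b - a)
  if (amplitude > 0) {
    dir <- (b - a) / chord
    ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * dir) * dir
    u <- u / sqrt(sum(u^2))
    v <- c(dir[2] * u[3] - dir[3] * u[2],
           dir[3] * u[1] - dir[1] * u[3],
           dir[1] * u[2] - dir[2] * u[1])
    phase <- runif(1, 0, 2 * pi)
    w <- cos(phase) * u + sin(phase) * v
    off <- amplitude * sin(pi * tt)
    path <- path + outer(off, w)
    eps <- 1e-3
    for (ax in 1:3) path[, ax] <- pmin(pmax(path[, ax], eps), domain_um[ax] - eps)
    keep <- c(TRUE, rowSums(abs(diff(path))) > 1e-9)
    path <- path[keep, , drop = FALSE]
  }
  dimnames(path) <- NULL
  path
}

#' Validate the internal consistency of a ground-truth network
#'
#' Checks that segment endpoints coincide with node positions (to 1e-6 um),
#' that node degrees equal the number of incident segment endpoints, that all
#' path points lie inside the domain, and that no empty-sleeve segment is
#' flagged perfused.
#'
#' @param graph a `vascular_graph_truth`.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_vascular_truth <- function(graph) {
  stopifnot(inherits(graph, "vascular_graph_truth"))
  np <- as.matrix(graph$nodes[, c("z", "y", "x")])
  inc <- integer(nrow(np))
  for (s in graph$segments) {
    p <- s$path_um
    if (nrow(p) < 2L) stop("segment ", s$id, " has fewer than 2 path points")
    if (any(rowSums(abs(diff(p))) <= 1e-12))
      stop("segment ", s$id, " has duplicate consecutive path points")
    if (s$radius_um <= 0) stop("segment ", s$id, " has non-positive radius")
    if (s$is_empty_sleeve && s$is_perfused)
      stop("segment ", s$id, " is an empty sleeve flagged as perfused")
    for (end in list(c(s$from, 1L), c(s$to, nrow(p)))) {
      d <- sqrt(sum((np[end[1], ] - p[end[2], ])^2))
      if (d > 1e-6)
        stop("segment ", s$id, " endpoint does not coincide with its node")
    }
    inc[s$from] <- inc[s$from] + 1L
    inc[s$to] <- inc[s$to] + 1L
    for (ax in 1:3)
      if (any(p[, ax] < -1e-9 | p[, ax] > graph$domain_um[ax] + 1e-9))
        stop("segment ", s$id, " leaves the domain")
  }
  if (!all(inc == graph$nodes$degree))
    stop("node degrees do not match incident segment endpoints")
  invisible(TRUE)
}

#' @export
print.vascular_graph_truth <- function(x, ...) {
  ns <- length(x$segments)
  sl <- sum(vapply(x$segments, `[[`, logical(1), "is_empty_sleeve"))
  cat(sprintf("<vascular_graph_truth> %d nodes, %d segments (%d empty sleeves) in %.0f x %.0f x %.0f um\n",
              nrow(x$nodes), ns, sl,
              x$domain_um[1], x$domain_um[2], x$domain_um[3]))
  invisible(x)
}

#' Flag a fraction of segments as empty basement-membrane sleeves
#'
#' Marks `round(fraction * n_segments)` segments, sampled without
#' replacement, as empty sleeves (COL IV positive / ICAM2 negative) -- the
#' ground truth for pruning events. Pruning removes redundant connections
#' between perfused vessels, so sleeves are preferentially drawn from
#' bridging segments (both endpoints of degree >= 3) when enough exist;
#' uniform placement is available with `prefer_bridging = FALSE`. Sleeves are
#' never perfused.
#'
#' @param graph a `vascular_graph_truth`.
#' @param fraction fraction of segments to flag, in `[0, 1]`. The postnatal
#'   heart shows roughly 4% of segments as sleeves, hence the default.
#' @param seed integer seed.
#' @param prefer_bridging prefer segments whose two endpoints are branching
#'   nodes.
#' @param min_length_um prefer segments at least this long (um): a pruned
#'   capillary is a full segment, and stubs shorter than the detection
#'   trimming scale would be invisible sleeves. Shorter segments are used
#'   only when the preferred pool runs out.
#' @return The graph with updated `is_empty_sleeve` / `is_perfused` flags.
#' @export
plant_empty_sleeves <- function(graph, fraction = 0.04, seed = 1L,
                                prefer_bridging = TRUE, min_length_um = 14) {
  stopifnot(inherits(graph, "vascular_graph_truth"),
            fraction >= 0, fraction <= 1)
  ns <- length(graph$segments)
  k <- round(fraction * ns)
  deg <- graph$nodes$degree
  for (i in seq_len(ns)) {
    graph$segments[[i]]$is_empty_sleeve <- FALSE
    graph$segments[[i]]$is_perfused <- TRUE
  }
  if (k == 0) return(graph)
  with_seed(seed, {
    seg_len <- vapply(graph$segments, function(s)
      sum(sqrt(rowSums(diff(s$path_um)^2))), numeric(1))
    is_bridge <- vapply(graph$segments, function(s)
      deg[s$from] >= 3L && deg[s$to] >= 3L, logical(1))
    if (!prefer_bridging) is_bridge[] <- FALSE
    # preference tiers: bridging and long, bridging, long, the rest
    tiers <- list(which(is_bridge & seg_len >= min_length_um),
                  which(is_bridge & seg_len < min_length_um),
                  which(!is_bridge & seg_len >= min_length_um),
                  which(!is_bridge & seg_len < min_length_um))
    # greedy draw avoiding sleeves that share an endpoint node: adjacent
    # sleeves would fuse into one basement-membrane remnant
    chosen <- integer(0)
    used_nodes <- integer(0)
    for (pass in 1:2) {
      for (tier in tiers) {
        if (length(chosen) >= k) break
        pool <- setdiff(tier, chosen)
        if (!length(pool)) next
        for (i in pool[sample.int(length(pool))]) {
          if (length(chosen) >= k) break
          ends <- c(graph$segments[[i]]$from, graph$segments[[i]]$to)
          if (pass == 1L && any(ends %in% used_nodes)) next
          chosen <- c(chosen, i)
          used_nodes <- c(used_nodes, ends)
        }
      }
      if (length(chosen) >= k) break
    }
    for (i in chosen) {
      graph$segments[[i]]$is_empty_sleeve <- TRUE
      graph$segments[[i]]$is_perfused <- FALSE
    }
    graph
  })
}

#' Flag a fraction of intact segments as non-perfused
#'
#' Marks a random subset of non-sleeve segments as carrying no intravascular
#' tracer, emulating incomplete perfusion of an otherwise intact network.
#'
#' @param graph a `vascular_graph_truth`.
#' @param fraction fraction of non-sleeve segments to de-perfuse.
#' @param seed integer seed.
#' @return The updated graph.
#' @export
set_nonperfused <- function(graph, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  idx <- which(!vapply(graph$segments, `[[`, logical(1), "is_empty_sleeve"))
  k <- round(fraction * length(idx))
  for (i in idx) graph$segments[[i]]$is_perfused <- TRUE
  if (k == 0) return(graph)
  with_seed(seed, {
    chosen <- idx[sample.int(length(idx), k)]
    for (i in chosen) graph$segments[[i]]$is_perfused <- FALSE
    graph
  })
}

# Sum of path lengths for a subset of segments.
truth_total_length <- function(graph, which_segments = NULL) {
  segs <- graph$segments
  if (!is.null(which_segments)) segs <- segs[which_segments]
  sum(vapply(segs, function(s) sum(sqrt(rowSums(diff(s$path_um)^2))),
             numeric(1)))
}

# Shared raster geometry: voxel counts from domain size and spacing.
raster_shape <- function(domain_um, voxel_size_um) {
  pmax(1L, as.integer(round(domain_um / voxel_size_um)))
}

# Paint a set of truth segments as capsules on a voxel grid.
paint_segments <- function(graph, voxel_size_um, which_segments,
                           radius_offset_um = 0) {
  shp <- raster_shape(graph$domain_um, voxel_size_um)
  segs <- graph$segments[which_segments]
  if (!length(segs)) {
    return(array(FALSE, shp))
  }
  paths <- lapply(segs, `[[`, "path_um")
  radii <- vapply(segs, `[[`, numeric(1), "radius_um") + radius_offset_um
  m <- cpp_paint_capsules(shp, voxel_size_um, paths, radii)
  array(m, shp)
}

#' Scatter endothelial nuclei along the vessel walls
#'
#' Draws a Poisson number of nuclei with expectation
#' `linear_density_per_um x total non-sleeve path length`, places each at a
#' uniformly random arc-length position offset to the vessel wall (one
#' segment radius away from the centreline, in a random perpendicular
#' direction), and renders them as spheres. The returned truth list is
#' independent of rendering overlaps.
#'
#' @param graph a `vascular_graph_truth`.
#' @param linear_density_per_um nuclei per um of vessel length. The default
#'   0.05/um mirrors an endothelial cell roughly every 20 um of capillary.
#' @param nucleus_radius_um rendered nucleus radius (um).
#' @param voxel_size_um raster spacing `(dz, dy, dx)`.
#' @param seed integer seed.
#' @return list with `grid` (binary `voxel_grid`) and `points`
#'   (n x 3 matrix of um positions, possibly 0 rows).
#' @export
scatter_nuclei <- function(graph, linear_density_per_um = 0.05,
                           nucleus_radius_um = 2.5,
                           voxel_size_um = c(2, 0.6, 0.6), seed = 1L) {
  stopifnot(linear_density_per_um >= 0)
  with_seed(seed,
    scatter_nuclei_core(graph, linear_density_per_um, nucleus_radius_um,
                        voxel_size_um))
}

scatter_nuclei_core <- function(graph, linear_density_per_um,
                                nucleus_radius_um, voxel_size_um) {
  shp <- raster_shape(graph$domain_um, voxel_size_um)
  keep <- which(!vapply(graph$segments, `[[`, logical(1), "is_empty_sleeve"))
  seg_len <- vapply(graph$segments[keep], function(s)
    sum(sqrt(rowSums(diff(s$path_um)^2))), numeric(1))
  total <- sum(seg_len)
  n <- if (total > 0 && linear_density_per_um > 0)
    rpois(1L, linear_density_per_um * total) else 0L
  pts <- matrix(numeric(0), 0, 3)
  if (n > 0) {
    u <- runif(n) * total
    cum <- cumsum(seg_len)
    si <- findInterval(u, cum, left.open = TRUE) + 1L
    pts <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      s <- graph$segments[[keep[si[i]]]]
      arc <- u[i] - if (si[i] > 1) cum[si[i] - 1] else 0
      p <- point_along_path(s$path_um, arc)
      dir <- p$tangent
      repeat {
        v <- rnorm(3)
        v <- v - sum(v * dir) * dir
        nv <- sqrt(sum(v^2))
        if (nv > 1e-9) { v <- v / nv; break }
      }
      pts[i, ] <- p$point + s$radius_um * v
    }
    for (ax in 1:3)
      pts[, ax] <- pmin(pmax(pts[, ax], 1e-3), graph$domain_um[ax] - 1e-3)
  }
  vals <- if (nrow(pts) > 0) {
    paths <- lapply(seq_len(nrow(pts)), function(i) pts[i, , drop = FALSE])
    array(cpp_paint_capsules(shp, voxel_size_um, paths,
                             rep(nucleus_radius_um, nrow(pts))), shp)
  } else array(FALSE, shp)
  list(grid = voxel_grid(vals, voxel_size_um, "nuclei"), points = pts)
}

# Point and unit tangent at arc length `arc` along a polyline.
point_along_path <- function(path, arc) {
  steps <- sqrt(rowSums(diff(path)^2))
  cum <- c(0, cumsum(steps))
  arc <- min(max(arc, 0), cum[length(cum)])
  i <- findInterval(arc, cum, left.open = TRUE)
  i <- min(max(i, 1L), nrow(path) - 1L)
  t <- if (steps[i] > 0) (arc - cum[i]) / steps[i] else 0
  dir <- (path[i + 1L, ] - path[i, ])
  dir <- dir / sqrt(sum(dir^2))
  list(point = path[i, ] + t * (path[i + 1L, ] - path[i, ]), tangent = dir)
}

#' Synthetic tissue-hypoxia intensity field
#'
#' Builds a 12-bit hypoxia-probe intensity field that saturates with distance
#' from the nearest perfused vessel:
#' `I(v) = max_intensity * (1 - exp(-d(v) / decay_length_um))`, where `d` is
#' the anisotropy-aware euclidean distance (um) to the vessel mask. Vessel
#' voxels read 0; intensity is monotone non-decreasing in `d`.
#'
#' @param vessel_mask perfused-vessel mask (`voxel_grid`).
#' @param decay_length_um distance scale of the rise (um); of the order of
#'   the oxygen diffusion length in tissue.
#' @param max_intensity plateau intensity, at most 4095.
#' @return an intensity `voxel_grid`.
#' @export
make_hypoxia_field <- function(vessel_mask, decay_length_um = 30,
                               max_intensity = 3000) {
  stopifnot(decay_length_um > 0, max_intensity <= 4095)
  v <- vg_mask(vessel_mask)
  sp <- vg_spacing(vessel_mask)
  if (!any(v)) {
    warning("empty vessel mask: hypoxia field is uniformly at max_intensity")
    return(voxel_grid(array(max_intensity, dim(v)), sp, "hypoxia"))
  }
  d <- distance_transform_um(vessel_mask)
  voxel_grid(max_intensity * (1 - exp(-d / decay_length_um)), sp, "hypoxia")
}

#' Rasterize a ground-truth network into a multi-channel synthetic dataset
#'
#' Renders the six channels of the imaging regime this package targets, each
#' as blurred tube indicator x amplitude + background + gaussian noise,
#' clipped to the 12-bit range and rounded to integer counts:
#' \describe{
#'   \item{endothelium}{tubes of all non-sleeve segments (ICAM2).}
#'   \item{basement_membrane}{tubes of ALL segments, sleeves included, with
#'     radius enlarged by `bm_wall_um` (COL IV ensheathing the endothelium).}
#'   \item{nuclei}{spheres scattered on vessel walls (ERG).}
#'   \item{perfusion}{tubes of perfused segments only (i.v. IB4).}
#'   \item{dextran}{perfused tubes plus optional extravascular leak blobs.}
#'   \item{hypoxia}{distance-saturating field from the perfused mask
#'     (pimonidazole).}
#' }
#' Noise-free ground-truth voxelizations of the structural masks are kept in
#' `$masks` so downstream detectors can be scored against exact truth.
#'
#' @param graph a `vascular_graph_truth`.
#' @param voxel_size_um raster spacing `(dz, dy, dx)`; the default mirrors
#'   2 um optical sections at x20 magnification.
#' @param psf_sigma_um isotropic gaussian blur emulating the point-spread
#'   function, in um (0 = none).
#' @param noise_sd gaussian noise standard deviation (intensity counts).
#' @param background,amplitude baseline and foreground intensity (counts).
#' @param bm_wall_um extra basement-membrane radius beyond the endothelial
#'   tube, so sleeves are thin-walled.
#' @param nuclei_density_per_um,nucleus_radius_um passed to the nucleus
#'   scatterer.
#' @param hypoxia_decay_um,hypoxia_max hypoxia-field parameters.
#' @param n_leak_blobs,leak_radius_um optional extravascular dextran leaks.
#' @param seed integer seed; all draws (nucleus scatter, leak centres, then
#'   per-channel noise in the order endothelium, basement_membrane, nuclei,
#'   perfusion, dextran, hypoxia) come from this one stream.
#' @return a `synthetic_dataset`: `channels` (named intensity `voxel_grid`s),
#'   `masks` (noise-free binary truth), `truth` (the input graph),
#'   `nuclei_truth` (n x 3 um), `seed`, `params`.
#' @export
rasterize <- function(graph, voxel_size_um = c(2, 0.6, 0.6),
                      psf_sigma_um = 0.5, noise_sd = 100,
                      background = 100, amplitude = 2000,
                      bm_wall_um = 0.5,
                      nuclei_density_per_um = 0.05, nucleus_radius_um = 2.5,
                      hypoxia_decay_um = 30, hypoxia_max = 3000,
                      n_leak_blobs = 0, leak_radius_um = 5,
                      seed = 1L) {
  stopifnot(inherits(graph, "vascular_graph_truth"),
            all(voxel_size_um > 0), noise_sd >= 0)
  radii <- vapply(graph$segments, `[[`, numeric(1), "radius_um")
  if (length(radii) && max(voxel_size_um) > min(radii))
    warning("voxel size exceeds the smallest tube radius: thin tubes may ",
            "vanish from the raster")

  sleeve <- vapply(graph$segments, `[[`, logical(1), "is_empty_sleeve")
  perf <- vapply(graph$segments, `[[`, logical(1), "is_perfused")
  sp <- as.numeric(voxel_size_um)

  ec <- paint_segments(graph, sp, which(!sleeve))
  bm <- paint_segments(graph, sp, seq_along(graph$segments), bm_wall_um)
  pf <- paint_segments(graph, sp, which(perf))
  shp <- dim(ec)

  with_seed(seed, {
    nuc <- scatter_nuclei_core(graph, nuclei_density_per_um,
                               nucleus_radius_um, sp)
    leak <- array(FALSE, shp)
    if (n_leak_blobs > 0) {
      centres <- matrix(runif(3L * n_leak_blobs), ncol = 3)
      centres <- sweep(centres, 2L, graph$domain_um, `*`)
      paths <- lapply(seq_len(n_leak_blobs), function(i)
        centres[i, , drop = FALSE])
      blob <- array(cpp_paint_capsules(shp, sp, paths,
                                       rep(leak_radius_um, n_leak_blobs)), shp)
      leak <- blob & !ec
    }
    dx <- pf | leak

    hypo <- make_hypoxia_field(voxel_grid(pf, sp, "perfusion"),
                               hypoxia_decay_um, hypoxia_max)

    render <- function(m, name) {
      f <- if (psf_sigma_um > 0)
        gaussian_smooth_um(m + 0, psf_sigma_um, sp) else m + 0
      i <- f * amplitude + background
      if (noise_sd > 0) i <- i + rnorm(length(i), 0, noise_sd)
      voxel_grid(array(round(pmin(pmax(i, 0), 4095)), shp), sp, name)
    }
    render_field <- function(vals, name) {
      i <- vals + background
      if (noise_sd > 0) i <- i + rnorm(length(i), 0, noise_sd)
      voxel_grid(array(round(pmin(pmax(i, 0), 4095)), shp), sp, name)
    }

    channels <- list(
      endothelium = render(ec, "endothelium"),
      basement_membrane = render(bm, "basement_membrane"),
      nuclei = render(vg_values(nuc$grid), "nuclei"),
      perfusion = render(pf, "perfusion"),
      dextran = render(dx, "dextran"),
      hypoxia = render_field(hypo$values, "hypoxia"))

    masks <- list(
      endothelium = voxel_grid(ec, sp, "endothelium"),
      basement_membrane = voxel_grid(bm, sp, "basement_membrane"),
      perfusion = voxel_grid(pf, sp, "perfusion"),
      nuclei = nuc$grid,
      dextran = voxel_grid(dx, sp, "dextran"),
      leak = voxel_grid(leak, sp, "leak"))

    structure(list(channels = channels, masks = masks, truth = graph,
                   nuclei_truth = nuc$points, seed = seed,
                   params = list(voxel_size_um = sp,
                                 psf_sigma_um = psf_sigma_um,
                                 noise_sd = noise_sd, background = background,
                                 amplitude = amplitude, bm_wall_um = bm_wall_um,
                                 nuclei_density_per_um = nuclei_density_per_um,
                                 nucleus_radius_um = nucleus_radius_um,
                                 hypoxia_decay_um = hypoxia_decay_um,
                                 hypoxia_max = hypoxia_max,
                                 n_leak_blobs = n_leak_blobs,
                                 leak_radius_um = leak_radius_um)),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  d <- dim(vg_values(x$channels[[1]]))
  cat(sprintf("<synthetic_dataset> %d channels, %d x %d x %d voxels, seed %d\n",
              length(x$channels), d[1], d[2], d[3], x$seed))
  print(x$truth)
  invisible(x)
}
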