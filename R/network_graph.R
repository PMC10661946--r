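#' Skeletonize a binary vessel mask
#'
#' Reduces the mask to a unit-width, 26-connected curve skeleton by
#' distance-ordered homotopic thinning: border voxels are deleted in order of
#' increasing distance to the background, but only while they are simple
#' points (deletion preserves the topology of both foreground and
#' background) and not curve endpoints. The number of connected components
#' is therefore preserved exactly.
#'
#' @param mask a binary `voxel_grid`.
#' @return a binary `voxel_grid` holding the skeleton.
#' @export
skeletonize_mask <- function(mask) {
  v <- vg_mask(mask)
  sp <- vg_spacing(mask)
  sk <- cpp_skeletonize(as.logical(v), dim(v), sp)
  voxel_grid(array(sk, dim(v)), sp, "skeleton")
}

# 26-neighbourhood offsets as a 26 x 3 integer matrix.
offsets26 <- function() {
  g <- as.matrix(expand.grid(o1 = -1:1, o2 = -1:1, o3 = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# Adjacency (as a list of integer vectors) among the skeleton voxels whose
# sorted linear indices are `idx` in a volume of dimension `d`.
skeleton_adjacency <- function(idx, coords, d) {
  n <- length(idx)
  offs <- offsets26()
  pi_ <- integer(0); pj_ <- integer(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    ok <- coords[, 1] + o[1] >= 1L & coords[, 1] + o[1] <= d[1] &
          coords[, 2] + o[2] >= 1L & coords[, 2] + o[2] <= d[2] &
          coords[, 3] + o[3] >= 1L & coords[, 3] + o[3] <= d[3]
    ni <- which(ok)
    if (!length(ni)) next
    nl <- idx[ni] + o[1] + d[1] * (o[2] + d[2] * o[3])
    m <- match(nl, idx)
    hit <- which(!is.na(m))
    pi_ <- c(pi_, ni[hit]); pj_ <- c(pj_, m[hit])
  }
  unname(split(pj_, factor(pi_, levels = seq_len(n))))
}

# Core graph extraction from a set of skeleton voxels. `depth` gives the
# interior depth (um) of the underlying mask at each voxel of `idx`.
# Sliding-mean smoothing of a polyline (endpoints fixed): suppresses the
# digital staircase so path lengths and tortuosities are not inflated by
# voxelization.
smooth_polyline <- function(pu, window = 5L) {
  n <- nrow(pu)
  if (n <= 2L || window <= 1L) return(pu)
  h <- window %/% 2L
  out <- pu
  for (i in 2:(n - 1L)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    out[i, ] <- colMeans(pu[lo:hi, , drop = FALSE])
  }
  out
}

graph_from_voxels <- function(idx, d, sp, depth, smooth_window = 5L) {
  n <- length(idx)
  empty_nodes <- data.frame(id = integer(0), z = numeric(0), y = numeric(0),
                            x = numeric(0), degree = integer(0))
  empty_segs <- data.frame(id = integer(0), from = integer(0), to = integer(0),
                           n_voxels = integer(0), length_um = numeric(0),
                           chord_um = numeric(0), tortuosity = numeric(0),
                           mean_diameter_um = numeric(0), is_loop = logical(0))
  if (n == 0L)
    return(structure(list(nodes = empty_nodes, segments = empty_segs,
                          paths = list(), total_skeleton_length_um = 0,
                          dim = d, voxel_size_um = sp,
                          skeleton_idx = idx, depth = depth,
                          smooth_window = smooth_window),
                     class = "vessel_graph"))

  coords <- arrayInd(idx, d)
  adj <- skeleton_adjacency(idx, coords, d)
  nnb <- lengths(adj)

  junction <- nnb >= 3L
  nodevox <- junction | nnb <= 1L

  # single-linkage clustering of 26-adjacent junction voxels into one node
  node_id <- integer(n)
  nid <- 0L
  for (v in which(junction)) {
    if (node_id[v]) next
    nid <- nid + 1L
    stack <- v; node_id[v] <- nid
    while (length(stack)) {
      u <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      for (w in adj[[u]]) if (junction[w] && !node_id[w]) {
        node_id[w] <- nid; stack <- c(stack, w)
      }
    }
  }
  for (v in which(nnb <= 1L)) { nid <- nid + 1L; node_id[v] <- nid }

  paths <- list()
  seg_from <- integer(0); seg_to <- integer(0)
  visited <- logical(n)
  cluster_edges <- character(0)

  walk <- function(v, w) {
    start_cluster <- node_id[v]
    path <- c(v, w)
    visited[w] <<- TRUE
    prev <- v; cur <- w; first <- TRUE
    repeat {
      nxt <- adj[[cur]]
      nxt <- nxt[nxt != prev]
      if (!length(nxt)) break
      nodenb <- nxt[nodevox[nxt]]
      if (first) {
        # the first chain voxel often touches several voxels of the start
        # junction clump diagonally; do not close a degenerate self-loop
        # when the path can continue elsewhere
        other <- nodenb[node_id[nodenb] != start_cluster]
        chain <- nxt[!nodevox[nxt] & !visited[nxt]]
        if (length(other)) { path <- c(path, other[1]); break }
        if (length(chain)) {
          visited[chain[1]] <<- TRUE
          path <- c(path, chain[1])
          prev <- cur; cur <- chain[1]; first <- FALSE
          next
        }
        if (length(nodenb)) { path <- c(path, nodenb[1]) }
        break
      }
      if (length(nodenb)) { path <- c(path, nodenb[1]); break }
      nxt <- nxt[!visited[nxt]]
      if (!length(nxt)) break
      visited[nxt[1]] <<- TRUE
      path <- c(path, nxt[1])
      prev <- cur; cur <- nxt[1]
    }
    path
  }

  for (v in which(nodevox)) {
    for (w in adj[[v]]) {
      if (nodevox[w]) {
        a <- node_id[v]; b <- node_id[w]
        if (a == b) next
        key <- paste(min(a, b), max(a, b))
        if (key %in% cluster_edges) next
        cluster_edges <- c(cluster_edges, key)
        paths[[length(paths) + 1L]] <- c(v, w)
        seg_from <- c(seg_from, a); seg_to <- c(seg_to, b)
      } else {
        if (visited[w]) next
        path <- walk(v, w)
        last <- path[length(path)]
        if (!nodevox[last]) {
          # dead-ended on consumed chain voxels: promote the last voxel
          nid <- nid + 1L
          node_id[last] <- nid
          nodevox[last] <- TRUE
        }
        paths[[length(paths) + 1L]] <- path
        seg_from <- c(seg_from, node_id[v]); seg_to <- c(seg_to, node_id[last])
      }
    }
  }

  # pure cycles with no junction or endpoint: anchor a node anywhere on them
  for (v in seq_len(n)) {
    if (nodevox[v] || visited[v] || nnb[v] != 2L) next
    nid <- nid + 1L
    node_id[v] <- nid
    nodevox[v] <- TRUE
    visited[v] <- TRUE
    path <- walk(v, adj[[v]][1])
    if (path[length(path)] != v) path <- c(path, v) # close the loop
    paths[[length(paths) + 1L]] <- path
    seg_from <- c(seg_from, nid); seg_to <- c(seg_to, nid)
  }

  # node table: positions are cluster centroids in um
  used <- which(node_id > 0L)
  ids <- sort(unique(node_id[used]))
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
  node_pos <- matrix(0, length(ids), 3)
  for (k in seq_along(ids)) {
    members <- which(node_id == ids[k])
    node_pos[k, ] <- colMeans(voxel_to_um(coords[members, , drop = FALSE], sp))
  }
  seg_from <- remap[seg_from]; seg_to <- remap[seg_to]

  ns <- length(paths)
  length_um <- chord_um <- tort <- diam <- numeric(ns)
  is_loop <- logical(ns)
  for (s in seq_len(ns)) {
    p <- paths[[s]]
    pu <- smooth_polyline(voxel_to_um(coords[p, , drop = FALSE], sp),
                          smooth_window)
    steps <- sqrt(rowSums(diff(pu)^2))
    length_um[s] <- sum(steps)
    ch <- sqrt(sum((pu[1, ] - pu[nrow(pu), ])^2))
    is_loop[s] <- seg_from[s] == seg_to[s]
    if (ch < 1e-9) ch <- min(sp) # self-loop convention
    chord_um[s] <- ch
    tort[s] <- length_um[s] / ch
    diam[s] <- 2 * mean(depth[p])
  }

  degree <- tabulate(c(seg_from, seg_to), nbins = length(ids))
  nodes <- data.frame(id = seq_along(ids),
                      z = node_pos[, 1], y = node_pos[, 2], x = node_pos[, 3],
                      degree = as.integer(degree))
  segments <- if (ns > 0)
    data.frame(id = seq_len(ns), from = seg_from, to = seg_to,
               n_voxels = lengths(paths), length_um = length_um,
               chord_um = chord_um, tortuosity = tort,
               mean_diameter_um = diam, is_loop = is_loop)
  else empty_segs

  structure(list(nodes = nodes, segments = segments,
                 paths = lapply(paths, function(p) idx[p]),
                 total_skeleton_length_um = sum(length_um),
                 dim = d, voxel_size_um = sp,
                 skeleton_idx = idx, depth = depth,
                 smooth_window = smooth_window),
            class = "vessel_graph")
}

#' Extract the vascular graph from a skeleton
#'
#' Clusters 26-adjacent junction voxels (3 or more skeleton neighbours) into
#' single branching nodes (single linkage, centroid position), takes
#' endpoint voxels as degree-1 nodes, and traces the simple voxel paths
#' between nodes as segments. Per segment it reports the path length (um,
#' anisotropy-aware), the endpoint chord, tortuosity = length / chord, and
#' the mean diameter, estimated as twice the mean euclidean distance
#' transform of the mask sampled along the path.
#'
#' @param skeleton skeleton `voxel_grid` from [skeletonize_mask()].
#' @param mask the binary mask the skeleton was derived from.
#' @return a `vessel_graph` with `nodes`, `segments`, `paths` (voxel linear
#'   indices), and `total_skeleton_length_um`.
#' @export
build_graph <- function(skeleton, mask, smooth_window = 5L) {
  sk <- vg_mask(skeleton)
  m <- vg_mask(mask)
  check_same_geometry(sk, m, "skeleton and mask")
  if (any(sk & !m))
    stop("consistency error: skeleton voxel outside the mask")
  sp <- vg_spacing(skeleton, vg_spacing(mask))
  idx <- which(sk)
  depth_arr <- interior_depth_um(mask)
  graph_from_voxels(idx, dim(sk), sp, depth_arr[idx], smooth_window)
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %d nodes, %d segments, %.1f um total skeleton length\n",
              nrow(x$nodes), nrow(x$segments), x$total_skeleton_length_um))
  invisible(x)
}

#' Remove short terminal spurs from a vascular graph
#'
#' Iteratively deletes terminal segments (one endpoint of degree 1, the
#' other of degree >= 3) shorter than `min_length_um` -- the classic
#' skeletonization artifact on bumpy tube surfaces -- then re-extracts the
#' graph from the surviving skeleton voxels, which merges any node left with
#' degree 2 back into a single through-segment. Idempotent at the fixpoint.
#' The default threshold of 4 um is about one capillary radius.
#'
#' @param graph a `vessel_graph`.
#' @param min_length_um spur length threshold (um).
#' @return the pruned `vessel_graph`.
#' @export
prune_spurs <- function(graph, min_length_um = 4) {
  stopifnot(inherits(graph, "vessel_graph"), min_length_um >= 0)
  if (min_length_um == 0) return(graph)
  repeat {
    segs <- graph$segments
    if (!nrow(segs)) return(graph)
    degv <- graph$nodes$degree
    spur <- which(!segs$is_loop & segs$length_um < min_length_um &
                  ((degv[segs$from] == 1L & degv[segs$to] >= 3L) |
                   (degv[segs$to] == 1L & degv[segs$from] >= 3L)))
    if (!length(spur)) return(graph)
    depth_lookup <- graph$depth
    names(depth_lookup) <- as.character(graph$skeleton_idx)
    drop_vox <- integer(0)
    for (s in spur) {
      p <- graph$paths[[s]]
      # keep the voxel(s) belonging to the branching-node end
      keep_end <- if (degv[segs$from[s]] >= 3L) 1L else length(p)
      drop_vox <- c(drop_vox, p[-keep_end])
    }
    # voxels shared between two spurs at a junction must survive if kept once
    keep_idx <- setdiff(graph$skeleton_idx, drop_vox)
    graph <- graph_from_voxels(sort(keep_idx), graph$dim, graph$voxel_size_um,
                               unname(depth_lookup[as.character(sort(keep_idx))]),
                               graph$smooth_window)
  }
}

#' Angio-architecture summary metrics of a vascular graph
#'
#' @param graph a `vessel_graph`.
#' @param mask binary vessel mask used for the volume density (optional).
#' @param tissue_mask tissue mask; `NULL` = whole volume.
#' @param nuclei_count number of endothelial nuclei counted in the same
#'   volume, for the cells-per-vascular-length ratio.
#' @param diameter_breaks bin edges (um) of the diameter histogram; the
#'   default includes the 5-8 um capillary bin.
#' @return a `network_metrics` list: segment/node counts (bifurcations are
#'   degree-3 branching nodes, trifurcations degree-4), vascular volume
#'   density, mean diameter and tortuosity, the diameter histogram, and
#'   endothelial cells per um of vascular length.
#' @export
compute_metrics <- function(graph, mask = NULL, tissue_mask = NULL,
                            nuclei_count = 0,
                            diameter_breaks = c(0, 3, 5, 8, 12, Inf)) {
  stopifnot(inherits(graph, "vessel_graph"), nuclei_count >= 0)
  deg <- graph$nodes$degree
  vvd <- if (!is.null(mask)) vascular_volume_density(mask, tissue_mask) else NA_real_
  tl <- graph$total_skeleton_length_um
  if (tl == 0 && nuclei_count > 0)
    stop("undefined ratio: zero skeleton length with a positive nucleus count")
  ecl <- if (tl > 0) nuclei_count / tl else NA_real_
  dd <- graph$segments$mean_diameter_um
  hh <- if (length(dd))
    table(cut(dd, breaks = diameter_breaks, right = FALSE,
              include.lowest = TRUE))
  else table(cut(numeric(0), breaks = diameter_breaks, right = FALSE))
  structure(list(
    n_segments = nrow(graph$segments),
    n_branching_nodes = sum(deg >= 3L),
    n_bifurcations = sum(deg == 3L),
    n_trifurcations = sum(deg == 4L),
    n_end_nodes = sum(deg == 1L),
    vascular_volume_density = vvd,
    mean_diameter_um = if (length(dd)) mean(dd) else NA_real_,
    diameter_histogram = hh,
    mean_tortuosity = if (length(dd)) mean(graph$segments$tortuosity) else NA_real_,
    ec_per_vascular_length = ecl,
    total_skeleton_length_um = tl), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf("<network_metrics> %d segments, %d bifurcations, %d trifurcations, %d end nodes\n",
              x$n_segments, x$n_bifurcations, x$n_trifurcations, x$n_end_nodes))
  cat(sprintf("  vascular volume density %.4f | mean diameter %.2f um | mean tortuosity %.3f\n",
              x$vascular_volume_density, x$mean_diameter_um, x$mean_tortuosity))
  cat(sprintf("  total skeleton length %.1f um | EC per um %.4f\n",
              x$total_skeleton_length_um, x$ec_per_vascular_length))
  invisible(x)
}

#' @export
as.data.frame.network_metrics <- function(x, ...) {
  data.frame(n_segments = x$n_segments,
             n_branching_nodes = x$n_branching_nodes,
             n_bifurcations = x$n_bifurcations,
             n_trifurcations = x$n_trifurcations,
             n_end_nodes = x$n_end_nodes,
             vascular_volume_density = x$vascular_volume_density,
             mean_diameter_um = x$mean_diameter_um,
             mean_tortuosity = x$mean_tortuosity,
             ec_per_vascular_length = x$ec_per_vascular_length,
             total_skeleton_length_um = x$total_skeleton_length_um)
}

#' Merge branching nodes connected by very short segments
#'
#' A single anatomical junction can resolve into two nearby skeleton
#' junction clumps joined by a segment of a voxel or two (typically when
#' four or more tubes meet). This contracts every non-loop segment shorter
#' than `max_dist_um` whose two endpoints are both branching nodes, merging
#' the endpoints into one node (length-weighted centroid) whose degree is
#' the sum of the surviving incidences -- so two merged bifurcations become
#' one trifurcation.
#'
#' Self-loops shorter than `max_dist_um` are dropped as digitization
#' artifacts as well: the voxelized union of tubes meeting at a junction can
#' enclose a one-voxel tunnel that homotopic thinning faithfully preserves
#' as a tiny cycle.
#'
#' @param graph a `vessel_graph`.
#' @param max_dist_um segments between branching nodes shorter than this
#'   are treated as part of the junction. About one vessel diameter is a
#'   sensible choice.
#' @return the contracted `vessel_graph`.
#' @export
merge_close_junctions <- function(graph, max_dist_um = 3) {
  stopifnot(inherits(graph, "vessel_graph"))
  # drop short self-loops first: junction-scale digitization tunnels
  short_loop <- which(graph$segments$is_loop &
                      graph$segments$length_um < max_dist_um)
  if (length(short_loop)) {
    graph$segments <- graph$segments[-short_loop, , drop = FALSE]
    graph$paths <- graph$paths[-short_loop]
    if (nrow(graph$segments)) graph$segments$id <- seq_len(nrow(graph$segments))
    graph$nodes$degree <- tabulate(c(graph$segments$from, graph$segments$to),
                                   nbins = nrow(graph$nodes))
    graph$total_skeleton_length_um <- sum(graph$segments$length_um)
  }
  repeat {
    segs <- graph$segments
    if (!nrow(segs)) return(graph)
    deg <- graph$nodes$degree
    cand <- which(!segs$is_loop & segs$from != segs$to &
                  segs$length_um < max_dist_um &
                  deg[segs$from] >= 3L & deg[segs$to] >= 3L)
    if (!length(cand)) return(graph)
    s <- cand[which.min(segs$length_um[cand])]
    a <- segs$from[s]; b <- segs$to[s]
    nodes <- graph$nodes
    nodes[a, c("z", "y", "x")] <-
      (nodes[a, c("z", "y", "x")] + nodes[b, c("z", "y", "x")]) / 2
    segs <- segs[-s, , drop = FALSE]
    graph$paths <- graph$paths[-s]
    segs$from[segs$from == b] <- a
    segs$to[segs$to == b] <- a
    segs$is_loop <- segs$from == segs$to
    # drop node b, renumber
    keep <- setdiff(seq_len(nrow(nodes)), b)
    remap <- integer(nrow(nodes)); remap[keep] <- seq_along(keep)
    nodes <- nodes[keep, , drop = FALSE]
    segs$from <- remap[segs$from]; segs$to <- remap[segs$to]
    nodes$id <- seq_len(nrow(nodes))
    nodes$degree <- tabulate(c(segs$from, segs$to), nbins = nrow(nodes))
    if (nrow(segs)) segs$id <- seq_len(nrow(segs))
    rownames(nodes) <- rownames(segs) <- NULL
    graph$nodes <- nodes
    graph$segments <- segs
    graph$total_skeleton_length_um <- sum(segs$length_um)
  }
}
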