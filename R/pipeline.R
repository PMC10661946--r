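#' Quantify one volume of interest end to end
#'
#' Convenience wrapper running the full analysis on a (synthetic or loaded)
#' multi-channel dataset: segments the endothelium and basement-membrane
#' channels, skeletonizes the endothelial mask, extracts and spur-prunes the
#' vascular graph, computes the angio-architecture metrics, and detects
#' empty-sleeve pruning events.
#'
#' @param ds a `synthetic_dataset` (or any list with the same `channels`
#'   layout).
#' @param seg_params segmentation parameters for the structural channels.
#'   The default (single 1 um scale, 3 Otsu classes, top class kept) gives
#'   tight tube masks on brightly stained vasculature; the wider multi-scale
#'   default of [segmentation_params()] is better suited to stains with
#'   graded intensity.
#' @param sleeve_par sleeve-detection parameters, see [sleeve_params()].
#' @param spur_min_um spur-pruning threshold passed to [prune_spurs()].
#' @param junction_merge_um threshold passed to [merge_close_junctions()].
#' @param nuclei_count endothelial nucleus count; defaults to the dataset's
#'   ground-truth count when present.
#' @return list with `ec_mask`, `bm_mask`, `graph`, `metrics`, `sleeves`,
#'   `n_pruning_events`, `pruning_percent`.
#' @export
quantify_voi <- function(ds,
                         seg_params = segmentation_params(scales_um = 1,
                                                          n_levels = 3),
                         sleeve_par = sleeve_params(), spur_min_um = 4,
                         junction_merge_um = 5, nuclei_count = NULL) {
  ec_mask <- multiscale_multilevel_segment(ds$channels$endothelium, seg_params)
  bm_mask <- multiscale_multilevel_segment(ds$channels$basement_membrane,
                                           seg_params)
  sk <- skeletonize_mask(ec_mask)
  graph <- merge_close_junctions(
    prune_spurs(build_graph(sk, ec_mask), spur_min_um), junction_merge_um)
  if (is.null(nuclei_count))
    nuclei_count <- if (!is.null(ds$nuclei_truth)) nrow(ds$nuclei_truth) else 0L
  metrics <- compute_metrics(graph, mask = ec_mask,
                             nuclei_count = nuclei_count)
  sleeves <- detect_empty_sleeves(bm_mask, ec_mask, sleeve_par)
  n_ev <- nrow(sleeves)
  list(ec_mask = ec_mask, bm_mask = bm_mask, graph = graph,
       metrics = metrics, sleeves = sleeves, n_pruning_events = n_ev,
       pruning_percent = if (metrics$n_segments > 0)
         pruning_segment_ratio(n_ev, metrics$n_segments) else NA_real_)
}
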