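#' Build TF-to-peak bipartite links from motif hits
#'
#' Collapses motif occurrences into one edge per (TF, peak) pair. By
#' default edges are binary (weight 1): log-odds scales depend on motif
#' width, and score-weighting would distort the competition between TFs in
#' the walk. `mode = "score"` instead uses the maximum hit score.
#' Hits naming TFs or peaks absent from the supplied layers are dropped
#' with a warning stating how many.
#'
#' @param hits Tibble as returned by [scan_motifs()] (needs columns `tf`,
#'   `seq`, and `score` for score mode), or read from a precomputed TSV.
#' @param tf_layer,peak_layer The two layers the links join.
#' @param mode `"binary"` (default) or `"score"`.
#' @return An [bipartite_links()] from the TF layer to the peak layer.
#' @export
link_tf_peaks <- function(hits, tf_layer, peak_layer,
                          mode = c("binary", "score")) {
  mode <- match.arg(mode)
  stopifnot(is(tf_layer, "scrw_layer"), is(peak_layer, "scrw_layer"))
  stopifnot(all(c("tf", "seq") %in% names(hits)))
  ok <- hits$tf %in% tf_layer$nodes & hits$seq %in% peak_layer$nodes
  if (any(!ok)) {
    warn(sprintf("link_tf_peaks: dropping %d hit(s) with unmappable TF or peak",
                 sum(!ok)))
  }
  hits <- hits[ok, , drop = FALSE]
  edges <- if (mode == "binary") {
    distinct(tibble(from = hits$tf, to = hits$seq, weight = 1))
  } else {
    summarise(group_by(tibble(from = hits$tf, to = hits$seq,
                              score = hits$score),
                       .data$from, .data$to),
              weight = max(.data$score), .groups = "drop")
  }
  bipartite_links(tf_layer$name, peak_layer$name, edges)
}

# distance between interval [s, e) and point t, both 0-based
interval_point_dist <- function(s, e, t) {
  ifelse(s <= t & t < e, 0L, pmin(abs(t - s), abs(t - (e - 1L))))
}

#' Link two genomic feature sets by proximity
#'
#' Creates a unit-weight link between an `a` feature and a `b` feature when
#' they sit on the same chromosome within `window` bp of each other. With
#' `anchor = "tss"` the `b` features are reduced to their transcription
#' start site (interval start for `+`/`.` strand, `end - 1` for `-`) and
#' the distance is interval-to-point; with `anchor = "body"` the distance
#' is interval-to-interval (0 when they overlap). Distances follow the
#' BED half-open convention: a peak `[100,150)` lies 1 bp from a TSS at
#' 150.
#'
#' The default 100 kb window keeps the bipartite itself local (promoter and
#' nearby enhancers); more distal regulatory regions are still reachable by
#' the walk through peak--peak co-accessibility edges.
#'
#' @param a,b Feature sets ([feature_set()] tibbles). For gene TSS
#'   anchoring, build `b` with [gene_features()].
#' @param window Maximum distance in bp (>= 0).
#' @param anchor `"tss"` or `"body"`.
#' @return Tibble `from` (a id), `to` (b id), `weight` (1), `distance`.
#'   Pass to [bipartite_links()] to install in a multilayer.
#' @export
link_by_proximity <- function(a, b, window = 1e5, anchor = c("tss", "body")) {
  anchor <- match.arg(anchor)
  stopifnot(window >= 0)
  a <- validate_features(a)
  b <- validate_features(b)
  pairs <- inner_join(
    select(a, a_id = "id", "chrom", a_start = "start", a_end = "end"),
    select(b, b_id = "id", "chrom", b_start = "start", b_end = "end",
           b_strand = "strand"),
    by = "chrom", relationship = "many-to-many")
  if (nrow(pairs) == 0) {
    return(tibble(from = character(), to = character(), weight = double(),
                  distance = integer()))
  }
  d <- if (anchor == "tss") {
    t <- ifelse(pairs$b_strand == "-", pairs$b_end - 1L, pairs$b_start)
    interval_point_dist(pairs$a_start, pairs$a_end, t)
  } else {
    overlap <- pairs$a_start < pairs$b_end & pairs$b_start < pairs$a_end
    gap <- pmin(abs(pairs$b_start - (pairs$a_end - 1L)),
                abs(pairs$a_start - (pairs$b_end - 1L)))
    ifelse(overlap, 0L, gap)
  }
  keep <- d <= window
  out <- tibble(from = pairs$a_id[keep], to = pairs$b_id[keep],
                weight = 1, distance = as.integer(d[keep]))
  arrange(out, .data$from, .data$to)
}
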