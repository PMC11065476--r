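#' Mean overlap between per-TF rankings and a ground truth, at cutoffs
#'
#' For each ranking cutoff `k`, computes the number of ground-truth targets
#' found in each TF's top `k` predictions, averaged over the TFs that have a
#' non-empty ground truth (TFs without one are excluded, not counted as
#' zero). The default cutoffs span the head of the ranking
#' (3--100), where predictions are actionable.
#'
#' @param ranking An `scrw_ranking` (e.g. from [tf_targets()]) or any
#'   tibble whose first column is the seed (TF), with columns `rank` and a
#'   node column.
#' @param truth Tibble with the same seed column and a node column: the
#'   known associations.
#' @param cutoffs Increasing positive integer cutoffs.
#' @return Tibble `cutoff`, `mean_overlap`, `n_seeds`.
#' @export
overlap_at_cutoffs <- function(ranking, truth,
                               cutoffs = c(3, 5, 10, 15, 20, 30, 40, 50, 75, 100)) {
  stopifnot(all(cutoffs > 0), !is.unsorted(cutoffs, strictly = TRUE))
  cols <- ranking_cols(ranking, truth)
  shared <- intersect(unique(ranking[[cols$seed]]),
                      unique(truth[[cols$truth_seed]]))
  if (length(shared) == 0) abort("overlap_at_cutoffs: no seeds shared between ranking and ground truth")
  hits <- inner_join(
    tibble(seed = ranking[[cols$seed]], node = ranking[[cols$node]],
           rank = ranking$rank),
    tibble(seed = truth[[cols$truth_seed]], node = truth[[cols$truth_node]]),
    by = c("seed", "node"))
  map_dfr(cutoffs, function(k) {
    per_seed <- vapply(shared, function(s)
      sum(hits$seed == s & hits$rank <= k), 0)
    tibble(cutoff = k, mean_overlap = mean(per_seed),
           n_seeds = length(shared))
  })
}

ranking_cols <- function(ranking, truth) {
  seed_col <- attr(ranking, "seed_col") %||% names(ranking)[1]
  node_col <- attr(ranking, "node_col") %||% names(ranking)[2]
  if (!seed_col %in% names(truth) || !node_col %in% names(truth)) {
    # fall back to positional matching of the truth table
    return(list(seed = seed_col, node = node_col,
                truth_seed = names(truth)[1], truth_node = names(truth)[2]))
  }
  list(seed = seed_col, node = node_col,
       truth_seed = seed_col, truth_node = node_col)
}

#' One-sided Fisher enrichment of ground-truth targets in top-k predictions
#'
#' For every seed (TF), the top `k` predictions are tested for enrichment
#' in ground-truth targets against the universe of ranked nodes, with the
#' one-sided Fisher exact test on the 2x2 table (in top-k and true, in
#' top-k only, true only, neither). One-sided because the claim being
#' tested -- a significant amount of correctly predicted targets -- is
#' directional. Seeds with an empty ground truth (within the universe) are
#' excluded.
#'
#' `fisher_significant_tfs()` returns the number of seeds with `p < alpha`;
#' `rank_enrichment()` returns the full per-seed table for inspection.
#'
#' @inheritParams overlap_at_cutoffs
#' @param k Ranking cutoff.
#' @param alpha Significance level (default 0.05).
#' @param universe Optional character vector overriding the universe
#'   (default: the nodes ranked for each seed).
#' @return `rank_enrichment()`: tibble `seed`, `n_top`, `n_truth`,
#'   `n_universe`, `overlap`, `p`. `fisher_significant_tfs()`: integer
#'   count.
#' @export
rank_enrichment <- function(ranking, truth, k, universe = NULL) {
  stopifnot(k >= 1)
  cols <- ranking_cols(ranking, truth)
  rk <- tibble(seed = ranking[[cols$seed]], node = ranking[[cols$node]],
               rank = ranking$rank)
  tr <- tibble(seed = truth[[cols$truth_seed]], node = truth[[cols$truth_node]])
  map_dfr(c_sort(unique(rk$seed)), function(s) {
    ranked <- rk[rk$seed == s, , drop = FALSE]
    uni <- universe %||% ranked$node
    gt <- intersect(tr$node[tr$seed == s], uni)
    if (length(gt) == 0) return(NULL)
    top <- intersect(ranked$node[ranked$rank <= k], uni)
    a <- length(intersect(top, gt))
    p <- phyper(a - 1, length(gt), length(uni) - length(gt), length(top),
                lower.tail = FALSE)
    tibble(seed = s, n_top = length(top), n_truth = length(gt),
           n_universe = length(uni), overlap = a, p = p)
  })
}

#' @rdname rank_enrichment
#' @export
fisher_significant_tfs <- function(ranking, truth, k, alpha = 0.05,
                                   universe = NULL) {
  enr <- rank_enrichment(ranking, truth, k, universe = universe)
  if (nrow(enr) == 0) abort("fisher_significant_tfs: no seeds with non-empty ground truth")
  sum(enr$p < alpha)
}

#' F1 score between predicted and true sets
#'
#' For plain id sets, `F1 = 2TP / (2TP + FP + FN)` with exact membership.
#' For genomic region sets (feature tibbles with `chrom`, `start`, `end`),
#' predicted and true regions are matched by interval overlap of at least
#' `min_overlap` bp: a predicted region overlapping any true region is a
#' true positive, a true region overlapped by no prediction is a false
#' negative. Returns 0 when both precision and recall are 0.
#'
#' @param predicted,truth Character vectors, or feature tibbles with
#'   `chrom`, `start`, `end` columns for region matching.
#' @param min_overlap Minimum overlap in bp for two regions to match
#'   (region mode only).
#' @return F1 score in \[0, 1\].
#' @export
f1_sets <- function(predicted, truth, min_overlap = 1L) {
  if (is.data.frame(predicted) && all(c("chrom", "start", "end") %in%
                                      names(predicted))) {
    gr <- function(x) GenomicRanges::GRanges(
      x$chrom, IRanges::IRanges(x$start + 1L, x$end))  # BED -> 1-based closed
    if (nrow(predicted) == 0 && nrow(truth) == 0) return(0)
    if (nrow(predicted) == 0 || nrow(truth) == 0) return(0)
    gp <- gr(predicted); gt <- gr(truth)
    ov <- GenomicRanges::countOverlaps(gp, gt, minoverlap = min_overlap)
    tp <- sum(ov > 0)
    fp <- sum(ov == 0)
    fn <- sum(GenomicRanges::countOverlaps(gt, gp,
                                           minoverlap = min_overlap) == 0)
  } else {
    predicted <- unique(as.character(predicted))
    truth <- unique(as.character(truth))
    tp <- length(intersect(predicted, truth))
    fp <- length(setdiff(predicted, truth))
    fn <- length(setdiff(truth, predicted))
  }
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Gene-set enrichment of communities
#'
#' Tests every (community, gene set) pair with the hypergeometric tail over
#' a stated gene universe, corrects with Benjamini-Hochberg per collection
#' (across all pairs in that collection), and reports the percentage and
#' count of communities enriched in at least one set at `alpha`.
#'
#' @param partition A single-resolution `scrw_partition` (see
#'   [select_resolution()]) or tibble with `node`, `community`.
#' @param collections Named list of collections, each a named list of gene
#'   sets (as from [read_gmt()]); a bare list of gene sets is treated as
#'   one collection.
#' @param universe Character vector of genes defining the testable
#'   universe; defaults to the partition's nodes. Community members outside
#'   the universe are ignored.
#' @param alpha Adjusted-p significance level.
#' @param method Multiple-testing correction (see [stats::p.adjust()]).
#' @return List with `summary` (tibble `collection`, `n_communities`,
#'   `n_enriched`, `pct_enriched`) and `tests` (per-pair tibble with raw
#'   and adjusted p).
#' @export
enrich_communities <- function(partition, collections, universe = NULL,
                               alpha = 0.05, method = "BH") {
  stopifnot(all(c("node", "community") %in% names(partition)))
  if ("resolution" %in% names(partition) &&
      dplyr::n_distinct(partition$resolution) > 1) {
    abort("enrich_communities: pass a single-resolution partition (see select_resolution())")
  }
  if (!is.list(collections[[1]])) collections <- list(sets = collections)
  if (any(lengths(collections) == 0)) abort("enrich_communities: empty collection")
  universe <- universe %||% unique(partition$node)
  comms <- split(partition$node, partition$community)
  comms <- lapply(comms, intersect, y = universe)

  tests <- map_dfr(names(collections), function(cn) {
    map_dfr(names(collections[[cn]]), function(sn) {
      set <- intersect(collections[[cn]][[sn]], universe)
      m_set <- length(set)
      map_dfr(names(comms), function(cm) {
        q <- length(intersect(comms[[cm]], set))
        k_comm <- length(comms[[cm]])
        tibble(collection = cn, set = sn, community = cm,
               overlap = q, community_size = k_comm, set_size = m_set,
               p = phyper(q - 1, m_set, length(universe) - m_set, k_comm,
                          lower.tail = FALSE))
      })
    })
  })
  tests <- tests %>%
    group_by(.data$collection) %>%
    mutate(p_adj = p.adjust(.data$p, method = method)) %>%
    ungroup()
  summary <- tests %>%
    group_by(.data$collection, .data$community) %>%
    summarise(enriched = any(.data$p_adj < alpha), .groups = "drop") %>%
    group_by(.data$collection) %>%
    summarise(n_communities = dplyr::n(), n_enriched = sum(.data$enriched),
              pct_enriched = 100 * mean(.data$enriched), .groups = "drop")
  list(summary = summary, tests = tests)
}

#' Spearman comparison of two weighted edge lists
#'
#' Computes the Spearman correlation of edge weights over the union of the
#' two edge sets, with weight 0 substituted for an edge absent from one
#' side; ties get average ranks (the `stats::cor` default). Used to
#' quantify robustness of a reconstruction against a perturbed rebuild --
#' for GRNs via `compare_grns()`, or for a single inferred layer via
#' `compare_edge_weights()` on its edge tibble.
#'
#' @param g1,g2 `scrw_grn` objects (for `compare_grns`) or tibbles with
#'   `from`, `to`, `weight` (for `compare_edge_weights`).
#' @return Spearman correlation in \[-1, 1\].
#' @export
compare_grns <- function(g1, g2) {
  e <- function(g) tibble(from = g$tf, to = g$gene, weight = g$weight)
  compare_edge_weights(e(g1), e(g2))
}

#' @rdname compare_grns
#' @export
compare_edge_weights <- function(g1, g2) {
  stopifnot(all(c("from", "to", "weight") %in% names(g1)),
            all(c("from", "to", "weight") %in% names(g2)))
  u <- full_join(
    tibble(from = g1$from, to = g1$to, w1 = g1$weight),
    tibble(from = g2$from, to = g2$to, w2 = g2$weight),
    by = c("from", "to"))
  if (nrow(u) == 0) abort("compare_edge_weights: empty edge union")
  cor(u$w1 %na% 0, u$w2 %na% 0, method = "spearman")
}

#' Rank-based AUROC of scored predictions against binary labels
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive outscores a randomly chosen negative (ties count 1/2).
#'
#' @param score Numeric prediction scores.
#' @param label Logical (or 0/1) ground-truth labels.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(score, label) {
  label <- as.logical(label)
  stopifnot(length(score) == length(label), any(label), any(!label))
  r <- rank(score)
  (sum(r[label]) - sum(label) * (sum(label) + 1) / 2) /
    (sum(label) * sum(!label))
}

#' Precision of per-seed rankings at a cutoff
#'
#' Mean over seeds of `|top-k intersect truth| / k`. Seeds absent from the
#' ground truth are excluded.
#'
#' @inheritParams overlap_at_cutoffs
#' @param k Cutoff.
#' @return Scalar mean precision.
#' @export
precision_at <- function(ranking, truth, k) {
  ov <- overlap_at_cutoffs(ranking, truth, cutoffs = k)
  ov$mean_overlap / k
}
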