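#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_tile labs theme_minimal scale_fill_viridis_c facet_wrap
NULL

#' Plot a per-seed ranking
#'
#' Bar chart of walk scores for the top nodes of each seed's ranking.
#'
#' @param object An `scrw_ranking` (from [tf_targets()],
#'   [tf_binding_regions()] or [gene_regulatory_regions()]).
#' @param top Number of top-ranked nodes to show per seed.
#' @param seeds Optional subset of seeds to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scrw_ranking <- function(object, top = 10, seeds = NULL, ...) {
  seed_col <- attr(object, "seed_col") %||% names(object)[1]
  node_col <- attr(object, "node_col") %||% names(object)[2]
  df <- as_tibble(unclass_tbl(object))
  if (!is.null(seeds)) df <- df[df[[seed_col]] %in% seeds, ]
  df <- df[df$rank <= top, ]
  ggplot(df, aes(x = .data$rank, y = .data$score)) +
    geom_col(fill = "steelblue") +
    facet_wrap(seed_col, scales = "free_y") +
    labs(x = "rank", y = "walk score",
         title = sprintf("top %d %ss per %s", top, node_col, seed_col)) +
    theme_minimal()
}

#' Plot a gene regulatory network as a TF-by-gene weight heatmap
#'
#' @param object An `scrw_grn`.
#' @param max_genes Cap on the number of genes displayed (those with the
#'   highest total incoming weight).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scrw_grn <- function(object, max_genes = 50, ...) {
  df <- as_tibble(unclass_tbl(object))
  keep <- df %>%
    group_by(.data$gene) %>%
    summarise(tot = sum(.data$weight), .groups = "drop") %>%
    arrange(desc(.data$tot)) %>%
    head(max_genes)
  df <- df[df$gene %in% keep$gene, ]
  ggplot(df, aes(x = .data$gene, y = .data$tf, fill = .data$weight)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = "gene", y = "TF", fill = "walk score",
         title = "gene regulatory network") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot community counts and modularity across resolutions
#'
#' @param object An `scrw_partition` from [detect_communities()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scrw_partition <- function(object, ...) {
  gl <- glance(object)
  df <- pivot_longer(gl, c("n_communities", "modularity"),
                     names_to = "metric", values_to = "value")
  ggplot(df, aes(x = .data$resolution, y = .data$value)) +
    geom_line() + geom_point() +
    facet_wrap("metric", scales = "free_y") +
    labs(x = "Louvain resolution", title = "community structure vs resolution") +
    theme_minimal()
}

#' Plot mean ranking overlap against the cutoff
#'
#' Companion to [overlap_at_cutoffs()]: the benchmark curve of correctly
#' predicted targets per TF as the ranking is cut deeper.
#'
#' @param overlap Tibble from [overlap_at_cutoffs()] (optionally with an
#'   extra grouping column `method`).
#' @return A ggplot object.
#' @export
plot_overlap_curve <- function(overlap) {
  p <- ggplot(overlap, aes(x = .data$cutoff, y = .data$mean_overlap))
  if ("method" %in% names(overlap)) {
    p <- p + geom_line(aes(color = .data$method)) +
      geom_point(aes(color = .data$method))
  } else {
    p <- p + geom_line() + geom_point()
  }
  p + labs(x = "ranking cutoff", y = "mean correct predictions per TF") +
    theme_minimal()
}
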