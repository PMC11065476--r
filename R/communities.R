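#' Community detection configuration
#'
#' @param density Target GRN density handed to [filter_to_density()] before
#'   clustering (dense inferred GRNs carry no community structure). The
#'   default 0.05 keeps roughly the strongest twentieth of possible edges.
#' @param resolutions Resolution grid for Louvain, within \[0, 2\]. Lower
#'   resolutions merge, higher ones split; scanning a grid and requiring a
#'   reasonable number of communities (see `min_communities`) avoids
#'   cherry-picking a single value.
#' @param min_communities Minimum community count for a resolution to be
#'   considered interpretable (default 10); used by [select_resolution()].
#' @param seed Seed fixed before each Louvain run so partitions are
#'   byte-reproducible.
#' @return List of class `scrw_community_config`.
#' @export
community_config <- function(density = 0.05,
                             resolutions = seq(0.2, 2, by = 0.2),
                             min_communities = 10L, seed = 1L) {
  stopifnot(density > 0, density <= 1,
            all(resolutions >= 0), all(resolutions <= 2))
  structure(list(density = density, resolutions = resolutions,
                 min_communities = as.integer(min_communities),
                 seed = as.integer(seed)),
            class = "scrw_community_config")
}

#' Detect gene communities in a GRN with Louvain
#'
#' The GRN is treated as an undirected weighted graph over TF and gene
#' nodes, and Louvain modularity optimization is run once per resolution in
#' the grid with a fixed RNG seed. Tightly linked TF/gene groups frequently
#' correspond to shared pathways or biological processes, which
#' [enrich_communities()] quantifies.
#'
#' Apply [filter_to_density()] first (or pass a raw GRN and `config$density`
#' via [grn_communities()]): near-complete graphs have no modular structure.
#'
#' @param grn An `scrw_grn` (non-empty).
#' @param config An [community_config()] (only `resolutions` and `seed` are
#'   used here).
#' @return Tibble of class `scrw_partition`: `resolution`, `node`,
#'   `community` (integer ids per resolution), with per-resolution
#'   modularity in attribute `modularity`.
#' @export
detect_communities <- function(grn, config = community_config()) {
  stopifnot(inherits(grn, "scrw_grn"))
  if (nrow(grn) == 0) abort("detect_communities: empty GRN")
  g <- igraph::graph_from_data_frame(
    tibble(from = grn$tf, to = grn$gene, weight = grn$weight),
    directed = FALSE)
  parts <- map_dfr(config$resolutions, function(res) {
    cl <- withr::with_seed(config$seed,
                           igraph::cluster_louvain(g, resolution = res))
    memb <- igraph::membership(cl)
    tibble(resolution = res, node = names(memb),
           community = as.integer(memb),
           modularity = igraph::modularity(g, memb,
                                           weights = igraph::E(g)$weight,
                                           resolution = res))
  })
  structure(parts, class = c("scrw_partition", class(parts)))
}

#' Filter a GRN to target density and detect communities
#'
#' Convenience wrapper: [filter_to_density()] then [detect_communities()].
#'
#' @inheritParams detect_communities
#' @return An `scrw_partition`.
#' @export
grn_communities <- function(grn, config = community_config()) {
  detect_communities(filter_to_density(grn, config$density), config)
}

#' @export
glance.scrw_partition <- function(x, ...) {
  x %>%
    group_by(.data$resolution) %>%
    summarise(n_communities = dplyr::n_distinct(.data$community),
              n_nodes = dplyr::n(),
              modularity = .data$modularity[1], .groups = "drop")
}

#' Pick the smallest resolution with an interpretable partition
#'
#' Returns the partition at the smallest resolution yielding at least
#' `min_communities` communities (communities too few to be informative are
#' skipped); falls back to the largest resolution when none qualifies.
#'
#' @param partition An `scrw_partition`.
#' @param min_communities Minimum acceptable community count.
#' @return The single-resolution subset of `partition`.
#' @export
select_resolution <- function(partition, min_communities = 10L) {
  gl <- glance(partition)
  ok <- gl$resolution[gl$n_communities >= min_communities]
  res <- if (length(ok) > 0) min(ok) else max(gl$resolution)
  out <- partition[partition$resolution == res, , drop = FALSE]
  structure(out, class = unique(c("scrw_partition", class(out))))
}

#' Write community partitions as TSV
#'
#' @param partition An `scrw_partition`.
#' @param path Output TSV (`node`, `community`, `resolution`).
#' @return Invisibly, `path`.
#' @export
write_partition <- function(partition, path) {
  tb <- as_tibble(partition)[, c("node", "community", "resolution")]
  readr::write_tsv(tb, path)
  invisible(path)
}
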