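# seeded multi-walk helper: one RWR per seed node, shared operator
multi_seed_walk <- function(ml, seed_layer, rank_layer_name, config,
                            included = NULL) {
  cfg <- config
  cfg$included_layers <- included
  op <- build_transition(ml, cfg)
  if (!seed_layer %in% op$index$layer) {
    abort(sprintf("layer '%s' is empty or excluded", seed_layer))
  }
  if (!rank_layer_name %in% op$index$layer) {
    abort(sprintf("layer '%s' is empty or excluded", rank_layer_name))
  }
  seeds <- which(op$index$layer == seed_layer)
  if (length(seeds) == 0) abort(sprintf("layer '%s' has no nodes", seed_layer))
  n <- nrow(op$index)
  S <- Matrix::sparseMatrix(i = seeds, j = seq_along(seeds), x = 1,
                            dims = c(n, length(seeds)))
  X <- rwr_matrix(op, as.matrix(S), cfg)
  target <- which(op$index$layer == rank_layer_name)
  target_nodes <- op$index$node[target]
  out <- map_dfr(seq_along(seeds), function(j) {
    sc <- unname(X[target, j])
    keep <- target_nodes != op$index$node[seeds[j]] |
      rank_layer_name != seed_layer
    nd <- target_nodes[keep]; sc <- sc[keep]
    o <- c_order(-sc, nd)
    tibble(seed = op$index$node[seeds[j]], node = nd[o], score = sc[o],
           rank = seq_along(o))
  })
  out
}

#' Predict the targets of each transcription factor
#'
#' One random walk with restart per TF node, seeded at the TF and free to
#' explore the full multilayer down to the gene layer. The resulting
#' steady-state probability of each gene measures its regulatory closeness
#' to the TF; ranking genes within one walk makes the *genes* compete among
#' themselves for each TF, which is the right orientation for target
#' prediction (the reverse orientation, where TFs compete for each gene, is
#' [build_grn()]).
#'
#' @param ml An `scrw_multilayer` containing TF and gene layers.
#' @param config An [rwr_config()].
#' @param tf_layer,rna_layer Names of the TF and gene layers.
#' @return Tibble of class `scrw_ranking`: `tf`, `gene`, `score`, `rank`
#'   (rank within each TF, best first; ties broken lexicographically).
#' @export
tf_targets <- function(ml, config = rwr_config(), tf_layer = "TF",
                       rna_layer = "RNA") {
  out <- multi_seed_walk(ml, tf_layer, rna_layer, config)
  out <- rename(out, tf = "seed", gene = "node")
  new_ranking(out, seed_col = "tf", node_col = "gene")
}

#' Predict the peaks bound by each transcription factor
#'
#' Like [tf_targets()], but the walk is restricted to the TF and
#' accessibility layers: peak rankings then reflect motif evidence
#' propagated through peak--peak co-accessibility, without dilution through
#' the gene layer. Use [top_fraction()] to filter each ranking to its top
#' 100/80/60/20% of peaks.
#'
#' @inheritParams tf_targets
#' @param atac_layer Name of the accessibility layer.
#' @return `scrw_ranking` tibble: `tf`, `peak`, `score`, `rank`.
#' @export
tf_binding_regions <- function(ml, config = rwr_config(), tf_layer = "TF",
                               atac_layer = "ATAC") {
  out <- multi_seed_walk(ml, tf_layer, atac_layer, config,
                         included = c(tf_layer, atac_layer))
  out <- rename(out, tf = "seed", peak = "node")
  new_ranking(out, seed_col = "tf", node_col = "peak")
}

#' Predict the regulatory regions of each gene
#'
#' One walk per gene over the gene and accessibility layers only; peaks are
#' ranked by steady-state probability, recovering both proximal regions
#' (direct proximity links) and distal enhancers (reached through
#' co-accessibility edges).
#'
#' @inheritParams tf_binding_regions
#' @return `scrw_ranking` tibble: `gene`, `peak`, `score`, `rank`.
#' @export
gene_regulatory_regions <- function(ml, config = rwr_config(),
                                    rna_layer = "RNA", atac_layer = "ATAC") {
  out <- multi_seed_walk(ml, rna_layer, atac_layer, config,
                         included = c(rna_layer, atac_layer))
  out <- rename(out, gene = "seed", peak = "node")
  new_ranking(out, seed_col = "gene", node_col = "peak")
}

new_ranking <- function(x, seed_col, node_col) {
  structure(x, seed_col = seed_col, node_col = node_col,
            class = c("scrw_ranking", class(x)))
}

#' Keep the top fraction of each per-seed ranking
#'
#' @param ranking An `scrw_ranking` tibble.
#' @param fraction Fraction in (0, 1]; the top `ceiling(fraction * n)`
#'   nodes of each seed's ranking are retained.
#' @return Filtered `scrw_ranking`.
#' @export
top_fraction <- function(ranking, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  seed_col <- attr(ranking, "seed_col") %||% names(ranking)[1]
  out <- ranking %>%
    group_by(.data[[seed_col]]) %>%
    filter(.data$rank <= ceiling(fraction * dplyr::n())) %>%
    ungroup()
  new_ranking(out, seed_col, attr(ranking, "node_col") %||% names(ranking)[2])
}

#' Reconstruct the gene regulatory network
#'
#' One walk per *gene*, seeded in the gene layer and exploring the full
#' multilayer up to the TF layer. The score of TF `t` in the walk seeded at
#' gene `g` becomes the weight of the GRN edge `t -> g`; only strictly
#' positive scores yield edges. This orientation makes the TFs compete
#' within each gene's walk -- the standard contract of GRN inference --
#' whereas [tf_targets()] makes genes compete within each TF's walk.
#'
#' @inheritParams tf_targets
#' @return Tibble of class `scrw_grn`: `tf`, `gene`, `weight`, sorted by
#'   TF then descending weight. See [regulons()] for the per-TF view.
#' @export
build_grn <- function(ml, config = rwr_config(), tf_layer = "TF",
                      rna_layer = "RNA") {
  walks <- multi_seed_walk(ml, rna_layer, tf_layer, config)
  edges <- walks[walks$score > 0, , drop = FALSE]
  edges <- tibble(tf = edges$node, gene = edges$seed, weight = edges$score)
  edges <- edges[c_order(edges$tf, -edges$weight, edges$gene), , drop = FALSE]
  new_grn(edges, n_tfs = length(ml$layers[[tf_layer]]$nodes),
          n_genes = length(ml$layers[[rna_layer]]$nodes))
}

new_grn <- function(edges, n_tfs = dplyr::n_distinct(edges$tf),
                    n_genes = dplyr::n_distinct(edges$gene)) {
  structure(as_tibble(edges), n_tfs = n_tfs, n_genes = n_genes,
            class = c("scrw_grn", class(as_tibble(edges))))
}

#' Per-TF regulon view of a GRN
#'
#' A regulon is a TF together with its predicted target genes ranked by
#' association strength (the walk score).
#'
#' @param grn An `scrw_grn`.
#' @return Tibble `tf`, `gene`, `weight`, `rank` (within TF).
#' @export
regulons <- function(grn) {
  stopifnot(inherits(grn, "scrw_grn"))
  grn %>%
    group_by(.data$tf) %>%
    arrange(desc(.data$weight), .data$gene, .by_group = TRUE) %>%
    mutate(rank = dplyr::row_number()) %>%
    ungroup()
}

#' @export
glance.scrw_grn <- function(x, ...) {
  n_tfs <- attr(x, "n_tfs") %||% dplyr::n_distinct(x$tf)
  n_genes <- attr(x, "n_genes") %||% dplyr::n_distinct(x$gene)
  tibble(n_edges = nrow(x), n_regulons = dplyr::n_distinct(x$tf),
         n_tfs = n_tfs, n_genes = n_genes,
         density = nrow(x) / (n_tfs * n_genes))
}

#' @export
tidy.scrw_grn <- function(x, ...) as_tibble(unclass_tbl(x))

unclass_tbl <- function(x) {
  class(x) <- setdiff(class(x), c("scrw_grn", "scrw_ranking"))
  attr(x, "n_tfs") <- NULL; attr(x, "n_genes") <- NULL
  attr(x, "seed_col") <- NULL; attr(x, "node_col") <- NULL
  x
}

#' Filter a GRN to a target edge density
#'
#' Keeps the `ceiling(d * n_tfs * n_genes)` heaviest edges. Inferred GRNs
#' are often near-complete bipartite graphs, which makes raw comparisons
#' (and community structure) meaningless; equalizing density first puts
#' networks on a common footing. Ties at the cutoff are broken
#' deterministically (weight descending, then TF id, then gene id).
#'
#' @param grn An `scrw_grn`.
#' @param density Target density `d` in (0, 1], relative to the complete
#'   TF-by-gene bipartite graph.
#' @return The filtered `scrw_grn`.
#' @export
filter_to_density <- function(grn, density) {
  stopifnot(inherits(grn, "scrw_grn"), density > 0, density <= 1)
  n_tfs <- attr(grn, "n_tfs") %||% dplyr::n_distinct(grn$tf)
  n_genes <- attr(grn, "n_genes") %||% dplyr::n_distinct(grn$gene)
  n_keep <- ceiling(density * n_tfs * n_genes)
  o <- c_order(-grn$weight, grn$tf, grn$gene)
  out <- grn[head(o, n_keep), , drop = FALSE]
  out <- out[c_order(out$tf, -out$weight, out$gene), , drop = FALSE]
  new_grn(out, n_tfs, n_genes)
}

#' Write a GRN as TSV (plus optional per-TF regulon files)
#'
#' @param grn An `scrw_grn`.
#' @param path Output TSV (`tf`, `gene`, `weight`).
#' @param regulon_dir Optional directory: one `<tf>.tsv` ranked regulon per
#'   TF.
#' @return Invisibly, `path`.
#' @export
write_grn <- function(grn, path, regulon_dir = NULL) {
  readr::write_tsv(unclass_tbl(grn), path)
  if (!is.null(regulon_dir)) {
    dir.create(regulon_dir, showWarnings = FALSE, recursive = TRUE)
    reg <- regulons(grn)
    for (tf in unique(reg$tf)) {
      readr::write_tsv(reg[reg$tf == tf, c("gene", "weight", "rank")],
                       file.path(regulon_dir, paste0(tf, ".tsv")))
    }
  }
  invisible(path)
}

#' Read a GRN from TSV
#'
#' @param path TSV with columns `tf`, `gene`, `weight`.
#' @return An `scrw_grn`.
#' @export
read_grn <- function(path) {
  tb <- readr::read_tsv(path, col_types = "ccd")
  names(tb)[1:3] <- c("tf", "gene", "weight")
  new_grn(tb)
}
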