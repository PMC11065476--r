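#' Build the full multilayer network from a multi-omics bundle
#'
#' Runs the standard reconstruction on a synthetic (or similarly shaped)
#' bundle: infer the gene layer from scRNA, the peak co-accessibility layer
#' from scATAC, build the TF layer (isolated TFs, or with cooperation edges
#' when `use_tf_edges = TRUE`), scan peak sequences for motif occurrences
#' to obtain TF -> peak links, link peaks to gene TSSs by proximity, and
#' assemble everything. With `include_methylation = TRUE` the methylation
#' layer is added with proximity links to both genes and peaks, giving a
#' four-layer network.
#'
#' @param bundle An `scrw_bundle` (see [generate_multiome()]), or any list
#'   with the same fields.
#' @param gene_config An [gene_layer_config()].
#' @param peak_config An [peak_layer_config()].
#' @param proximity_window Peak-to-TSS window in bp for the bipartite
#'   links.
#' @param rel_threshold Motif-score threshold, fraction of each motif's
#'   maximum attainable score.
#' @param use_tf_edges Install the bundle's TF--TF cooperation edges in the
#'   TF layer (the "+TF" variant).
#' @param include_methylation Add the methylation layer and its proximity
#'   links.
#' @param link_mode TF -> peak weighting, `"binary"` or `"score"`.
#' @return An `scrw_multilayer` with layers `TF`, `ATAC`, `RNA` (and
#'   `meC`).
#' @export
build_multilayer <- function(bundle,
                             gene_config = gene_layer_config(),
                             peak_config = peak_layer_config(),
                             proximity_window = 1e5,
                             rel_threshold = 0.8,
                             use_tf_edges = FALSE,
                             include_methylation = FALSE,
                             link_mode = c("binary", "score")) {
  link_mode <- match.arg(link_mode)
  tf_l <- tf_layer(bundle$tfs,
                   edges = if (use_tf_edges) bundle$tf_edges else NULL)
  rna_l <- infer_gene_layer(bundle$rna, gene_config)
  atac_l <- infer_peak_layer(bundle$atac, bundle$peaks, peak_config)

  hits <- scan_motifs(extract_sequences(bundle$genome, bundle$peaks),
                      bundle$motifs, rel_threshold = rel_threshold)
  no_motif <- setdiff(bundle$tfs, vapply(bundle$motifs, function(m) m$tf[1], ""))
  if (length(no_motif) > 0) {
    warn(sprintf("build_multilayer: %d TF(s) without a motif model remain isolated: %s",
                 length(no_motif), paste(head(no_motif, 5), collapse = ", ")))
  }
  tf_peak <- link_tf_peaks(hits, tf_l, atac_l, mode = link_mode)
  peak_gene <- bipartite_links(
    "ATAC", "RNA",
    link_by_proximity(bundle$peaks, gene_features(bundle$genes),
                      window = proximity_window, anchor = "tss"))

  layers <- list(tf_l, atac_l, rna_l)
  bps <- list(tf_peak, peak_gene)
  if (include_methylation) {
    me_l <- infer_generic_layer(bundle$methylation, bundle$regions_methyl,
                                config = peak_config, name = "meC")
    me_gene <- bipartite_links(
      "meC", "RNA",
      link_by_proximity(bundle$regions_methyl, gene_features(bundle$genes),
                        window = proximity_window, anchor = "tss"))
    me_peak <- bipartite_links(
      "meC", "ATAC",
      link_by_proximity(bundle$regions_methyl, bundle$peaks,
                        window = proximity_window, anchor = "body"))
    layers <- c(layers, list(me_l))
    bps <- c(bps, list(me_gene, me_peak))
  }
  assemble_multilayer(layers, bps)
}

#' Generate a random multilayer network
#'
#' Draws a small random heterogeneous multilayer (Erdos-Renyi layers
#' chained by random bipartite links) with uniformly random edge weights.
#' Intended for verification and benchmarking of the walk engine, where a
#' broad family of valid inputs matters more than biological structure.
#'
#' @param n_layers Number of layers (chained linearly by bipartites).
#' @param nodes_per_layer Nodes in each layer (recycled).
#' @param intra_p,inter_p Edge probabilities for intra-layer and bipartite
#'   edges.
#' @param directed_layers Logical, recycled: directedness per layer.
#' @param seed Seed for reproducibility.
#' @return An `scrw_multilayer`.
#' @export
random_multilayer <- function(n_layers = 3, nodes_per_layer = 20,
                              intra_p = 0.2, inter_p = 0.2,
                              directed_layers = FALSE, seed = 1L) {
  withr::with_seed(seed, {
    nodes_per_layer <- rep_len(nodes_per_layer, n_layers)
    directed_layers <- rep_len(directed_layers, n_layers)
    layers <- lapply(seq_len(n_layers), function(i) {
      nm <- paste0("L", i)
      nd <- sprintf("%s_n%02d", tolower(nm), seq_len(nodes_per_layer[i]))
      pairs <- crossing(from = nd, to = nd)
      pairs <- pairs[pairs$from < pairs$to, ]
      pairs <- pairs[runif(nrow(pairs)) < intra_p, ]
      if (nrow(pairs) > 0) pairs$weight <- runif(nrow(pairs), 0.1, 1)
      layer(nm, edges = pairs, nodes = nd, directed = directed_layers[i])
    })
    bps <- lapply(seq_len(n_layers - 1), function(i) {
      a <- layers[[i]]; b <- layers[[i + 1]]
      pairs <- crossing(from = a$nodes, to = b$nodes)
      pairs <- pairs[runif(nrow(pairs)) < inter_p, ]
      if (nrow(pairs) == 0) pairs <- tibble(from = a$nodes[1], to = b$nodes[1])
      pairs$weight <- runif(nrow(pairs), 0.1, 1)
      bipartite_links(a$name, b$name, pairs)
    })
    suppressWarnings(assemble_multilayer(layers, bps))
  })
}
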