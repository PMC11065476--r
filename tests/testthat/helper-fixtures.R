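# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# --- tiny hand-built multilayers -----------------------------------------

path3_ml <- function() {
  # 3-node undirected path a - b - c in a single layer
  assemble_multilayer(list(
    layer("L", tibble::tibble(from = c("a", "b"), to = c("b", "c"),
                              weight = 1))))
}

two_layer_ml <- function() {
  l1 <- layer("A", tibble::tibble(from = "a1", to = c("a2", "a3"), weight = 1))
  l2 <- layer("B", nodes = c("b1", "b2"),
              edges = tibble::tibble(from = "b1", to = "b2", weight = 1))
  assemble_multilayer(
    list(l1, l2),
    list(bipartite_links("A", "B",
                         tibble::tibble(from = "a1", to = "b1", weight = 1))))
}

# small synthetic bundle for unit tests (fast: ~2 s pipeline)
small_config <- function(seed = 0) {
  synthetic_config(n_tfs = 4, n_peaks = 40, n_genes = 20,
                   n_regions_methyl = 10,
                   n_cells = c(rna = 60, atac = 50, methylation = 40),
                   peaks_per_tf = 3, genes_per_tf = 5, seed = seed)
}

small_bundle <- function() memo("small_bundle", generate_multiome(small_config()))

small_ml <- function() memo("small_ml", {
  build_multilayer(small_bundle(), gene_config = gene_layer_config(n_trees = 50))
})

# default-scale bundle and derived objects (the study conditions; seed 0)

default_bundle <- function() memo("default_bundle",
                                  generate_multiome(synthetic_config()))

default_ml <- function() memo("default_ml", build_multilayer(default_bundle()))

default_grn <- function() memo("default_grn", build_grn(default_ml()))

# complete-pairs score table for AUROC against planted TF->gene edges
grn_score_table <- function(bundle, grn) {
  pairs <- tidyr::crossing(tf = bundle$tfs, gene = bundle$genes$id)
  pairs <- dplyr::left_join(pairs, grn, by = c("tf", "gene"))
  pairs$weight[is.na(pairs$weight)] <- 0
  pairs$planted <- paste(pairs$tf, pairs$gene) %in%
    paste(bundle$truth$tf_gene$tf, bundle$truth$tf_gene$gene)
  pairs
}

# 8-node GRN with two 4-node bipartite blocks joined by one weak edge
toy_grn_8 <- function() {
  edges <- tibble::tibble(
    tf = c("t1", "t1", "t2", "t2", "t3", "t3", "t4", "t4", "t1"),
    gene = c("g1", "g2", "g1", "g2", "g3", "g4", "g3", "g4", "g3"),
    weight = c(1, 1, 1, 1, 1, 1, 1, 1, 0.1))
  scregwalk:::new_grn(edges, n_tfs = 4, n_genes = 4)
}

# enumerate all set partitions of n elements as membership vectors
# (restricted growth strings); Bell(8) = 4140
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, k) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(k + 1L)) rec(c(prefix, v), max(k, v))
  }
  rec(integer(0), 0L)
  out
}
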