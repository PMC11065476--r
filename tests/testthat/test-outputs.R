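# hand-built noiseless cascade: TF1 -> {p1,p2} -> {g1,g2}, plus an
# unreachable gene g3 and a motif-less TF2
toy_cascade_ml <- function() {
  tf <- tf_layer(c("TF1", "TF2"))
  atac <- layer("ATAC", tibble::tibble(from = "p1", to = "p2", weight = 1),
                nodes = c("p1", "p2", "p3"))
  rna <- layer("RNA", nodes = c("g1", "g2", "g3"), directed = TRUE)
  suppressWarnings(assemble_multilayer(
    list(tf, atac, rna),
    list(bipartite_links("TF", "ATAC",
                         tibble::tibble(from = c("TF1", "TF1"),
                                        to = c("p1", "p2"), weight = 1)),
         bipartite_links("ATAC", "RNA",
                         tibble::tibble(from = c("p1", "p2"),
                                        to = c("g1", "g2"), weight = 1)))))
}

test_that("TF target prediction ranks only reachable genes above zero", {
  rk <- tf_targets(toy_cascade_ml())
  t1 <- rk[rk$tf == "TF1", ]
  expect_setequal(t1$gene, c("g1", "g2", "g3"))
  expect_setequal(t1$gene[t1$rank <= 2], c("g1", "g2"))
  expect_identical(t1$score[t1$gene == "g3"], 0)   # unreachable: exactly 0
  expect_equal(t1$rank[t1$gene == "g3"], 3)
  # TF with no motif hits: all-zero gene scores
  t2 <- rk[rk$tf == "TF2", ]
  expect_true(all(t2$score == 0))
})

test_that("binding-region walks stay in the TF+ATAC subnetwork", {
  rk <- tf_binding_regions(toy_cascade_ml())
  t1 <- rk[rk$tf == "TF1", ]
  expect_setequal(t1$peak, c("p1", "p2", "p3"))
  # clique peaks outrank the disconnected peak
  expect_setequal(t1$peak[t1$rank <= 2], c("p1", "p2"))
  expect_identical(t1$score[t1$peak == "p3"], 0)
  expect_true(all(rk$score[rk$tf == "TF2"] == 0))
})

test_that("fraction filtering keeps ceiling(fraction * n) peaks per TF", {
  rk <- tf_binding_regions(small_ml())
  n_peaks <- dplyr::n_distinct(rk$peak)
  for (f in c(1, 0.8, 0.6, 0.2)) {
    kept <- top_fraction(rk, f)
    per_tf <- dplyr::count(kept, tf)
    expect_true(all(per_tf$n == ceiling(f * n_peaks)))
  }
})

test_that("gene regulatory regions rank proximal above distal-only peaks", {
  # gene g links to p (proximal); p co-accessible with distal q
  tf <- tf_layer("TF1")
  atac <- layer("ATAC", tibble::tibble(from = "p", to = "q", weight = 1))
  rna <- layer("RNA", nodes = "g", directed = TRUE)
  ml <- suppressWarnings(assemble_multilayer(
    list(tf, atac, rna),
    list(bipartite_links("ATAC", "RNA",
                         tibble::tibble(from = "p", to = "g", weight = 1)))))
  rk <- gene_regulatory_regions(ml)
  g <- rk[rk$gene == "g", ]
  expect_true(all(g$score > 0))
  expect_gte(g$score[g$peak == "p"], g$score[g$peak == "q"])
  expect_equal(g$peak[g$rank == 1], "p")
})

test_that("a gene with no links yields all-zero peak scores", {
  tf <- tf_layer("TF1")
  atac <- layer("ATAC", tibble::tibble(from = "p", to = "q", weight = 1))
  rna <- layer("RNA", nodes = c("g", "h"), directed = TRUE)
  ml <- suppressWarnings(assemble_multilayer(
    list(tf, atac, rna),
    list(bipartite_links("ATAC", "RNA",
                         tibble::tibble(from = "p", to = "g", weight = 1)))))
  rk <- gene_regulatory_regions(ml)
  expect_true(all(rk$score[rk$gene == "h"] == 0))
})

test_that("the GRN makes TFs compete per gene and counts regulons by edges", {
  ml <- toy_cascade_ml()
  g <- build_grn(ml)
  expect_true(all(g$weight > 0))
  expect_equal(anyDuplicated(paste(g$tf, g$gene)), 0)
  # TF2 is unreachable from every gene: no regulon
  expect_false("TF2" %in% g$tf)
  expect_equal(glance(g)$n_regulons, dplyr::n_distinct(g$tf))
  reg <- regulons(g)
  expect_true(all(reg$rank >= 1))
})

test_that("two TFs with identical connectivity get equal weights per gene", {
  tf <- tf_layer(c("TFa", "TFb"))
  atac <- layer("ATAC", nodes = "p1")
  rna <- layer("RNA", nodes = "g1", directed = TRUE)
  ml <- assemble_multilayer(
    list(tf, atac, rna),
    list(bipartite_links("TF", "ATAC",
                         tibble::tibble(from = c("TFa", "TFb"), to = "p1",
                                        weight = 1)),
         bipartite_links("ATAC", "RNA",
                         tibble::tibble(from = "p1", to = "g1", weight = 1))))
  g <- build_grn(ml)
  expect_equal(dplyr::n_distinct(g$weight), 1)
  expect_setequal(g$tf, c("TFa", "TFb"))
})

test_that("target prediction and GRN orientation agree on top-1 in a symmetric toy", {
  # two disjoint one-TF cascades: each gene has exactly one TF ancestor
  tf <- tf_layer(c("TF1", "TF2"))
  atac <- layer("ATAC", nodes = c("p1", "p2"))
  rna <- layer("RNA", nodes = c("g1", "g2"), directed = TRUE)
  ml <- assemble_multilayer(
    list(tf, atac, rna),
    list(bipartite_links("TF", "ATAC",
                         tibble::tibble(from = c("TF1", "TF2"),
                                        to = c("p1", "p2"), weight = 1)),
         bipartite_links("ATAC", "RNA",
                         tibble::tibble(from = c("p1", "p2"),
                                        to = c("g1", "g2"), weight = 1))))
  tt <- tf_targets(ml)
  grn <- build_grn(ml)
  top_gene <- tt[tt$rank == 1, c("tf", "gene")]
  top_tf <- regulons(grn) %>% dplyr::group_by(gene) %>%
    dplyr::slice_max(weight, n = 1) %>% dplyr::ungroup()
  merged <- dplyr::inner_join(top_gene, top_tf, by = "tf")
  expect_equal(merged$gene.x, merged$gene.y)
})

test_that("rankings cover exactly the target layer's nodes", {
  ml <- small_ml()
  b <- small_bundle()
  tt <- tf_targets(ml)
  for (tf in b$tfs) {
    expect_setequal(tt$gene[tt$tf == tf], b$genes$id)
  }
  rr <- gene_regulatory_regions(ml)
  expect_setequal(unique(rr$peak), b$peaks$id)
})

test_that("density filtering keeps the heaviest edges with deterministic ties", {
  # 4x4 complete bipartite with distinct weights
  edges <- tidyr::crossing(tf = paste0("t", 1:4), gene = paste0("g", 1:4))
  edges$weight <- seq(16, 1) / 16
  g <- scregwalk:::new_grn(edges, n_tfs = 4, n_genes = 4)
  g25 <- filter_to_density(g, 0.25)
  expect_equal(nrow(g25), 4)
  expect_setequal(g25$weight, sort(edges$weight, decreasing = TRUE)[1:4])
  # identity at d = 1
  expect_equal(nrow(filter_to_density(g, 1)), 16)
  # tie at the cutoff: weight desc, then tf asc, then gene asc
  edges2 <- tibble::tibble(tf = c("t2", "t1", "t1"),
                           gene = c("gA", "gB", "gA"),
                           weight = c(0.5, 0.5, 0.9))
  g2 <- scregwalk:::new_grn(edges2, n_tfs = 2, n_genes = 2)
  kept <- filter_to_density(g2, 0.5)           # ceiling(0.5*4) = 2 edges
  expect_equal(nrow(kept), 2)
  expect_true(all(paste(kept$tf, kept$gene) %in% c("t1 gA", "t1 gB")))
})
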