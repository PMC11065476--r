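test_that("transition columns are stochastic and split intra/inter mass per contract", {
  op <- build_transition(two_layer_ml())
  P <- as.matrix(op$P)
  expect_true(all(abs(Matrix::colSums(op$P)[!op$dangling] - 1) <= 1e-12))
  expect_true(all(P >= 0))
  # a1: two unit intra edges + one bipartite link, lambda = 0.5
  expect_equal(P["A:a2", "A:a1"], 0.25)
  expect_equal(P["A:a3", "A:a1"], 0.25)
  expect_equal(P["B:b1", "A:a1"], 0.5)
  # b1 has an intra edge and a bipartite link: 0.5 each
  expect_equal(P["B:b2", "B:b1"], 0.5)
  expect_equal(P["A:a1", "B:b1"], 0.5)
  # a2: intra only -> full mass intra
  expect_equal(P["A:a1", "A:a2"], 1)
})

test_that("an isolated node with one bipartite link sends full mass across", {
  tf <- tf_layer("t1")
  atac <- layer("ATAC", tibble::tibble(from = "p1", to = "p2", weight = 1))
  ml <- assemble_multilayer(
    list(tf, atac),
    list(bipartite_links("TF", "ATAC", tibble::tibble(from = "t1", to = "p1"))))
  P <- as.matrix(build_transition(ml)$P)
  expect_equal(P["ATAC:p1", "TF:t1"], 1)
})

test_that("nodes with neither intra nor inter edges are dangling", {
  tf <- tf_layer(c("t1", "t2"))
  atac <- layer("ATAC", nodes = c("p1", "p2"))
  ml <- assemble_multilayer(
    list(tf, atac),
    list(bipartite_links("TF", "ATAC", tibble::tibble(from = "t1", to = "p1"))))
  op <- build_transition(ml)
  dang <- op$index$gid[op$dangling]
  expect_setequal(dang, c("TF:t2", "ATAC:p2"))
  expect_true(all(Matrix::colSums(op$P)[op$dangling] == 0))
})

test_that("jump mass renormalizes when a node reaches more than two layers", {
  # center node in layer B linked to A, C, D: 3 adjacent layers, no intra
  layers <- list(layer("A", nodes = "a"), layer("B", nodes = "b"),
                 layer("C", nodes = "c"), layer("D", nodes = "d"))
  bps <- list(
    bipartite_links("B", "A", tibble::tibble(from = "b", to = "a")),
    bipartite_links("B", "C", tibble::tibble(from = "b", to = "c")),
    bipartite_links("B", "D", tibble::tibble(from = "b", to = "d")))
  ml <- assemble_multilayer(layers, bps)
  P <- as.matrix(build_transition(ml)$P)
  expect_equal(unname(P[c("A:a", "C:c", "D:d"), "B:b"]), rep(1 / 3, 3))
  expect_equal(sum(P[, "B:b"]), 1)
})

test_that("relabeling nodes permutes the operator identically", {
  ml <- random_multilayer(n_layers = 2, nodes_per_layer = 5, seed = 7)
  op <- build_transition(ml)
  relabel <- function(x) chartr("n", "z", x)   # changes sort order-safe? no:
  # use a prefix swap that changes lexicographic order
  relabel <- function(x) ifelse(grepl("01$|02$", x), paste0("zz_", x), x)
  rl_layer <- function(l) layer(l$name,
                                edges = tibble::tibble(from = relabel(l$edges$from),
                                                       to = relabel(l$edges$to),
                                                       weight = l$edges$weight),
                                nodes = relabel(l$nodes), directed = l$directed)
  rl_bp <- function(bp) bipartite_links(
    bp$layer_a, bp$layer_b,
    tibble::tibble(from = relabel(bp$edges$from), to = relabel(bp$edges$to),
                   weight = bp$edges$weight))
  ml2 <- assemble_multilayer(lapply(ml$layers, rl_layer),
                             lapply(ml$bipartites, rl_bp))
  op2 <- build_transition(ml2)
  # map original gids to relabeled gids and compare entries
  gid2 <- paste0(op$index$layer, ":", relabel(op$index$node))
  P1 <- as.matrix(op$P); P2 <- as.matrix(op2$P)[gid2, gid2]
  expect_equal(unname(P2), unname(P1), tolerance = 1e-15)
})

test_that("removing all bipartites yields a block-diagonal operator", {
  ml <- random_multilayer(n_layers = 3, nodes_per_layer = 8, seed = 11)
  ml_nb <- suppressWarnings(assemble_multilayer(ml$layers, list()))
  op <- build_transition(ml_nb)
  P <- as.matrix(op$P)
  lay <- op$index$layer
  off_block <- P[outer(lay, lay, "!=")]
  expect_true(all(off_block == 0))
})

test_that("subset_layers keeps only intra-subset bipartites", {
  ml <- small_ml()
  sub <- subset_layers(ml, c("TF", "ATAC"))
  expect_setequal(names(sub$layers), c("TF", "ATAC"))
  expect_true(all(purrr::map_lgl(sub$bipartites, ~
    all(c(.x$layer_a, .x$layer_b) %in% c("TF", "ATAC")))))
  # identity case
  sub_all <- subset_layers(ml, names(ml$layers))
  expect_equal(names(sub_all$layers), names(ml$layers))
  expect_equal(length(sub_all$bipartites), length(ml$bipartites))
  expect_error(subset_layers(ml, "nope"), "unknown layer")
})

test_that("a single kept layer with no intra edges is all dangling", {
  tf <- tf_layer(c("t1", "t2"))
  atac <- layer("ATAC", tibble::tibble(from = "p1", to = "p2", weight = 1))
  ml <- assemble_multilayer(
    list(tf, atac),
    list(bipartite_links("TF", "ATAC", tibble::tibble(from = "t1", to = "p1"))))
  op <- build_transition(subset_layers(ml, "TF"))
  expect_true(all(op$dangling))
})
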