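fake_ranking <- function(order_by_tf) {
  # order_by_tf: named list tf -> character vector of nodes in rank order
  out <- purrr::imap_dfr(order_by_tf, function(nodes, tf) {
    tibble::tibble(tf = tf, gene = nodes,
                   score = rev(seq_along(nodes)) / length(nodes),
                   rank = seq_along(nodes))
  })
  structure(out, seed_col = "tf", node_col = "gene",
            class = c("scrw_ranking", class(out)))
}

test_that("overlap at cutoffs counts ground-truth hits in the top k", {
  # gt hits at ranks 1, 4, 9 -> overlaps 1, 2, 3 at k = 3, 5, 10
  rk <- fake_ranking(list(T1 = paste0("g", 1:12)))
  gt <- tibble::tibble(tf = "T1", gene = c("g1", "g4", "g9"))
  ov <- overlap_at_cutoffs(rk, gt, cutoffs = c(3, 5, 10))
  expect_equal(ov$mean_overlap, c(1, 2, 3))
  # monotone non-decreasing in k over the default grid
  ov2 <- overlap_at_cutoffs(rk, gt)
  expect_true(all(diff(ov2$mean_overlap) >= 0))
})

test_that("TFs with empty ground truth are excluded from the mean", {
  rk <- fake_ranking(list(T1 = paste0("g", 1:10), T2 = paste0("g", 1:10)))
  gt <- tibble::tibble(tf = "T1", gene = "g1")
  ov <- overlap_at_cutoffs(rk, gt, cutoffs = 5)
  expect_equal(ov$n_seeds, 1)
  expect_equal(ov$mean_overlap, 1)   # not diluted by T2
  expect_error(overlap_at_cutoffs(rk, tibble::tibble(tf = "TX", gene = "g1"),
                                  cutoffs = 5), "no seeds shared")
})

test_that("random rankings match the hypergeometric expected overlap", {
  n_uni <- 50; n_gt <- 10; k <- 10; n_rep <- 1000
  uni <- sprintf("g%02d", 1:n_uni)
  gt <- tibble::tibble(tf = "T", gene = uni[1:n_gt])
  ovs <- withr::with_seed(42, vapply(seq_len(n_rep), function(i) {
    rk <- fake_ranking(list(T = sample(uni)))
    overlap_at_cutoffs(rk, gt, cutoffs = k)$mean_overlap
  }, 0))
  expected <- k * n_gt / n_uni
  se <- sd(ovs) / sqrt(n_rep)
  expect_lt(abs(mean(ovs) - expected), 3 * se)
})

test_that("one-sided Fisher p equals the exact hypergeometric tail sum", {
  # worked 2x2 table (4, 6, 16, 74): universe 100, |gt| 20, k 10
  rk <- fake_ranking(list(T = sprintf("g%03d", 1:100)))
  gt_genes <- c(sprintf("g%03d", c(1, 3, 5, 7)),        # 4 in top 10
                sprintf("g%03d", 21:36))                 # 16 outside
  gt <- tibble::tibble(tf = "T", gene = gt_genes)
  enr <- rank_enrichment(rk, gt, k = 10)
  expect_equal(enr$overlap, 4)
  oracle <- sum(vapply(4:10, function(i)
    choose(20, i) * choose(80, 10 - i) / choose(100, 10), 0))
  expect_equal(enr$p, oracle, tolerance = 1e-12)
  # and agrees with stats::fisher.test one-sided
  ft <- fisher.test(matrix(c(4, 6, 16, 74), 2, byrow = TRUE),
                    alternative = "greater")
  expect_equal(enr$p, ft$p.value, tolerance = 1e-12)
})

test_that("Fisher agreement with the tail-sum oracle holds across small tables", {
  idx <- 0
  for (U in c(30, 120, 200)) for (G in c(5, 25)) for (k in c(5, 20)) {
    idx <- idx + 1
    uni <- sprintf("u%03d", seq_len(U))
    gt <- tibble::tibble(tf = "T", gene = uni[seq_len(G)])
    perm <- withr::with_seed(idx, sample(uni))
    rk <- fake_ranking(list(T = perm))
    enr <- rank_enrichment(rk, gt, k = k)
    a <- enr$overlap
    oracle <- sum(vapply(a:min(G, k), function(i)
      choose(G, i) * choose(U - G, k - i) / choose(U, k), 0))
    expect_equal(enr$p, oracle, tolerance = 1e-12)
  }
})

test_that("perfect and empty predictions bound the Fisher count", {
  rk <- fake_ranking(list(T = sprintf("g%03d", 1:200)))
  gt <- tibble::tibble(tf = "T", gene = sprintf("g%03d", 1:10))
  expect_equal(fisher_significant_tfs(rk, gt, k = 10), 1)   # gt == top-k
  gt_none <- tibble::tibble(tf = "T", gene = "not_in_universe")
  expect_error(fisher_significant_tfs(rk, gt_none, k = 10),
               "non-empty ground truth")
})

test_that("F1 reproduces hand-computed set and region toys", {
  expect_equal(f1_sets(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(f1_sets(c("a", "b"), c("x", "y")), 0)
  expect_equal(f1_sets(c("a", "b", "c"), c("b", "c", "d")), 2 / 3)
  expect_equal(f1_sets(character(), c("a")), 0)
  # symmetry
  expect_equal(f1_sets(c("a", "b", "c"), c("b", "c", "d")),
               f1_sets(c("b", "c", "d"), c("a", "b", "c")))
  # genomic mode: >= 1 bp overlap matches
  pred <- feature_set(c("p1", "p2"), "chr1", c(0L, 500L), c(100L, 600L))
  tru <- feature_set(c("t1", "t2"), "chr1", c(99L, 900L), c(200L, 950L))
  # p1 overlaps t1 by 1 bp; p2 matches nothing; t2 missed
  expect_equal(f1_sets(pred, tru), 2 * 1 / (2 * 1 + 1 + 1))
})

test_that("community enrichment p-values match the tail-sum oracle and BH applies", {
  part <- tibble::tibble(node = sprintf("g%02d", 1:20),
                         community = rep(1:4, each = 5))
  sets <- list(S1 = sprintf("g%02d", 1:10), S2 = sprintf("g%02d", 11:12))
  uni <- sprintf("g%02d", 1:50)
  res <- enrich_communities(part, list(coll = sets), universe = uni)
  # community 1 (g01..g05) vs S1 (10 genes in universe of 50): overlap 5
  t1 <- res$tests[res$tests$community == "1" & res$tests$set == "S1", ]
  oracle <- sum(vapply(5:5, function(i)
    choose(10, i) * choose(40, 5 - i) / choose(50, 5), 0))
  expect_equal(t1$p, oracle, tolerance = 1e-12)
  expect_true(all(res$tests$p_adj >= res$tests$p - 1e-15))
  expect_equal(res$summary$n_communities, 4)
  expect_equal(res$summary$pct_enriched,
               100 * res$summary$n_enriched / res$summary$n_communities)
  # community with no genes in the universe is never enriched
  part2 <- dplyr::bind_rows(part, tibble::tibble(node = paste0("x", 1:3),
                                                 community = 9L))
  res2 <- enrich_communities(part2, list(coll = sets), universe = uni)
  c9 <- res2$tests[res2$tests$community == "9", ]
  expect_true(all(c9$p == 1))
})

test_that("Spearman GRN comparison handles identity, reversal and absent edges", {
  e <- tidyr::crossing(tf = paste0("t", 1:3), gene = paste0("g", 1:3))
  e$weight <- seq(0.9, 0.1, length.out = 9)
  g1 <- scregwalk:::new_grn(e)
  expect_equal(compare_grns(g1, g1), 1)
  g_rev <- scregwalk:::new_grn(dplyr::mutate(e, weight = rev(weight)))
  expect_equal(compare_grns(g1, g_rev), -1)
  # an edge absent from one side counts as weight 0
  g_half <- scregwalk:::new_grn(e[1:5, ])
  s <- compare_grns(g1, g_half)
  u <- dplyr::full_join(e, e[1:5, ], by = c("tf", "gene"))
  s_oracle <- cor(u$weight.x, ifelse(is.na(u$weight.y), 0, u$weight.y),
                  method = "spearman")
  expect_equal(s, s_oracle)
})

test_that("rank-based AUROC matches pROC on random scores", {
  skip_if_not_installed("pROC")
  withr::with_seed(7, {
    score <- c(rnorm(40, 1), rnorm(60, 0))
    label <- rep(c(TRUE, FALSE), c(40, 60))
  })
  got <- auroc(score, label)
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(label, score,
                                                         direction = "<"))))
  expect_equal(got, ref, tolerance = 1e-12)
  expect_equal(auroc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
})
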