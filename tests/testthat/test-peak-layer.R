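toy_atac <- function() {
  withr::with_seed(0, {
    f <- rnorm(80)
    p1 <- rbinom(80, 1, plogis(f))
    p2 <- p1                                  # duplicated profile
    p3 <- rbinom(80, 1, plogis(f))            # shares the latent factor
    p4 <- rbinom(80, 1, 0.3)                  # independent
    p5 <- rbinom(80, 1, 0.3)                  # other chromosome
    m <- rbind(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5)
    colnames(m) <- paste0("c", 1:80)
    m
  })
}

toy_peaks <- function() {
  feature_set(paste0("p", 1:5),
              c("chr1", "chr1", "chr1", "chr1", "chr2"),
              c(1000L, 3000L, 5000L, 7000L, 1000L),
              c(1400L, 3400L, 5400L, 7400L, 1400L))
}

test_that("edge weights equal the direct Pearson correlation", {
  m <- toy_atac()
  l <- infer_peak_layer(count_matrix(m, "atac"), toy_peaks(),
                        peak_layer_config(window = 5e5, tau = 0))
  # duplicated profile: weight exactly 1
  w12 <- l$edges$weight[l$edges$from == "p1" & l$edges$to == "p2"]
  expect_equal(w12, 1, tolerance = 1e-12)
  # every retained weight matches cor() on the raw profiles to 1e-10
  for (i in seq_len(nrow(l$edges))) {
    expect_equal(l$edges$weight[i],
                 cor(m[l$edges$from[i], ], m[l$edges$to[i], ]),
                 tolerance = 1e-10)
  }
  # planted latent-factor pair retained with positive weight
  expect_true(any(l$edges$from == "p1" & l$edges$to == "p3" |
                    l$edges$from == "p3" & l$edges$to == "p1"))
})

test_that("different chromosomes and out-of-window pairs are never linked", {
  m <- toy_atac()
  m["p5", ] <- m["p1", ]   # perfect correlation, but on chr2
  l <- infer_peak_layer(count_matrix(m, "atac"), toy_peaks())
  expect_false(any(l$edges$from == "p5" | l$edges$to == "p5"))
  # window smaller than any midpoint gap: no edges at all
  l2 <- infer_peak_layer(count_matrix(m, "atac"), toy_peaks(),
                         peak_layer_config(window = 100))
  expect_equal(nrow(l2$edges), 0)
  expect_equal(length(l2$nodes), 5)
})

test_that("negative and sub-threshold correlations are dropped", {
  withr::with_seed(1, {
    a <- rbinom(100, 1, 0.5)
    m <- rbind(p1 = a, p2 = 1 - a,                       # perfectly negative
               p3 = rbinom(100, 1, 0.5))
    colnames(m) <- paste0("c", 1:100)
  })
  pk <- feature_set(paste0("p", 1:3), "chr1", c(0L, 1000L, 2000L),
                    c(400L, 1400L, 2400L))
  l <- infer_peak_layer(count_matrix(m, "atac"), pk)
  expect_false(any((l$edges$from == "p1" & l$edges$to == "p2") |
                     (l$edges$from == "p2" & l$edges$to == "p1")))
  l_tau <- infer_peak_layer(count_matrix(m, "atac"), pk,
                            peak_layer_config(tau = 0.99))
  expect_equal(nrow(l_tau$edges), 0)
})

test_that("layers satisfy invariants and all peaks appear as nodes", {
  b <- small_bundle()
  l <- infer_peak_layer(b$atac, b$peaks)
  expect_setequal(l$nodes, rownames(b$atac$counts))
  expect_true(all(is.finite(l$edges$weight)) && all(l$edges$weight > 0))
  expect_false(l$directed)
  expect_error(infer_peak_layer(b$atac, b$peaks[-1, ]), "no coordinates")
})

test_that("pseudo-cell aggregation changes profiles deterministically", {
  b <- small_bundle()
  cfg <- peak_layer_config(pseudo_cell_size = 10, seed = 5)
  l1 <- infer_peak_layer(b$atac, b$peaks, cfg)
  l2 <- infer_peak_layer(b$atac, b$peaks, cfg)
  expect_identical(l1$edges, l2$edges)
})

test_that("the generic layer applies the same construction to methylation", {
  b <- small_bundle()
  l <- infer_generic_layer(b$methylation, b$regions_methyl, name = "meC")
  expect_equal(l$name, "meC")
  expect_setequal(l$nodes, b$regions_methyl$id)
  # planted same-cascade region pair correlates positively within the window
  planted <- b$regions_methyl$id[!is.na(b$regions_methyl$cascade) &
                                   b$regions_methyl$cascade == 1]
  expect_true(any((l$edges$from %in% planted) & (l$edges$to %in% planted)))
  # all-distinct-chromosome features yield an edgeless layer
  solo <- feature_set(c("r1", "r2"), c("cA", "cB"), c(0L, 0L), c(100L, 100L))
  msolo <- matrix(rbinom(40, 5, 0.5), 2, 20,
                  dimnames = list(c("r1", "r2"), paste0("c", 1:20)))
  l2 <- infer_generic_layer(count_matrix(msolo, "methylation"), solo)
  expect_equal(nrow(l2$edges), 0)
  expect_equal(length(l2$nodes), 2)
})
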