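test_that("generation is byte-identical across runs with the same seed", {
  b1 <- generate_multiome(small_config())
  b2 <- generate_multiome(small_config())
  expect_identical(b1$genome, b2$genome)
  expect_identical(b1$rna$counts, b2$rna$counts)
  expect_identical(b1$atac$counts, b2$atac$counts)
  expect_identical(b1$methylation$counts, b2$methylation$counts)
  expect_identical(b1$truth, b2$truth)
  b3 <- generate_multiome(small_config(seed = 99))
  expect_false(identical(b1$rna$counts, b3$rna$counts))
})

test_that("omics are unpaired: independent cell sets of the configured sizes", {
  b <- small_bundle()
  expect_equal(ncol(b$rna$counts), 60)
  expect_equal(ncol(b$atac$counts), 50)
  expect_equal(ncol(b$methylation$counts), 40)
  expect_length(intersect(colnames(b$rna$counts), colnames(b$atac$counts)), 0)
})

test_that("every planted TF->gene pair is realized by a TF->peak->gene path", {
  b <- small_bundle()
  hits <- scan_motifs(extract_sequences(b$genome, b$peaks), b$motifs,
                      rel_threshold = 0.8)
  tf_peak <- dplyr::distinct(tibble::tibble(tf = hits$tf, peak = hits$seq))
  peak_gene <- link_by_proximity(b$peaks, gene_features(b$genes),
                                 window = 1e5, anchor = "tss")
  paths <- dplyr::inner_join(tf_peak, peak_gene, by = c(peak = "from"))
  realized <- dplyr::distinct(tibble::tibble(tf = paths$tf, gene = paths$to))
  missing <- dplyr::anti_join(b$truth$tf_gene, realized, by = c("tf", "gene"))
  expect_equal(nrow(missing), 0)
})

test_that("planted motifs are recovered in every cascade peak", {
  b <- small_bundle()
  hits <- scan_motifs(extract_sequences(b$genome, b$peaks), b$motifs,
                      rel_threshold = 0.8)
  found <- dplyr::distinct(tibble::tibble(tf = hits$tf, peak = hits$seq))
  missing <- dplyr::anti_join(b$truth$tf_peak, found, by = c("tf", "peak"))
  expect_equal(nrow(missing), 0)
})

test_that("planted co-accessible peak pairs correlate above background", {
  b <- small_bundle()
  m <- as.matrix(b$atac$counts)
  casc <- b$peaks$cascade
  planted <- purrr::map_dfr(unique(stats::na.omit(casc)), function(c_i) {
    ids <- b$peaks$id[!is.na(casc) & casc == c_i]
    tidyr::crossing(a = ids, b = ids) %>% dplyr::filter(a < b)
  })
  bg_ids <- b$peaks$id[is.na(casc)]
  bg_ids <- bg_ids[apply(m[bg_ids, ], 1, sd) > 0]   # correlations defined
  bg_pairs <- withr::with_seed(1, tibble::tibble(
    a = sample(bg_ids, 30, replace = TRUE),
    b = sample(bg_ids, 30, replace = TRUE)) %>% dplyr::filter(a < b))
  cor_of <- function(p) mean(purrr::map2_dbl(p$a, p$b,
                                             ~ cor(m[.x, ], m[.y, ])))
  expect_gt(cor_of(planted), cor_of(bg_pairs))
})

test_that("cell-group subsampling retains the exact fraction and nothing else changes", {
  b <- small_bundle()
  n2 <- sum(b$cell_groups$rna$group == 2)
  p <- perturb_cell_groups(b, "rna", 2, 0.5)
  expect_equal(sum(p$cell_groups$rna$group == 2), floor(0.5 * n2))
  expect_equal(sum(p$cell_groups$rna$group != 2),
               sum(b$cell_groups$rna$group != 2))
  expect_identical(p$atac$counts, b$atac$counts)
  expect_identical(p$truth, b$truth)
  # retained cells keep their original profiles
  expect_identical(p$rna$counts,
                   b$rna$counts[, colnames(p$rna$counts), drop = FALSE])
  # identity and errors
  expect_identical(perturb_cell_groups(b, "rna", 2, 1), b)
  expect_error(perturb_cell_groups(b, "rna", 99, 0.5), "no cells of group")
  # sequential perturbation of two omics composes
  p2 <- perturb_cell_groups(p, "atac", 3, 0.5)
  expect_lt(ncol(p2$atac$counts), ncol(b$atac$counts))
  expect_identical(p2$rna$counts, p$rna$counts)
})

test_that("bundles write to standard on-disk formats that the readers accept", {
  b <- small_bundle()
  dir <- withr::local_tempdir()
  write_multiome_bundle(b, dir, matrix_format = "mtx")
  rna <- read_count_matrix(file.path(dir, "rna", "matrix.mtx"), omic = "rna")
  expect_equal(unname(as.matrix(rna$counts)), unname(as.matrix(b$rna$counts)))
  peaks <- read_bed(file.path(dir, "peaks.bed"))
  expect_equal(peaks$id, b$peaks$id)
  motifs <- read_motifs_jaspar(file.path(dir, "motifs.jaspar"))
  expect_equal(length(motifs), length(b$motifs))
  expect_equal(motifs[[1]]$counts, b$motifs[[1]]$counts)
  genome <- read_fasta(file.path(dir, "genome.fa"))
  expect_equal(sort(names(genome)), sort(names(b$genome)))
  sets <- read_gmt(file.path(dir, "pathways.gmt"))
  expect_equal(sets, b$pathways)
  gt <- readr::read_tsv(file.path(dir, "truth_tf_gene.tsv"),
                        show_col_types = FALSE)
  expect_equal(nrow(gt), nrow(b$truth$tf_gene))
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_tfs = 30, genes_per_tf = 10, n_genes = 200),
               "must not exceed")
  expect_error(synthetic_config(n_peaks = 10, n_tfs = 20, peaks_per_tf = 5))
})
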