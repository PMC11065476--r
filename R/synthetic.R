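#' Synthetic multi-omics generator configuration
#'
#' Describes an unpaired single-cell multi-omics experiment with planted
#' TF -> peak -> gene regulatory cascades. Each TF owns one cascade: a set
#' of accessible peaks carrying its binding motif, placed on the cascade's
#' own chromosome within proximity range of the cascade's target genes.
#' A per-cell latent activity per cascade (cell-group mean plus Gaussian
#' noise) drives correlated accessibility of the cascade's peaks,
#' correlated expression of its genes and (inversely) methylation of its
#' regions, so every inferable layer contains the planted structure.
#'
#' Cell sets are drawn independently per omic from shared group
#' proportions: the data are unpaired by construction.
#'
#' @param n_tfs,n_peaks,n_genes,n_regions_methyl Feature counts. Defaults
#'   (20 TFs, 500 peaks, 200 genes, 50 regions) give a desk-scale dataset
#'   where the 20 cascades tile the 200 genes exactly.
#' @param n_cells Named integer vector: cells per omic (independent).
#' @param n_cell_groups Number of cell groups (cascades are activated in
#'   one group each, round-robin).
#' @param group_proportions Sampling proportions of the groups (recycled /
#'   normalized).
#' @param peaks_per_tf,genes_per_tf Cascade sizes.
#' @param motif_width Width of each planted consensus motif. At the default
#'   10 bp, chance consensus occurrences in background sequence are
#'   negligible.
#' @param noise_sd Standard deviation of the per-cell latent activity noise
#'   around its group mean.
#' @param activity_amplitude Latent group mean of an active cascade
#'   (inactive groups sit at 0).
#' @param rna_base_mean Range of baseline expression means (uniform draw
#'   per gene).
#' @param rna_effect Log-scale expression effect of one unit of latent
#'   activity.
#' @param nb_dispersion Negative-binomial dispersion of RNA counts
#'   (`size = 1/dispersion`).
#' @param atac_base_rate Baseline Bernoulli accessibility rate.
#' @param atac_effect Logit-scale accessibility effect per unit latent
#'   activity.
#' @param meth_coverage,meth_overdispersion Beta-binomial coverage and
#'   precision of methylation counts.
#' @param motif_mutation_rate Per-base probability of mutating a planted
#'   motif copy (0 = exact consensus insertion, the noise-free default).
#' @param seed Master seed; the emitted bundle is byte-identical across
#'   runs for a fixed configuration.
#' @return List of class `scrw_synth_config`.
#' @export
synthetic_config <- function(n_tfs = 20L, n_peaks = 500L, n_genes = 200L,
                             n_regions_methyl = 50L,
                             n_cells = c(rna = 300L, atac = 250L,
                                         methylation = 200L),
                             n_cell_groups = 3L,
                             group_proportions = c(0.4, 0.35, 0.25),
                             peaks_per_tf = 5L, genes_per_tf = 10L,
                             motif_width = 10L, noise_sd = 1,
                             activity_amplitude = 2,
                             rna_base_mean = c(2, 8), rna_effect = 0.8,
                             nb_dispersion = 0.3,
                             atac_base_rate = 0.05, atac_effect = 1.5,
                             meth_coverage = 20L, meth_overdispersion = 10,
                             motif_mutation_rate = 0,
                             seed = 0L) {
  stopifnot(n_tfs >= 1, n_peaks >= n_tfs * peaks_per_tf,
            n_genes >= n_tfs, genes_per_tf * n_tfs <= n_genes ||
              genes_per_tf * n_tfs > 0,
            all(n_cells > 0), n_cell_groups >= 1,
            motif_width >= 4, nb_dispersion > 0,
            motif_mutation_rate >= 0, motif_mutation_rate < 1)
  if (n_tfs * genes_per_tf > n_genes) {
    abort("synthetic_config: n_tfs * genes_per_tf must not exceed n_genes")
  }
  gp <- rep_len(group_proportions, n_cell_groups)
  structure(
    list(n_tfs = as.integer(n_tfs), n_peaks = as.integer(n_peaks),
         n_genes = as.integer(n_genes),
         n_regions_methyl = as.integer(n_regions_methyl),
         n_cells = n_cells, n_cell_groups = as.integer(n_cell_groups),
         group_proportions = gp / sum(gp),
         peaks_per_tf = as.integer(peaks_per_tf),
         genes_per_tf = as.integer(genes_per_tf),
         motif_width = as.integer(motif_width), noise_sd = noise_sd,
         activity_amplitude = activity_amplitude,
         rna_base_mean = rna_base_mean, rna_effect = rna_effect,
         nb_dispersion = nb_dispersion, atac_base_rate = atac_base_rate,
         atac_effect = atac_effect,
         meth_coverage = as.integer(meth_coverage),
         meth_overdispersion = meth_overdispersion,
         motif_mutation_rate = motif_mutation_rate,
         seed = as.integer(seed)),
    class = "scrw_synth_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Generate a synthetic unpaired multi-omics bundle
#'
#' Draws the full fixture described by [synthetic_config()]: a genome with
#' peaks placed as intervals and consensus motifs inserted into cascade
#' peaks (on a random strand), unpaired scRNA / scATAC / methylation count
#' matrices over independent cell sets, gene and region annotations, one
#' motif model per TF, TF--TF cooperation edges between cascades sharing an
#' active group, planted "pathway" gene sets (the cascade gene sets), and
#' the ground-truth association tables the construction implies.
#'
#' Every TF -> gene ground-truth pair is realized by at least one
#' TF -> peak -> gene path: the motif sits in the cascade peaks, and the
#' cascade peaks lie within proximity range of every cascade gene's TSS.
#'
#' @param config An [synthetic_config()].
#' @return List of class `scrw_bundle`: `config`, `genome` (named character
#'   vector of chromosome sequences), `tfs`, `motifs`, `peaks`, `genes`,
#'   `regions_methyl` ([feature_set()] tibbles / tables), `rna`, `atac`,
#'   `methylation` (`scrw_counts`), `cell_groups` (per-omic tibbles `cell`,
#'   `group`), `tf_edges`, `pathways` (named list), and `truth` (list of
#'   tibbles `tf_gene`, `tf_peak`, `gene_peak`).
#' @export
generate_multiome <- function(config = synthetic_config()) {
  stopifnot(is(config, "scrw_synth_config"))
  withr::with_seed(config$seed, generate_multiome_impl(config))
}

generate_multiome_impl <- function(cfg) {
  n_casc <- cfg$n_tfs
  tfs <- sprintf("TF%02d", seq_len(n_casc))
  genes <- sprintf("G%03d", seq_len(cfg$n_genes))
  peak_ids <- sprintf("P%03d", seq_len(cfg$n_peaks))
  active_group <- rep_len(seq_len(cfg$n_cell_groups), n_casc)

  ## --- genomic layout -----------------------------------------------------
  casc_chrom_len <- 200000L
  bg_chrom_len <- 2000000L
  peak_width <- 300L
  n_casc_peaks <- n_casc * cfg$peaks_per_tf
  n_bg_peaks <- cfg$n_peaks - n_casc_peaks
  casc_chroms <- sprintf("chr%02d", seq_len(n_casc))

  # cascade genes: TSS spread over [60 kb, 140 kb]; cascade peaks in the
  # middle so each peak is within 100 kb of every cascade gene's TSS
  casc_of_gene <- rep(seq_len(n_casc), each = cfg$genes_per_tf)[
    seq_len(min(cfg$n_genes, n_casc * cfg$genes_per_tf))]
  extra_genes <- cfg$n_genes - length(casc_of_gene)   # background genes
  gene_tbl <- tibble(
    id = genes,
    chrom = c(casc_chroms[casc_of_gene], rep("chrBg", extra_genes)),
    tss = c(
      unlist(lapply(seq_len(n_casc), function(c) {
        k <- sum(casc_of_gene == c)
        as.integer(round(seq(60000, 140000, length.out = max(k, 2))[seq_len(k)]))
      })),
      if (extra_genes > 0)
        as.integer(round(seq(50000, bg_chrom_len - 50000,
                             length.out = extra_genes))) else integer()),
    strand = rep(c("+", "-"), length.out = cfg$n_genes),
    cascade = c(casc_of_gene, rep(NA_integer_, extra_genes)))

  casc_of_peak <- rep(seq_len(n_casc), each = cfg$peaks_per_tf)
  casc_peak_start <- unlist(lapply(seq_len(n_casc), function(c) {
    as.integer(round(seq(95000, 108000,
                         length.out = cfg$peaks_per_tf)))
  }))
  bg_grid <- as.integer(round(seq(1000, bg_chrom_len - peak_width - 1000,
                                  length.out = max(n_bg_peaks, 1))))
  peak_tbl <- feature_set(
    id = peak_ids,
    chrom = c(casc_chroms[casc_of_peak], rep("chrBg", n_bg_peaks)),
    start = c(casc_peak_start, bg_grid[seq_len(n_bg_peaks)]),
    end = c(casc_peak_start, bg_grid[seq_len(n_bg_peaks)]) + peak_width)
  peak_tbl$cascade <- c(casc_of_peak, rep(NA_integer_, n_bg_peaks))

  # methylation regions: 2 per cascade near the cascade block, rest on chrMe
  n_casc_reg <- min(2L * n_casc, cfg$n_regions_methyl)
  n_bg_reg <- cfg$n_regions_methyl - n_casc_reg
  reg_casc <- rep(seq_len(n_casc), each = 2L)[seq_len(n_casc_reg)]
  reg_pos <- rep(c(85000L, 115000L), times = n_casc)[seq_len(n_casc_reg)]
  me_chrom_len <- 500000L
  regions <- feature_set(
    id = sprintf("M%03d", seq_len(cfg$n_regions_methyl)),
    chrom = c(casc_chroms[reg_casc], rep("chrMe", n_bg_reg)),
    start = c(reg_pos,
              if (n_bg_reg > 0)
                as.integer(round(seq(5000, me_chrom_len - 5000,
                                     length.out = n_bg_reg))) else integer()),
    end = c(reg_pos,
            if (n_bg_reg > 0)
              as.integer(round(seq(5000, me_chrom_len - 5000,
                                   length.out = n_bg_reg))) else integer()) + 500L)
  regions$cascade <- c(reg_casc, rep(NA_integer_, n_bg_reg))

  ## --- genome and motifs --------------------------------------------------
  chrom_lens <- c(setNames(rep(casc_chrom_len, n_casc), casc_chroms),
                  chrBg = bg_chrom_len, chrMe = me_chrom_len)
  genome <- vapply(chrom_lens, random_dna, "")

  consensus_pool <- character(0)
  while (length(consensus_pool) < n_casc) {
    cand <- random_dna(cfg$motif_width)
    if (!cand %in% consensus_pool && !revcomp_chr(cand) %in% consensus_pool) {
      consensus_pool <- c(consensus_pool, cand)
    }
  }
  motifs <- lapply(seq_len(n_casc), function(i) {
    bases <- strsplit(consensus_pool[i], "")[[1]]
    counts <- matrix(0, 4, cfg$motif_width,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    counts[cbind(match(bases, c("A", "C", "G", "T")),
                 seq_len(cfg$motif_width))] <- 10
    motif(paste0("MT", sprintf("%02d", i)), counts, tf = tfs[i])
  })

  # insert each cascade's consensus into its peaks (random offset + strand)
  for (i in seq_len(nrow(peak_tbl))) {
    c_i <- peak_tbl$cascade[i]
    if (is.na(c_i)) next
    ins <- consensus_pool[c_i]
    if (cfg$motif_mutation_rate > 0) {
      b <- strsplit(ins, "")[[1]]
      mut <- runif(length(b)) < cfg$motif_mutation_rate
      b[mut] <- vapply(b[mut], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
      ins <- paste(b, collapse = "")
    }
    if (runif(1) < 0.5) ins <- revcomp_chr(ins)
    off <- sample.int(peak_width - cfg$motif_width, 1)
    pos <- peak_tbl$start[i] + off   # 0-based offset into the chromosome
    substr(genome[[peak_tbl$chrom[i]]], pos + 1L,
           pos + cfg$motif_width) <- ins
  }

  ## --- cells and latent activities ---------------------------------------
  draw_cells <- function(omic, n) {
    grp <- sample(seq_len(cfg$n_cell_groups), n, replace = TRUE,
                  prob = cfg$group_proportions)
    tibble(cell = sprintf("%s_c%04d", omic, seq_len(n)), group = grp)
  }
  latent <- function(groups) {
    # cascades x cells
    m <- matrix(0, n_casc, length(groups))
    for (c_i in seq_len(n_casc)) {
      mu <- ifelse(groups == active_group[c_i], cfg$activity_amplitude, 0)
      m[c_i, ] <- mu + rnorm(length(groups), sd = cfg$noise_sd)
    }
    m
  }

  cells_rna <- draw_cells("rna", cfg$n_cells[["rna"]])
  cells_atac <- draw_cells("atac", cfg$n_cells[["atac"]])
  cells_meth <- draw_cells("meth", cfg$n_cells[["methylation"]])
  f_rna <- latent(cells_rna$group)
  f_atac <- latent(cells_atac$group)
  f_meth <- latent(cells_meth$group)

  ## --- count matrices -----------------------------------------------------
  base_mean <- runif(cfg$n_genes, cfg$rna_base_mean[1], cfg$rna_base_mean[2])
  rna <- matrix(0L, cfg$n_genes, nrow(cells_rna),
                dimnames = list(genes, cells_rna$cell))
  for (g in seq_len(cfg$n_genes)) {
    c_g <- gene_tbl$cascade[g]
    mu <- if (is.na(c_g)) rep(base_mean[g], ncol(rna)) else
      base_mean[g] * exp(cfg$rna_effect * f_rna[c_g, ])
    rna[g, ] <- rnbinom(ncol(rna), mu = mu, size = 1 / cfg$nb_dispersion)
  }

  peak_base <- runif(cfg$n_peaks, 0.5 * cfg$atac_base_rate,
                     2 * cfg$atac_base_rate)
  atac <- matrix(0L, cfg$n_peaks, nrow(cells_atac),
                 dimnames = list(peak_ids, cells_atac$cell))
  for (p in seq_len(cfg$n_peaks)) {
    c_p <- peak_tbl$cascade[p]
    rate <- if (is.na(c_p)) rep(peak_base[p], ncol(atac)) else
      plogis(qlogis(peak_base[p]) + cfg$atac_effect * f_atac[c_p, ])
    atac[p, ] <- rbinom(ncol(atac), 1L, rate)
  }

  meth <- matrix(0L, cfg$n_regions_methyl, nrow(cells_meth),
                 dimnames = list(regions$id, cells_meth$cell))
  for (m_i in seq_len(cfg$n_regions_methyl)) {
    c_m <- regions$cascade[m_i]
    # active cascades demethylate their regions
    p_mean <- if (is.na(c_m)) rep(0.7, ncol(meth)) else
      plogis(1.5 - cfg$atac_effect * f_meth[c_m, ])
    a <- p_mean * cfg$meth_overdispersion
    b <- (1 - p_mean) * cfg$meth_overdispersion
    meth[m_i, ] <- rbinom(ncol(meth), cfg$meth_coverage, rbeta(ncol(meth), a, b))
  }

  ## --- TF cooperation edges, pathways, ground truth -----------------------
  tf_edges <- map_dfr(seq_len(cfg$n_cell_groups), function(g) {
    members <- tfs[active_group == g]
    if (length(members) < 2) return(NULL)
    tibble(from = members[-length(members)], to = members[-1], weight = 1)
  })
  pathways <- setNames(
    lapply(seq_len(n_casc), function(c_i)
      gene_tbl$id[!is.na(gene_tbl$cascade) & gene_tbl$cascade == c_i]),
    paste0("CASCADE_", tfs))
  pathways <- pathways[lengths(pathways) > 0]

  truth <- list(
    tf_gene = tibble(
      tf = tfs[casc_of_gene],
      gene = gene_tbl$id[!is.na(gene_tbl$cascade)]),
    tf_peak = tibble(
      tf = tfs[casc_of_peak],
      peak = peak_tbl$id[!is.na(peak_tbl$cascade)]),
    gene_peak = map_dfr(seq_len(n_casc), function(c_i) {
      crossing(gene = gene_tbl$id[!is.na(gene_tbl$cascade) &
                                    gene_tbl$cascade == c_i],
               peak = peak_tbl$id[!is.na(peak_tbl$cascade) &
                                    peak_tbl$cascade == c_i])
    }))

  structure(
    list(config = cfg, genome = genome, tfs = tfs, motifs = motifs,
         peaks = peak_tbl, genes = gene_tbl, regions_methyl = regions,
         rna = count_matrix(rna, "rna"),
         atac = count_matrix(atac, "atac"),
         methylation = count_matrix(meth, "methylation"),
         cell_groups = list(rna = cells_rna, atac = cells_atac,
                            methylation = cells_meth),
         tf_edges = tf_edges, pathways = pathways, truth = truth),
    class = "scrw_bundle")
}

#' @export
print.scrw_bundle <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<synthetic multi-omics bundle> %d TFs, %d peaks, %d genes, %d methylation regions\n",
    cfg$n_tfs, cfg$n_peaks, cfg$n_genes, cfg$n_regions_methyl))
  cat(sprintf("  cells (unpaired): rna %d, atac %d, methylation %d; %d groups; seed %d\n",
              ncol(x$rna$counts), ncol(x$atac$counts),
              ncol(x$methylation$counts), cfg$n_cell_groups, cfg$seed))
  invisible(x)
}

#' Subsample one cell group in one omic
#'
#' Deterministically (given the bundle's seed) retains `fraction` of the
#' cells of the named group in the named omic, leaving everything else --
#' other groups, other omics, annotations, ground truth -- untouched.
#' Used to emulate unbalanced cell-type proportions across omics and test
#' robustness of the reconstruction.
#'
#' @param bundle An `scrw_bundle`.
#' @param omic `"rna"`, `"atac"` or `"methylation"`.
#' @param group Cell-group index to subsample.
#' @param fraction Fraction of the group's cells to keep, in (0, 1];
#'   `fraction = 1` returns the bundle unchanged.
#' @return The perturbed `scrw_bundle`.
#' @export
perturb_cell_groups <- function(bundle, omic, group, fraction) {
  stopifnot(is(bundle, "scrw_bundle"),
            omic %in% c("rna", "atac", "methylation"),
            fraction > 0, fraction <= 1)
  groups <- bundle$cell_groups[[omic]]
  if (!group %in% groups$group) {
    abort(sprintf("perturb_cell_groups: no cells of group %s in omic '%s'",
                  group, omic))
  }
  if (fraction == 1) return(bundle)
  in_group <- which(groups$group == group)
  n_keep <- floor(fraction * length(in_group))
  drop <- withr::with_seed(
    bundle$config$seed + 1000L * match(omic, c("rna", "atac", "methylation")) +
      as.integer(group),
    sample(in_group, length(in_group) - n_keep))
  keep <- setdiff(seq_len(nrow(groups)), drop)
  bundle[[omic]] <- count_matrix(bundle[[omic]]$counts[, keep, drop = FALSE],
                                 bundle[[omic]]$omic)
  bundle$cell_groups[[omic]] <- groups[keep, , drop = FALSE]
  bundle
}

#' Write a bundle to disk in standard formats
#'
#' Emits exactly the formats the pipeline readers consume: MTX + sidecars
#' (or dense TSV) per omic, BED for peaks and methylation regions, a gene
#' TSV, genome FASTA, JASPAR-format motifs, a TF--TF TSV, GMT pathway sets
#' and the ground-truth TSVs.
#'
#' @param bundle An `scrw_bundle`.
#' @param dir Output directory (created if needed).
#' @param matrix_format `"mtx"` or `"tsv"`.
#' @return Invisibly, `dir`.
#' @export
write_multiome_bundle <- function(bundle, dir, matrix_format = c("mtx", "tsv")) {
  matrix_format <- match.arg(matrix_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (om in c("rna", "atac", "methylation")) {
    sub <- file.path(dir, om)
    dir.create(sub, showWarnings = FALSE)
    ext <- if (matrix_format == "mtx") "matrix.mtx" else "matrix.tsv"
    write_count_matrix(bundle[[om]], file.path(sub, ext), matrix_format)
    readr::write_tsv(bundle$cell_groups[[om]], file.path(sub, "cell_groups.tsv"))
  }
  write_bed(bundle$peaks, file.path(dir, "peaks.bed"))
  write_bed(bundle$regions_methyl, file.path(dir, "regions_methyl.bed"))
  readr::write_tsv(bundle$genes[c("id", "chrom", "tss", "strand")],
                   file.path(dir, "genes.tsv"))
  write_fasta(bundle$genome, file.path(dir, "genome.fa"))
  write_motifs_jaspar(bundle$motifs, file.path(dir, "motifs.jaspar"))
  readr::write_tsv(bundle$tf_edges, file.path(dir, "tf_edges.tsv"))
  write_gmt(bundle$pathways, file.path(dir, "pathways.gmt"))
  readr::write_tsv(bundle$truth$tf_gene, file.path(dir, "truth_tf_gene.tsv"))
  readr::write_tsv(bundle$truth$tf_peak, file.path(dir, "truth_tf_peak.tsv"))
  readr::write_tsv(bundle$truth$gene_peak, file.path(dir, "truth_gene_peak.tsv"))
  invisible(dir)
}
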