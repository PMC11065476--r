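#' Construct a genomic feature set
#'
#' A tibble of genomic intervals in BED convention: 0-based start, exclusive
#' end, strand in `+`, `-` or `.`. Used for peaks, methylation regions and
#' gene bodies.
#'
#' @param id,chrom Character vectors.
#' @param start,end Integer coordinates, `start < end`, 0-based half-open.
#' @param strand Strand, defaults to `"."`.
#' @return Tibble of class `scrw_features` with columns `id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
feature_set <- function(id, chrom, start, end, strand = ".") {
  out <- tibble(id = as.character(id), chrom = as.character(chrom),
                start = as.integer(start), end = as.integer(end),
                strand = rep_len(as.character(strand), length(id)))
  validate_features(out)
}

validate_features <- function(x) {
  stopifnot(all(c("id", "chrom", "start", "end") %in% names(x)))
  if (!"strand" %in% names(x)) x$strand <- "."
  if (anyDuplicated(x$id)) abort("feature ids must be unique")
  if (any(x$start >= x$end)) {
    bad <- x$id[x$start >= x$end][1]
    abort(sprintf("feature '%s': start must be < end (0-based half-open)", bad))
  }
  if (!all(x$strand %in% c("+", "-", "."))) {
    abort("strand must be one of '+', '-', '.'")
  }
  x <- as_tibble(x[c("id", "chrom", "start", "end", "strand")])
  class(x) <- unique(c("scrw_features", class(x)))
  x
}

#' Read a BED file into a feature set
#'
#' Minimal BED reader: columns chrom, start, end, optional name, optional
#' score, optional strand. Missing names are synthesized as
#' `chrom:start-end`; missing strands default to `"."`.
#'
#' @param path BED file path.
#' @return An [feature_set()] tibble.
#' @export
read_bed <- function(path) {
  tb <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        comment = "#")
  if (ncol(tb) < 3) abort("read_bed: need at least chrom, start, end")
  out <- tibble(
    chrom = as.character(tb[[1]]),
    start = as.integer(tb[[2]]),
    end = as.integer(tb[[3]]),
    id = if (ncol(tb) >= 4) as.character(tb[[4]]) else
      paste0(tb[[1]], ":", tb[[2]], "-", tb[[3]]),
    strand = if (ncol(tb) >= 6) as.character(tb[[6]]) else "."
  )
  validate_features(out)
}

#' @rdname read_bed
#' @param x Feature set to write.
#' @export
write_bed <- function(x, path) {
  x <- validate_features(x)
  readr::write_tsv(
    tibble(chrom = x$chrom, start = x$start, end = x$end, id = x$id,
           score = 0L, strand = x$strand),
    path, col_names = FALSE)
  invisible(path)
}

#' Parse peak ids of the form "chrom:start-end" into a feature set
#'
#' Accepts `chr1:100-200` and `chr1-100-200`; coordinates are taken as
#' BED-convention 0-based half-open.
#'
#' @param ids Character vector of peak ids.
#' @return An [feature_set()] tibble (ids preserved).
#' @export
parse_peak_ids <- function(ids) {
  m <- stringr::str_match(ids, "^(.+?)[:-](\\d+)-(\\d+)$")
  if (anyNA(m[, 1])) {
    abort(sprintf("unparseable peak id(s): %s",
                  paste(head(ids[is.na(m[, 1])], 5), collapse = ", ")))
  }
  feature_set(ids, m[, 2], as.integer(m[, 3]), as.integer(m[, 4]))
}

#' Read a gene annotation table
#'
#' Expects a TSV with columns (in order or by name) gene id, chromosome,
#' TSS position and strand. A `tss` given with 1-based convention can be
#' converted by the caller; internally all coordinates are 0-based.
#'
#' @param path TSV path with header.
#' @return Tibble `id`, `chrom`, `tss`, `strand`.
#' @export
read_gene_table <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  nm <- names(tb)
  pick <- function(want, i) if (want %in% nm) tb[[want]] else tb[[i]]
  out <- tibble(id = as.character(pick("id", 1)),
                chrom = as.character(pick("chrom", 2)),
                tss = as.integer(pick("tss", 3)),
                strand = as.character(pick("strand", 4)))
  if (anyDuplicated(out$id)) abort("read_gene_table: duplicate gene ids")
  out
}

#' Turn a gene table into anchored gene features
#'
#' Builds fixed-width gene intervals from TSS positions so genes can enter
#' [link_by_proximity()]: for `+`/`.` genes the interval starts at the TSS;
#' for `-` genes it ends just after the TSS (TSS = `end - 1` in BED
#' convention).
#'
#' @param genes Tibble `id`, `chrom`, `tss`, `strand`.
#' @param body_width Width of the synthesized interval in bp.
#' @return An [feature_set()] tibble.
#' @export
gene_features <- function(genes, body_width = 1000L) {
  minus <- genes$strand == "-"
  start <- ifelse(minus, pmax(0L, genes$tss + 1L - body_width), genes$tss)
  end <- ifelse(minus, genes$tss + 1L, genes$tss + body_width)
  feature_set(genes$id, genes$chrom, start, end, genes$strand)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT path: one set per line, tab-separated
#'   `name  description  gene1  gene2 ...`.
#' @return Named list of character vectors (set name to genes).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) abort("read_gmt: each line needs name, description, >=1 gene")
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[[`, "", 1L))
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param description Optional vector of set descriptions.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  description <- description %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read / write genome sequences as FASTA
#'
#' Convenience wrappers around Biostrings.
#'
#' @param path FASTA path.
#' @return `read_fasta()` returns a `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @param x A `DNAStringSet` or named character vector of sequences.
#' @export
write_fasta <- function(x, path) {
  if (!is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Extract feature sequences from a genome
#'
#' @param genome Named `DNAStringSet` (one entry per chromosome) or named
#'   character vector.
#' @param features An [feature_set()] tibble (BED coordinates).
#' @return Named character vector of sequences, one per feature id.
#' @export
extract_sequences <- function(genome, features) {
  features <- validate_features(features)
  if (!is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  missing <- setdiff(unique(features$chrom), names(genome))
  if (length(missing) > 0) {
    abort(sprintf("extract_sequences: chromosomes absent from genome: %s",
                  paste(missing, collapse = ", ")))
  }
  seqs <- vapply(seq_len(nrow(features)), function(i) {
    as.character(Biostrings::subseq(genome[[features$chrom[i]]],
                                    start = features$start[i] + 1L,
                                    end = features$end[i]))
  }, "")
  setNames(seqs, features$id)
}
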