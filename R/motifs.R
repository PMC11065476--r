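#' Construct a TF binding motif model
#'
#' A position count matrix over the DNA alphabet, with a pseudocount and
#' background base probabilities. Scoring is log2 odds: column `j` of the
#' score matrix is `log2(((count[b,j] + p) / (total_j + 4p)) / background[b])`.
#'
#' @param id Motif identifier.
#' @param counts Numeric 4-by-width matrix, rows A, C, G, T (rownames
#'   optional but, when present, must be a permutation of ACGT).
#' @param tf Name(s) of the TF(s) the motif belongs to (default `id`).
#' @param pseudocount Positive pseudocount `p` added per cell.
#' @param background Base probabilities (A, C, G, T), default uniform.
#' @return Object of class `scrw_motif`.
#' @export
motif <- function(id, counts, tf = id, pseudocount = 0.01,
                  background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) abort("motif: counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 1) abort("motif: empty motif (zero width)")
  if (is.null(rownames(counts))) {
    rownames(counts) <- c("A", "C", "G", "T")
  } else {
    if (!setequal(rownames(counts), c("A", "C", "G", "T"))) {
      abort("motif: count matrix rows must be named A, C, G, T")
    }
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    abort("motif: counts must be finite and non-negative")
  }
  stopifnot(pseudocount > 0, length(background) == 4, all(background > 0))
  structure(list(id = id, tf = tf, counts = counts,
                 pseudocount = pseudocount,
                 background = background / sum(background)),
            class = "scrw_motif")
}

#' @export
print.scrw_motif <- function(x, ...) {
  cat(sprintf("<motif '%s'> TF %s, width %d, consensus %s\n", x$id,
              paste(x$tf, collapse = "/"), ncol(x$counts), consensus(x)))
  invisible(x)
}

consensus <- function(m) {
  paste(rownames(m$counts)[apply(m$counts, 2, which.max)], collapse = "")
}

# 4 x width log2-odds score matrix
score_matrix <- function(m) {
  p <- m$pseudocount
  tot <- colSums(m$counts) + 4 * p
  freq <- sweep(m$counts + p, 2, tot, "/")
  log2(freq / m$background)
}

#' Maximum attainable log-odds score of a motif
#'
#' @param m An [motif()].
#' @return Scalar: the score of the best-matching sequence window.
#' @export
max_score <- function(m) sum(apply(score_matrix(m), 2, max))

#' Scan sequences for motif occurrences
#'
#' Scores every window of every sequence on both strands with the motif's
#' log2-odds matrix and reports windows reaching `rel_threshold` times the
#' motif's maximum attainable score. Windows containing `N` score `-Inf`
#' and never match. Reverse-strand hits are found by scanning with the
#' reverse-complemented score matrix, so reported positions are always
#' forward-strand window starts (1-based).
#'
#' @param seqs Named character vector of DNA sequences (or a
#'   `Biostrings::DNAStringSet`), alphabet `ACGTN`.
#' @param motifs A single [motif()] or list of motifs.
#' @param rel_threshold Fraction of the maximum attainable score in (0, 1].
#' @return Tibble `motif`, `tf`, `seq`, `pos`, `strand`, `score`, sorted by
#'   motif then sequence then position. Sequences shorter than the motif
#'   simply yield no hits.
#' @export
scan_motifs <- function(seqs, motifs, rel_threshold = 0.8) {
  if (is(seqs, "DNAStringSet") || is(seqs, "XStringSet")) {
    seqs <- setNames(as.character(seqs), names(seqs))
  }
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (is(motifs, "scrw_motif")) motifs <- list(motifs)
  stopifnot(length(motifs) > 0, rel_threshold > 0, rel_threshold <= 1)

  up <- toupper(seqs)
  if (any(grepl("[^ACGTN]", up))) {
    abort("scan_motifs: sequences must be over the alphabet A, C, G, T, N")
  }
  widths <- max(vapply(motifs, function(m) ncol(m$counts), 1L))
  # concatenate all sequences with N-runs as separators; one pass per motif
  sep <- strrep("N", widths)
  concat <- paste(up, collapse = sep)
  code <- match(strsplit(concat, "", fixed = TRUE)[[1]],
                c("A", "C", "G", "T"))        # N -> NA
  code[is.na(code)] <- 5L
  lens <- nchar(up)
  offsets <- cumsum(c(0L, head(lens + nchar(sep), -1L)))  # concat start - 1

  out <- map_dfr(motifs, function(m) {
    w <- ncol(m$counts)
    sm <- rbind(score_matrix(m), -Inf)  # 5th row: N
    thr <- rel_threshold * max_score(m)
    n_win <- length(code) - w + 1L
    if (n_win < 1L) return(NULL)
    hits <- map_dfr(c("+", "-"), function(strand) {
      smx <- if (strand == "+") sm else
        rbind(score_matrix(m)[4:1, w:1, drop = FALSE], -Inf)
      s <- numeric(n_win)
      for (j in seq_len(w)) {
        s <- s + smx[cbind(code[j:(j + n_win - 1L)], j)]
      }
      idx <- which(s >= thr & is.finite(s))
      if (length(idx) == 0L) return(NULL)
      si <- findInterval(idx, unname(offsets) + 1L)
      pos <- as.integer(idx - unname(offsets)[si])
      keep <- pos + w - 1L <= unname(lens)[si]  # window fully inside one sequence
      tibble(motif = m$id, tf = m$tf[1], seq = names(seqs)[si[keep]],
             pos = pos[keep], strand = strand, score = unname(s[idx][keep]))
    })
    hits
  })
  if (nrow(out) == 0) {
    return(tibble(motif = character(), tf = character(), seq = character(),
                  pos = integer(), strand = character(), score = double()))
  }
  arrange(out, .data$motif, .data$seq, .data$pos, .data$strand)
}

#' Read motifs in JASPAR PFM format
#'
#' Parses blocks of the form
#' \preformatted{>MA0001.1 TFNAME
#' A [ 10  0  3 ]
#' C [  0 12  1 ]
#' G [  2  0  8 ]
#' T [  0  0  0 ]}
#' (brackets and row letters optional).
#'
#' @param path PFM file path.
#' @param pseudocount,background Passed to [motif()].
#' @return List of [motif()] objects.
#' @export
read_motifs_jaspar <- function(path, pseudocount = 0.01,
                               background = rep(0.25, 4)) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) abort("read_motifs_jaspar: no '>' headers found")
  ends <- c(heads[-1] - 1L, length(lines))
  purrr::map2(heads, ends, function(h, e) {
    hdr <- strsplit(sub("^>\\s*", "", lines[h]), "\\s+")[[1]]
    body <- lines[(h + 1):e]
    if (length(body) != 4) {
      abort(sprintf("read_motifs_jaspar: motif '%s' needs exactly 4 matrix rows", hdr[1]))
    }
    rows <- lapply(body, function(ln) {
      ln <- gsub("[][]", " ", ln)
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
      if (toks[1] %in% c("A", "C", "G", "T")) toks <- toks[-1]
      as.numeric(toks)
    })
    letters4 <- vapply(body, function(ln)
      substr(trimws(ln), 1, 1), "")
    counts <- do.call(rbind, rows)
    rownames(counts) <- if (all(letters4 %in% c("A", "C", "G", "T")))
      letters4 else c("A", "C", "G", "T")
    motif(hdr[1], counts, tf = if (length(hdr) > 1) hdr[2] else hdr[1],
          pseudocount = pseudocount, background = background)
  })
}

#' @rdname read_motifs_jaspar
#' @param motifs List of motifs to write.
#' @export
write_motifs_jaspar <- function(motifs, path) {
  if (is(motifs, "scrw_motif")) motifs <- list(motifs)
  lines <- unlist(lapply(motifs, function(m) {
    c(paste0(">", m$id, " ", m$tf[1]),
      vapply(c("A", "C", "G", "T"), function(b) {
        sprintf("%s [ %s ]", b,
                paste(format(m$counts[b, ], trim = TRUE), collapse = " "))
      }, ""))
  }))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections;
#' probabilities are converted to counts using the stated `nsites` (or 100
#' when absent).
#'
#' @inheritParams read_motifs_jaspar
#' @return List of [motif()] objects.
#' @export
read_motifs_meme <- function(path, pseudocount = 0.01,
                             background = rep(0.25, 4)) {
  lines <- readr::read_lines(path)
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0) abort("read_motifs_meme: no MOTIF blocks found")
  lapply(starts, function(st) {
    hdr <- strsplit(trimws(lines[st]), "\\s+")[[1]]
    lp <- st + grep("^letter-probability matrix",
                    lines[(st + 1):length(lines)])[1]
    spec <- lines[lp]
    get_num <- function(key, default) {
      m <- stringr::str_match(spec, paste0(key, "=\\s*(\\S+)"))[, 2]
      if (is.na(m)) default else as.numeric(m)
    }
    w <- get_num("w", NA)
    nsites <- get_num("nsites", 100)
    rows <- list(); i <- lp + 1
    while (i <= length(lines) &&
           grepl("^\\s*[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}\\s*$", lines[i])) {
      rows[[length(rows) + 1]] <- as.numeric(strsplit(trimws(lines[i]),
                                                      "\\s+")[[1]])
      i <- i + 1
    }
    probs <- do.call(rbind, rows)   # width x 4
    if (!is.na(w) && nrow(probs) != w) {
      abort(sprintf("read_motifs_meme: motif '%s' declares w=%d but has %d rows",
                    hdr[2], w, nrow(probs)))
    }
    counts <- t(probs) * nsites
    rownames(counts) <- c("A", "C", "G", "T")
    motif(hdr[2], counts, tf = if (length(hdr) > 2) hdr[3] else hdr[2],
          pseudocount = pseudocount, background = background)
  })
}
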