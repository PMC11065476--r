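#' Peak co-accessibility layer configuration
#'
#' @param window Maximum distance in bp between peak interval midpoints for
#'   a candidate co-accessibility pair (same chromosome only). Default
#'   500 kb, the usual cis-interaction horizon.
#' @param tau Correlation threshold: pairs with Pearson correlation
#'   `<= tau` are dropped (`tau >= 0`; negative correlations are always
#'   dropped -- anti-correlation is not evidence of co-regulation, and the
#'   walk needs non-negative mass).
#' @param pseudo_cell_size Optional integer: aggregate cells into random
#'   pseudo-cells of this size (summing counts) before correlating, which
#'   stabilizes correlations on sparse binary accessibility. `NULL`
#'   disables aggregation.
#' @param seed Seed for the random pseudo-cell grouping.
#' @return List of class `scrw_peak_config`.
#' @export
peak_layer_config <- function(window = 5e5, tau = 0, pseudo_cell_size = NULL,
                              seed = 1L) {
  stopifnot(window > 0, tau >= 0)
  if (!is.null(pseudo_cell_size)) stopifnot(pseudo_cell_size >= 2)
  structure(list(window = window, tau = tau,
                 pseudo_cell_size = pseudo_cell_size, seed = as.integer(seed)),
            class = "scrw_peak_config")
}

#' Infer the peak co-accessibility layer from scATAC counts
#'
#' Candidate pairs are same-chromosome peaks whose interval midpoints lie
#' within `window` bp of each other; the edge weight is the Pearson
#' correlation of their (optionally pseudo-cell-aggregated) accessibility
#' profiles across cells. Pairs with correlation `<= tau` and negative
#' correlations are dropped. The resulting layer is undirected.
#'
#' @param x An `scrw_counts` with `omic == "atac"`.
#' @param peaks An [feature_set()] giving the genomic interval of every
#'   peak; ids must cover the feature ids of `x` (peak ids of the form
#'   `chrom:start-end` can be recovered with [parse_peak_ids()]).
#' @param config An [peak_layer_config()].
#' @param name Layer name (default `"ATAC"`).
#' @return An undirected [layer()] over all peaks of `x`.
#' @export
infer_peak_layer <- function(x, peaks, config = peak_layer_config(),
                             name = "ATAC") {
  stopifnot(is(x, "scrw_counts"))
  peaks <- validate_features(peaks)
  ids <- features(x)
  missing <- setdiff(ids, peaks$id)
  if (length(missing) > 0) {
    abort(sprintf("infer_peak_layer: no coordinates for peak(s): %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  m <- as.matrix(x$counts)
  if (!is.null(config$pseudo_cell_size)) {
    m <- aggregate_pseudo_cells(m, config$pseudo_cell_size, config$seed)
  }
  peaks <- peaks[match(ids, peaks$id), , drop = FALSE]
  mid <- (peaks$start + peaks$end) %/% 2L

  edges <- map_dfr(unique(peaks$chrom), function(ch) {
    sel <- which(peaks$chrom == ch)
    if (length(sel) < 2) return(NULL)
    sel <- sel[order(mid[sel])]
    cm <- suppressWarnings(cor(t(m[sel, , drop = FALSE])))
    cm[!is.finite(cm)] <- 0   # zero-variance profiles correlate with nothing
    pair <- which(upper.tri(cm), arr.ind = TRUE)
    d <- abs(mid[sel][pair[, 1]] - mid[sel][pair[, 2]])
    w <- cm[pair]
    keep <- d <= config$window & w > config$tau & w > 0
    tibble(from = ids[sel][pair[keep, 1]], to = ids[sel][pair[keep, 2]],
           weight = w[keep])
  })
  # canonical orientation for undirected edges
  if (nrow(edges) > 0) {
    flip <- edges$from > edges$to
    tmp <- edges$from[flip]; edges$from[flip] <- edges$to[flip]
    edges$to[flip] <- tmp
  }
  layer(name, edges = edges, nodes = ids, directed = FALSE)
}

aggregate_pseudo_cells <- function(m, size, seed) {
  n <- ncol(m)
  n_groups <- max(1L, n %/% size)
  grp <- withr::with_seed(seed, sample(rep_len(seq_len(n_groups), n)))
  agg <- vapply(seq_len(n_groups),
                function(g) rowSums(m[, grp == g, drop = FALSE]),
                numeric(nrow(m)))
  agg
}

#' Infer a generic coordinate-based omics layer
#'
#' Applies the windowed-correlation construction of [infer_peak_layer()] to
#' any omic whose features carry genomic coordinates -- e.g. methylation
#' regions from snmC data. This is what makes the multilayer extensible
#' beyond accessibility and expression: any additional omic enters as one
#' more correlation layer plus proximity links.
#'
#' @inheritParams infer_peak_layer
#' @param features Coordinates of the omic's features.
#' @param name Layer name (e.g. `"meC"`).
#' @return An undirected [layer()].
#' @export
infer_generic_layer <- function(x, features, config = peak_layer_config(),
                                name = "generic") {
  infer_peak_layer(x, features, config = config, name = name)
}
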