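#' Gene-layer inference configuration
#'
#' @param n_trees Trees per regression forest. The default 100 is sized for
#'   desk-scale matrices; raise it for production data.
#' @param keep_fraction Fraction `q` of all candidate (regulator, target)
#'   importances retained as edges, in (0, 1]. Default 0.05 keeps the layer
#'   sparse enough that walk mass follows strong regulatory evidence.
#' @param seed Base seed for the per-target forests; inference is
#'   byte-reproducible for a fixed seed.
#' @param normalize If `TRUE`, apply library-size normalization followed by
#'   `log1p` before fitting. Off by default: preprocessing belongs
#'   upstream, and the layer uses the expression values as provided.
#' @return List of class `scrw_gene_config`.
#' @export
gene_layer_config <- function(n_trees = 100L, keep_fraction = 0.05,
                              seed = 1L, normalize = FALSE) {
  stopifnot(n_trees >= 1, keep_fraction > 0, keep_fraction <= 1)
  structure(list(n_trees = as.integer(n_trees),
                 keep_fraction = keep_fraction, seed = as.integer(seed),
                 normalize = isTRUE(normalize)),
            class = "scrw_gene_config")
}

#' Infer the transcriptional-regulation (gene) layer from scRNA counts
#'
#' For each target gene, a tree-ensemble regression of its expression
#' profile on all other genes yields variable importances; the importance
#' of regulator `x` for target `y` becomes the weight of the directed edge
#' `x -> y`. Over all candidate pairs, only the top `keep_fraction` of
#' importances are retained (and only those strictly positive), giving a
#' directed weighted gene--gene layer. Genes with zero variance across
#' cells carry no information and end with degree zero, both as regulator
#' and as target.
#'
#' @param x An `scrw_counts` with `omic == "rna"`, at least 2 genes and 10
#'   cells.
#' @param config An [gene_layer_config()].
#' @param name Layer name (default `"RNA"`).
#' @return A directed [layer()] over all genes of `x`.
#' @export
infer_gene_layer <- function(x, config = gene_layer_config(), name = "RNA") {
  stopifnot(is(x, "scrw_counts"))
  if (x$omic != "rna") warn("infer_gene_layer: input is not tagged 'rna'")
  E <- t(as.matrix(x$counts))              # cells x genes
  if (ncol(E) < 2) abort("infer_gene_layer: need at least 2 genes")
  if (nrow(E) < 10) abort("infer_gene_layer: need at least 10 cells")
  if (all(E == 0)) abort("infer_gene_layer: all-zero expression matrix")
  if (config$normalize) {
    libsize <- rowSums(E)
    libsize[libsize == 0] <- 1
    E <- log1p(E / libsize * stats::median(libsize))
  }
  genes <- colnames(E)
  variable <- genes[matrixStats_colVars(E) > 0]
  imp <- map_dfr(seq_along(variable), function(i) {
    g <- variable[i]
    regulators <- setdiff(variable, g)
    if (length(regulators) == 0) return(NULL)
    fit <- ranger::ranger(
      x = as.data.frame(E[, regulators, drop = FALSE]), y = E[, g],
      num.trees = config$n_trees,
      mtry = max(1L, floor(sqrt(length(regulators)))),
      importance = "impurity", num.threads = 1,
      seed = config$seed + i, verbose = FALSE)
    v <- fit$variable.importance
    tibble(from = names(v), to = g, weight = unname(v))
  })
  n_candidates <- length(variable) * (length(variable) - 1L)
  n_keep <- ceiling(config$keep_fraction * n_candidates)
  imp <- imp[imp$weight > 0, , drop = FALSE]
  imp <- imp[c_order(-imp$weight, imp$from, imp$to), , drop = FALSE]
  imp <- head(imp, n_keep)
  layer(name, edges = imp, nodes = genes, directed = TRUE)
}

# column variances without an extra dependency
matrixStats_colVars <- function(m) {
  n <- nrow(m)
  if (n < 2) return(rep(0, ncol(m)))
  mu <- colMeans(m)
  colSums(sweep(m, 2, mu)^2) / (n - 1)
}
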