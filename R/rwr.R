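#' Random-walk-with-restart configuration
#'
#' @param restart Restart (teleport) probability `r` in (0, 1]. At every
#'   step the walker returns to the seed distribution with probability `r`
#'   and follows the transition operator with probability `1 - r`. Higher
#'   values keep scores local to the seeds; the default 0.7 is standard for
#'   biological network prioritization.
#' @param lambda Layer-jump probability: total transition mass a node sends
#'   to each adjacent layer it has bipartite links into (renormalized so the
#'   total jump mass never exceeds 1; see [build_transition()]).
#' @param tol L1 convergence tolerance of the power iteration. Rankings are
#'   sensitive near ties, hence the tight default.
#' @param max_iter Maximum number of power iterations before aborting.
#' @param included_layers Optional character vector restricting the walk to
#'   a subset of layers (`NULL` = all layers).
#' @return A list of class `scrw_rwr_config`.
#' @export
rwr_config <- function(restart = 0.7, lambda = 0.5, tol = 1e-10,
                       max_iter = 1000L, included_layers = NULL) {
  stopifnot(is.numeric(restart), length(restart) == 1L,
            restart > 0, restart <= 1,
            is.numeric(lambda), lambda > 0, lambda <= 1,
            is.numeric(tol), tol > 0, max_iter >= 1)
  structure(list(restart = restart, lambda = lambda, tol = tol,
                 max_iter = as.integer(max_iter),
                 included_layers = included_layers),
            class = "scrw_rwr_config")
}

#' Construct a seed (restart) distribution
#'
#' @param nodes Character vector of node ids -- either global ids
#'   (`"layer:node"`) or bare ids resolvable unambiguously in the operator's
#'   index.
#' @param mass Optional non-negative masses (recycled); normalized to sum 1
#'   at use.
#' @return Named numeric vector of class `scrw_seeds`.
#' @export
seed_set <- function(nodes, mass = 1) {
  stopifnot(length(nodes) > 0)
  mass <- rep_len(as.double(mass), length(nodes))
  if (any(mass < 0) || !any(mass > 0)) {
    abort("seed_set: masses must be non-negative with positive total")
  }
  structure(setNames(mass, as.character(nodes)), class = "scrw_seeds")
}

resolve_seeds <- function(seeds, index) {
  if (!is.numeric(seeds)) seeds <- seed_set(seeds)
  ids <- names(seeds)
  pos <- match(ids, index$gid)
  bare <- is.na(pos)
  if (any(bare)) {
    hits <- lapply(ids[bare], function(id) which(index$node == id))
    nhit <- lengths(hits)
    if (any(nhit == 0)) {
      abort(sprintf("seed node(s) not in operator index: %s",
                    paste(head(ids[bare][nhit == 0], 5), collapse = ", ")))
    }
    if (any(nhit > 1)) {
      abort(sprintf(
        "ambiguous bare seed id(s) present in several layers: %s (qualify as 'layer:node')",
        paste(head(ids[bare][nhit > 1], 5), collapse = ", ")))
    }
    pos[bare] <- unlist(hits)
  }
  s <- numeric(nrow(index))
  s[pos] <- s[pos] + as.double(seeds)
  s / sum(s)
}

# power iteration on a matrix of seed columns; returns scores matrix
rwr_matrix <- function(op, S, config) {
  r <- config$restart
  X <- S
  if (r == 1) return(S)
  dang <- op$dangling
  res <- rep(Inf, ncol(S))
  for (it in seq_len(config$max_iter)) {
    dm <- if (any(dang)) Matrix::colSums(X[dang, , drop = FALSE]) else
      numeric(ncol(X))
    X1 <- (1 - r) * (op$P %*% X + S %*% Matrix::Diagonal(x = dm)) + r * S
    X1 <- as.matrix(X1)
    res <- colSums(abs(X1 - X))
    X <- X1
    if (all(res <= config$tol)) {
      return(X)
    }
  }
  abort(sprintf(
    "rwr: no convergence within %d iterations (max L1 residual %.3e)",
    config$max_iter, max(res)))
}

#' Random walk with restart over a multilayer transition operator
#'
#' Computes the steady state of
#' `x = (1 - r) (P x + s * m_dangling) + r s`, where `P` is the
#' column-stochastic supra-transition operator, `s` the normalized seed
#' distribution and `m_dangling` the probability mass sitting on dangling
#' nodes (redirected to the seeds, preserving the seed-relative
#' interpretation of scores). The steady-state probability of a node
#' measures its closeness to the seeds through all intra- and inter-layer
#' paths.
#'
#' @param op An `scrw_transition` from [build_transition()].
#' @param seeds A [seed_set()], or a character vector of node ids (unit
#'   mass each).
#' @param config An [rwr_config()].
#' @return A tibble of class `scrw_scores` with columns `layer`, `node`,
#'   `score` summing to 1; the seed vector is kept in attribute `seeds`.
#' @examples
#' atac <- layer("ATAC", tibble::tibble(from = "p1", to = "p2", weight = 1))
#' ml <- assemble_multilayer(list(atac))
#' op <- build_transition(ml)
#' rwr(op, "p1", rwr_config(restart = 0.5))
#' @export
rwr <- function(op, seeds, config = rwr_config()) {
  stopifnot(is(op, "scrw_transition"))
  s <- resolve_seeds(seeds, op$index)
  X <- rwr_matrix(op, matrix(s, ncol = 1), config)
  scores_tbl(op, drop(X), s)
}

scores_tbl <- function(op, x, s) {
  out <- tibble(layer = op$index$layer, node = op$index$node,
                score = as.double(x))
  structure(out, seeds = s, class = c("scrw_scores", class(out)))
}

#' Dense linear-solve reference for [rwr()]
#'
#' Solves `(I - (1 - r) * Ptilde) x = r s` directly, with dangling-column
#' redirection to the seeds folded into `Ptilde`. Mathematically identical
#' to the fixed point of the power iteration; implemented as an independent
#' dense route for verification, and limited to 2000 nodes.
#'
#' @inheritParams rwr
#' @return Same contract as [rwr()].
#' @export
rwr_dense <- function(op, seeds, config = rwr_config()) {
  stopifnot(is(op, "scrw_transition"))
  n <- nrow(op$index)
  if (n > 2000) abort("rwr_dense: dense reference limited to 2000 nodes")
  r <- config$restart
  s <- resolve_seeds(seeds, op$index)
  Pt <- as.matrix(op$P)
  if (any(op$dangling)) Pt[, op$dangling] <- s
  x <- solve(diag(n) - (1 - r) * Pt, r * s)
  scores_tbl(op, x, s)
}

#' Rank the nodes of one layer by walk score
#'
#' Extracts the nodes of a single layer from a score vector and ranks them
#' by descending score, breaking ties lexicographically by node id (a
#' deterministic, reproducible order). Seed nodes belonging to the ranked
#' layer are excluded: a seed trivially scores highest and is not a
#' prediction. Scores are reported as-is (not renormalized within the
#' layer); rank order is unaffected by renormalization.
#'
#' @param scores An `scrw_scores` tibble from [rwr()].
#' @param layer Name of the layer to rank.
#' @return Tibble `node`, `score`, `rank`.
#' @export
rank_layer <- function(scores, layer) {
  stopifnot(inherits(scores, "scrw_scores"))
  if (!layer %in% scores$layer) abort(sprintf("unknown layer '%s'", layer))
  s <- attr(scores, "seeds")
  sub <- scores[scores$layer == layer, , drop = FALSE]
  if (!is.null(s) && length(s) == nrow(scores)) {
    seeded <- scores$node[s > 0 & scores$layer == layer]
    sub <- sub[!sub$node %in% seeded, , drop = FALSE]
  }
  sub <- sub[c_order(-sub$score, sub$node), c("node", "score")]
  sub$rank <- seq_len(nrow(sub))
  as_tibble(sub)
}
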