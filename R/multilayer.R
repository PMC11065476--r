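#' Assemble a heterogeneous multilayer network
#'
#' Combines intra-omics layers and bipartite inter-layer links into one
#' heterogeneous multilayer network. Every bipartite endpoint is validated
#' against the named layer; node ids are namespaced internally as
#' `"layer:node"`, so a gene that is also a TF legitimately appears as two
#' distinct nodes (one per layer).
#'
#' If the "layer graph" (layers as vertices, bipartite link sets as edges) is
#' disconnected, a warning is emitted: walkers seeded in one block can never
#' reach the other, and unreachable layers receive zero probability mass.
#'
#' @param layers List of [layer()] objects with unique names.
#' @param bipartites List of [bipartite_links()] objects.
#' @return Object of class `scrw_multilayer` with fields `layers` (named
#'   list) and `bipartites`.
#' @examples
#' tf <- tf_layer(c("tfA", "tfB"))
#' atac <- layer("ATAC", tibble::tibble(from = "p1", to = "p2", weight = 1))
#' ml <- assemble_multilayer(
#'   list(tf, atac),
#'   list(bipartite_links("TF", "ATAC",
#'                        tibble::tibble(from = "tfA", to = "p1")))
#' )
#' @export
assemble_multilayer <- function(layers, bipartites = list()) {
  if (is(layers, "scrw_layer")) layers <- list(layers)
  if (is(bipartites, "scrw_bipartite")) bipartites <- list(bipartites)
  stopifnot(length(layers) > 0, all(map_chr(layers, class) == "scrw_layer"))
  nm <- map_chr(layers, "name")
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate layer names: %s",
                  paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  names(layers) <- nm
  for (bp in bipartites) {
    stopifnot(is(bp, "scrw_bipartite"))
    for (side in c("layer_a", "layer_b")) {
      if (!bp[[side]] %in% nm) {
        abort(sprintf("bipartite references unknown layer '%s'", bp[[side]]))
      }
    }
    bad_a <- setdiff(bp$edges$from, layers[[bp$layer_a]]$nodes)
    bad_b <- setdiff(bp$edges$to, layers[[bp$layer_b]]$nodes)
    if (length(bad_a) || length(bad_b)) {
      ex <- bp$edges[bp$edges$from %in% bad_a | bp$edges$to %in% bad_b, ][1, ]
      abort(sprintf(
        "bipartite %s--%s: edge (%s, %s) references a node absent from its layer",
        bp$layer_a, bp$layer_b, ex$from, ex$to))
    }
  }
  ml <- structure(list(layers = layers, bipartites = bipartites),
                  class = "scrw_multilayer")
  if (length(layers) > 1) {
    lg <- igraph::make_empty_graph(n = length(nm), directed = FALSE)
    lg <- igraph::set_vertex_attr(lg, "name", value = nm)
    for (bp in bipartites) {
      if (nrow(bp$edges) > 0) {
        lg <- igraph::add_edges(lg, c(match(bp$layer_a, nm), match(bp$layer_b, nm)))
      }
    }
    if (igraph::count_components(lg) > 1) {
      warn("multilayer: layer graph is disconnected; walkers cannot cross between blocks and unreachable layers will receive zero probability mass")
    }
  }
  ml
}

#' @export
print.scrw_multilayer <- function(x, ...) {
  cat(sprintf("<multilayer> %d layers, %d bipartite link sets\n",
              length(x$layers), length(x$bipartites)))
  for (l in x$layers) {
    cat("  "); print(l)
  }
  for (bp in x$bipartites) {
    cat("  "); print(bp)
  }
  invisible(x)
}

#' @export
glance.scrw_multilayer <- function(x, ...) {
  tibble(
    n_layers = length(x$layers),
    n_nodes = sum(map_int(x$layers, ~ length(.x$nodes))),
    n_intra_edges = sum(map_int(x$layers, ~ nrow(.x$edges))),
    n_inter_edges = sum(map_int(x$bipartites, ~ nrow(.x$edges)))
  )
}

#' @export
tidy.scrw_multilayer <- function(x, ...) {
  intra <- map_dfr(x$layers, function(l) {
    mutate(l$edges, layer_from = l$name, layer_to = l$name, .before = 1)
  })
  inter <- map_dfr(x$bipartites, function(bp) {
    mutate(bp$edges, layer_from = bp$layer_a, layer_to = bp$layer_b, .before = 1)
  })
  bind_rows(intra, inter)
}

#' Restrict a multilayer to a subset of layers
#'
#' Keeps the named layers and only the bipartite link sets whose two
#' endpoints are both kept. Used to orient walks: e.g. predicting the peaks
#' bound by a TF explores only the TF and accessibility layers.
#'
#' @param ml An `scrw_multilayer`.
#' @param keep Character vector of layer names to retain.
#' @return An `scrw_multilayer` over the kept layers.
#' @export
subset_layers <- function(ml, keep) {
  stopifnot(is(ml, "scrw_multilayer"))
  unknown <- setdiff(keep, names(ml$layers))
  if (length(unknown) > 0) {
    abort(sprintf("subset_layers: unknown layer(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  if (length(keep) == 0) abort("subset_layers: 'keep' must be non-empty")
  keep <- names(ml$layers)[names(ml$layers) %in% keep]  # preserve order
  bps <- purrr::keep(ml$bipartites,
                     ~ .x$layer_a %in% keep && .x$layer_b %in% keep)
  suppressWarnings(assemble_multilayer(ml$layers[keep], bps))
}

#' Build the supra-transition operator of a multilayer
#'
#' Translates the multilayer into the column-stochastic operator the random
#' walker follows. From a node `v` in layer `l`, outgoing probability splits
#' as follows: each adjacent layer `m` for which `v` has at least one
#' bipartite link receives total mass `lambda` (distributed within the jump
#' proportionally to bipartite edge weight); `lambda` is renormalized to
#' `1/k` when `v` reaches `k > 1/lambda` adjacent layers so the total jump
#' mass never exceeds 1. The remaining mass is distributed over intra-layer
#' out-edges proportionally to weight. A node with no bipartite links spends
#' all its mass intra-layer; a node with bipartite links but no intra-layer
#' out-edges sends all its mass across (split equally among adjacent
#' layers); a node with neither is *dangling* -- its column is all-zero and
#' flagged, and the walker restarts from the seed distribution there.
#'
#' @param ml An `scrw_multilayer`.
#' @param config An [rwr_config()]; `included_layers` (if non-`NULL`)
#'   restricts the operator to those layers, and `lambda` sets the
#'   layer-jump probability.
#' @return Object of class `scrw_transition`: fields `P` (sparse
#'   column-stochastic matrix over global node ids, layers in declared order
#'   and nodes in lexicographic order within layer), `index` (tibble `gid`,
#'   `layer`, `node`) and `dangling` (logical).
#' @export
build_transition <- function(ml, config = rwr_config()) {
  stopifnot(is(ml, "scrw_multilayer"))
  if (!is.null(config$included_layers)) {
    ml <- subset_layers(ml, config$included_layers)
  }
  lambda <- config$lambda
  if (lambda <= 0 || lambda > 1) {
    abort("build_transition: layer-jump probability lambda must be in (0, 1]")
  }

  index <- map_dfr(ml$layers, function(l) {
    tibble(layer = l$name, node = l$nodes)
  })
  index <- mutate(index, gid = paste0(.data$layer, ":", .data$node))
  n <- nrow(index)
  gid_of <- setNames(seq_len(n), index$gid)

  # intra-layer out-edges, globally indexed
  intra <- map_dfr(ml$layers, function(l) {
    e <- l$edges
    if (nrow(e) == 0) return(tibble(src = integer(), dst = integer(), w = double()))
    if (!l$directed) {
      e <- bind_rows(e, tibble(from = e$to, to = e$from, weight = e$weight))
    }
    tibble(src = gid_of[paste0(l$name, ":", e$from)],
           dst = gid_of[paste0(l$name, ":", e$to)],
           w = e$weight)
  })
  # inter-layer links, both directions, tagged with the target layer
  inter <- map_dfr(ml$bipartites, function(bp) {
    e <- bp$edges
    if (nrow(e) == 0) {
      return(tibble(src = integer(), dst = integer(), w = double(),
                    tgt_layer = character()))
    }
    a <- gid_of[paste0(bp$layer_a, ":", e$from)]
    b <- gid_of[paste0(bp$layer_b, ":", e$to)]
    bind_rows(
      tibble(src = a, dst = b, w = e$weight, tgt_layer = bp$layer_b),
      tibble(src = b, dst = a, w = e$weight, tgt_layer = bp$layer_a)
    )
  })

  intra_tot <- rep(0, n); inter_deg <- rep(0L, n)
  if (nrow(intra) > 0) {
    agg <- summarise(group_by(intra, .data$src), tot = sum(.data$w))
    intra_tot[agg$src] <- agg$tot
  }
  if (nrow(inter) > 0) {
    adj <- summarise(group_by(inter, .data$src),
                     k = dplyr::n_distinct(.data$tgt_layer))
    inter_deg[adj$src] <- adj$k
  }
  has_intra <- intra_tot > 0
  k <- inter_deg
  lambda_eff <- ifelse(k > 0, pmin(lambda, 1 / k), 0)
  # per-adjacent-layer jump mass; all mass crosses when there is no intra edge
  jump_mass <- ifelse(k > 0, ifelse(has_intra, lambda_eff, 1 / k), 0)
  intra_mass <- ifelse(has_intra, 1 - k * jump_mass, 0)
  dangling <- !has_intra & k == 0

  trip <- list()
  if (nrow(intra) > 0) {
    trip$intra <- mutate(intra,
                         p = .data$w / intra_tot[.data$src] * intra_mass[.data$src])
  }
  if (nrow(inter) > 0) {
    grp_tot <- stats::ave(inter$w, inter$src, inter$tgt_layer, FUN = sum)
    inter$p <- inter$w / grp_tot * jump_mass[inter$src]
    trip$inter <- inter
  }
  trip <- bind_rows(trip)
  P <- Matrix::sparseMatrix(
    i = if (nrow(trip)) trip$dst else integer(),
    j = if (nrow(trip)) trip$src else integer(),
    x = if (nrow(trip)) trip$p else double(),
    dims = c(n, n), dimnames = list(index$gid, index$gid)
  )
  structure(list(P = P, index = index, dangling = dangling),
            class = "scrw_transition")
}

#' @export
print.scrw_transition <- function(x, ...) {
  cat(sprintf("<transition operator> %d nodes (%s), %d non-zeros, %d dangling\n",
              nrow(x$index), paste(unique(x$index$layer), collapse = "+"),
              Matrix::nnzero(x$P), sum(x$dangling)))
  invisible(x)
}
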