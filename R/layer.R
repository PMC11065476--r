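#' Construct an intra-omics network layer
#'
#' A layer is one omics-specific weighted graph of a heterogeneous multilayer
#' network: gene--gene transcriptional regulation, peak--peak co-accessibility,
#' TF--TF cooperation, and so on. Edges live entirely inside the layer;
#' connections between layers are carried by [bipartite_links()].
#'
#' Zero-weight edges are dropped at construction. Weights must be finite and
#' non-negative: downstream random walks interpret them as transition mass.
#'
#' @param name Layer name (unique within a multilayer), e.g. `"RNA"`.
#' @param edges Data frame with columns `from`, `to`, `weight` (weight may be
#'   omitted; it then defaults to 1). May be `NULL` or empty for a layer of
#'   isolated nodes, such as an unlinked TF layer.
#' @param nodes Character vector of node ids. Defaults to the ids appearing
#'   in `edges`; supply explicitly to include isolated nodes.
#' @param directed Logical; `TRUE` for layers whose edges have a regulatory
#'   direction (the gene layer), `FALSE` for symmetric evidence
#'   (co-accessibility). Undirected edges are traversed both ways by the walk.
#'
#' @return An object of class `scrw_layer`: a list with fields `name`,
#'   `nodes` (sorted character), `edges` (tibble `from`, `to`, `weight`) and
#'   `directed`.
#' @examples
#' layer("ATAC", tibble::tibble(from = "p1", to = "p2", weight = 0.8))
#' @export
layer <- function(name, edges = NULL, nodes = NULL, directed = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(nodes)) {
    # default node set from the edge list as supplied, before zero-weight
    # edges are dropped: an endpoint named by the caller stays a node
    raw <- normalize_edges(edges, drop_zero = FALSE)
    nodes <- union(raw$from, raw$to)
  } else {
    nodes <- as.character(nodes)
  }
  edges <- normalize_edges(edges)
  if (anyDuplicated(nodes)) {
    abort(sprintf("layer '%s': duplicated node ids: %s", name,
                  paste(head(unique(nodes[duplicated(nodes)]), 5), collapse = ", ")))
  }
  missing <- setdiff(union(edges$from, edges$to), nodes)
  if (length(missing) > 0) {
    abort(sprintf("layer '%s': edges reference undeclared nodes: %s",
                  name, paste(head(missing, 5), collapse = ", ")))
  }
  structure(
    list(name = name, nodes = c_sort(nodes), edges = edges,
         directed = isTRUE(directed)),
    class = "scrw_layer"
  )
}

normalize_edges <- function(edges, drop_zero = TRUE) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0)) {
    return(tibble(from = character(), to = character(), weight = double()))
  }
  stopifnot(is.data.frame(edges))
  if (!all(c("from", "to") %in% names(edges))) {
    abort("edges must have columns 'from' and 'to'")
  }
  if (!"weight" %in% names(edges)) edges$weight <- 1
  edges <- tibble(from = as.character(edges$from),
                  to = as.character(edges$to),
                  weight = as.double(edges$weight))
  if (anyNA(edges) || any(!is.finite(edges$weight))) {
    abort("edge weights must be finite and non-missing")
  }
  if (any(edges$weight < 0)) abort("edge weights must be non-negative")
  if (drop_zero) edges <- edges[edges$weight > 0, , drop = FALSE]
  arrange(edges, .data$from, .data$to)
}

#' @export
print.scrw_layer <- function(x, ...) {
  cat(sprintf("<layer '%s'> %d nodes, %d %s edges\n", x$name,
              length(x$nodes), nrow(x$edges),
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

#' Construct a transcription-factor layer
#'
#' The default TF layer contains only isolated TF nodes: all TF--target
#' information then flows through motif-based bipartite links, which keeps the
#' comparison between TFs unbiased by prior interaction knowledge. Supplying
#' `edges` (known TF--TF cooperation, e.g. dimerization partners) gives the
#' variant with an internally connected TF layer.
#'
#' @param tfs Character vector of TF ids.
#' @param edges Optional TF--TF edge data frame (`from`, `to`, `weight`);
#'   endpoints must be in `tfs`.
#' @param name Layer name, default `"TF"`.
#' @return An `scrw_layer` (undirected).
#' @export
tf_layer <- function(tfs, edges = NULL, name = "TF") {
  tfs <- as.character(tfs)
  if (length(tfs) == 0) abort("tf_layer: 'tfs' must be non-empty")
  edges <- normalize_edges(edges)
  bad <- setdiff(union(edges$from, edges$to), tfs)
  if (length(bad) > 0) {
    abort(sprintf("tf_layer: edge endpoints not in TF list: %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  layer(name, edges = edges, nodes = tfs, directed = FALSE)
}

#' Construct bipartite links between two layers
#'
#' Bipartite links carry the inter-omics evidence of the multilayer: TF to
#' peak edges from motif occurrences, peak to gene edges from genomic
#' proximity to the TSS, and so on. Endpoints are validated against the two
#' layers at [assemble_multilayer()] time.
#'
#' @param layer_a,layer_b Names of the two linked layers (must differ).
#' @param edges Data frame with columns `from` (node in `layer_a`), `to`
#'   (node in `layer_b`) and optional `weight` (default 1).
#' @return Object of class `scrw_bipartite`.
#' @export
bipartite_links <- function(layer_a, layer_b, edges) {
  stopifnot(is.character(layer_a), is.character(layer_b))
  if (identical(layer_a, layer_b)) {
    abort("bipartite_links: layer_a and layer_b must differ")
  }
  structure(
    list(layer_a = layer_a, layer_b = layer_b, edges = normalize_edges(edges)),
    class = "scrw_bipartite"
  )
}

#' @export
print.scrw_bipartite <- function(x, ...) {
  cat(sprintf("<bipartite %s -- %s> %d edges\n", x$layer_a, x$layer_b,
              nrow(x$edges)))
  invisible(x)
}

#' Read / write a layer as a TSV edge list
#'
#' Layers serialize as a 3-column TSV (`from`, `to`, `weight`) plus an
#' optional single-column node list capturing isolated nodes.
#'
#' @param path Edge-list TSV path.
#' @param name Layer name to assign.
#' @param nodes_path Optional node-list TSV (one id per line, no header).
#' @param directed Directedness flag of the layer.
#' @return `read_layer()` returns an `scrw_layer`; `write_layer()` invisibly
#'   returns `path`.
#' @export
read_layer <- function(path, name, nodes_path = NULL, directed = FALSE) {
  edges <- readr::read_tsv(path, col_types = "ccd")
  names(edges)[1:3] <- c("from", "to", "weight")
  nodes <- NULL
  if (!is.null(nodes_path)) {
    nodes <- readr::read_tsv(nodes_path, col_names = "node",
                             col_types = "c")$node
  }
  layer(name, edges = edges, nodes = nodes, directed = directed)
}

#' @rdname read_layer
#' @param x Layer to write.
#' @export
write_layer <- function(x, path, nodes_path = NULL) {
  stopifnot(is(x, "scrw_layer"))
  readr::write_tsv(x$edges, path)
  if (!is.null(nodes_path)) {
    readr::write_tsv(tibble(node = x$nodes), nodes_path, col_names = FALSE)
  }
  invisible(path)
}

#' @export
tidy.scrw_layer <- function(x, ...) {
  mutate(x$edges, layer = x$name, .before = 1)
}

#' @export
glance.scrw_layer <- function(x, ...) {
  tibble(layer = x$name, n_nodes = length(x$nodes), n_edges = nrow(x$edges),
         directed = x$directed)
}
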