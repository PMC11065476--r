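#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
tidy.scrw_scores <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "scrw_scores")
  attr(out, "seeds") <- NULL
  out
}

#' @export
glance.scrw_scores <- function(x, ...) {
  tibble(n_nodes = nrow(x), total = sum(x$score),
         n_zero = sum(x$score == 0),
         top_node = x$node[which.max(x$score)])
}

#' @export
tidy.scrw_ranking <- function(x, ...) as_tibble(unclass_tbl(x))

#' @export
glance.scrw_ranking <- function(x, ...) {
  seed_col <- attr(x, "seed_col") %||% names(x)[1]
  tibble(n_seeds = dplyr::n_distinct(x[[seed_col]]), n_rows = nrow(x))
}
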