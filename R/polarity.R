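#' Polarity arithmetic for signed causal links
#'
#' A causal loop diagram edge carries a polarity: `"+"` means cause and effect
#' move in the same direction, `"-"` that they move in opposite directions.
#' Polarities compose multiplicatively along a causal chain, so the net sign of
#' a path or loop is `"+"` exactly when it contains an even number of negative
#' links.
#'
#' @param signs Character vector of `"+"` / `"-"` polarities, in traversal
#'   order (order does not affect the product).
#' @return `polarity_product()`: a single `"+"` or `"-"`.
#' @examples
#' polarity_product(c("+", "+")) # "+"
#' polarity_product(c("+", "-")) # "-"
#' polarity_product(c("-", "-", "-")) # "-"
#' @export
polarity_product <- function(signs) {
  check_polarity(signs)
  if (sum(signs == "-") %% 2L == 0L) "+" else "-"
}

#' @rdname polarity_product
#' @details `path_net_polarity()` is the same product applied to the edges of a
#'   directed walk given as a data frame with `cause` and `effect` columns; it
#'   additionally checks that consecutive edges are contiguous
#'   (each edge's cause equals the previous edge's effect).
#' @param path_edges Data frame with columns `cause`, `effect`, `polarity`
#'   describing a directed walk.
#' @export
path_net_polarity <- function(path_edges) {
  stopifnot(is.data.frame(path_edges))
  if (nrow(path_edges) == 0L) {
    stop("path must contain at least one edge", call. = FALSE)
  }
  if (nrow(path_edges) > 1L) {
    ok <- path_edges$cause[-1L] == path_edges$effect[-nrow(path_edges)]
    if (!all(ok)) {
      i <- which(!ok)[1L]
      stop(sprintf(
        "edges do not form a contiguous walk: edge %d starts at '%s' but edge %d ends at '%s'",
        i + 1L, path_edges$cause[i + 1L], i, path_edges$effect[i]
      ), call. = FALSE)
    }
  }
  polarity_product(path_edges$polarity)
}

check_polarity <- function(signs) {
  bad <- !signs %in% c("+", "-")
  if (any(bad)) {
    stop(sprintf("invalid polarity '%s' (must be \"+\" or \"-\")", signs[bad][1L]),
      call. = FALSE
    )
  }
  invisible(signs)
}

#' Standardize a factor label
#'
#' Default normalization used when no synonym mapping applies: case-fold,
#' trim leading/trailing whitespace, and collapse internal whitespace runs to a
#' single underscore. Deterministic and auditable, so the same raw label always
#' yields the same canonical id.
#'
#' @param x Character vector of raw labels.
#' @return Character vector of normalized labels.
#' @examples
#' normalize_label("  Social   Isolation ") # "social_isolation"
#' @export
normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", "_", x)
}
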