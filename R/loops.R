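#' Enumerate simple feedback loops of a signed digraph
#'
#' Finds every simple directed cycle with at most `max_len` nodes. Each loop is
#' reported in canonical rotation (starting at its lexicographically smallest
#' node), so equal cycles compare equal regardless of discovery order, and the
#' inventory is sorted lexicographically by node sequence. When the same
#' ordered node pair carries both polarities in the input, every sign
#' combination along a node cycle is a distinct loop.
#'
#' Enumeration walks depth-first from each start node, restricted to nodes
#' that sort at or after the start; this visits each node cycle exactly once,
#' already in canonical rotation. If more than `max_count` loops exist the
#' partial inventory is returned with attribute `truncated = TRUE` and a
#' warning of class `cld_loops_truncated` — never a silent truncation.
#'
#' @param edges Edge tibble with `cause`, `effect`, `polarity` columns (other
#'   columns are ignored; multiple groups are treated as one edge set).
#' @param max_len Maximum cycle length in nodes (>= 2). Default 12: workshop
#'   CLD loops are short, and the cap bounds worst-case work on dense graphs.
#' @param max_count Abort threshold on the number of loops (default 1e5).
#' @return Tibble of class `cld_loops`: `loop_id`, `nodes` (list of character),
#'   `signs` (list of character), `length`, `n_negative`, `classification`
#'   (`"reinforcing"`/`"balancing"`).
#' @examples
#' r1 <- tibble::tibble(
#'   cause = c("trauma", "substance_abuse", "domestic_violence"),
#'   effect = c("substance_abuse", "domestic_violence", "trauma"),
#'   polarity = "+"
#' )
#' enumerate_loops(r1)
#' @export
enumerate_loops <- function(edges, max_len = 12L, max_count = 100000L) {
  if (max_len < 2L) stop("max_len must be >= 2", call. = FALSE)
  if (max_count < 1L) stop("max_count must be >= 1", call. = FALSE)
  stopifnot(is.data.frame(edges))
  edges <- as_tibble(edges)
  check_polarity(edges$polarity)
  self <- edges$cause == edges$effect
  if (any(self)) {
    stop(sprintf("self-edge not allowed: (%s -> %s)", edges$cause[self][1L], edges$effect[self][1L]),
      call. = FALSE
    )
  }

  nodes <- sort(unique(c(edges$cause, edges$effect)))
  n <- length(nodes)
  if (n == 0L) {
    return(empty_loops())
  }
  ci <- match(edges$cause, nodes)
  ei <- match(edges$effect, nodes)
  # per ordered pair: which signs are present
  pair_key <- paste(ci, ei)
  sign_sets <- split(edges$polarity, pair_key)
  sign_sets <- lapply(sign_sets, function(s) sort(unique(s)))
  adj <- vector("list", n)
  for (k in unique(pair_key)) {
    uv <- as.integer(strsplit(k, " ", fixed = TRUE)[[1L]])
    adj[[uv[1L]]] <- c(adj[[uv[1L]]], uv[2L])
  }
  adj <- lapply(adj, function(x) sort(unique(x)))

  cycles <- list() # integer node vectors, canonical rotation
  n_loops <- 0L # sign-expanded count
  truncated <- FALSE
  n_sign_options <- function(path) {
    # product over hops of number of available signs
    hops <- cbind(path, c(path[-1L], path[1L]))
    prod(vapply(seq_len(nrow(hops)), function(i) {
      length(sign_sets[[paste(hops[i, 1L], hops[i, 2L])]])
    }, numeric(1)))
  }

  for (s in seq_len(n)) {
    if (truncated) break
    # iterative DFS over nodes >= s, start s
    stack <- list(list(path = s, nbrs = adj[[s]][adj[[s]] >= s]))
    in_path <- rep(FALSE, n)
    in_path[s] <- TRUE
    while (length(stack) > 0L) {
      top <- stack[[length(stack)]]
      if (length(top$nbrs) == 0L) {
        in_path[top$path[length(top$path)]] <- FALSE
        stack[[length(stack)]] <- NULL
        next
      }
      v <- top$nbrs[1L]
      stack[[length(stack)]]$nbrs <- top$nbrs[-1L]
      if (v == s) {
        if (length(top$path) >= 2L) {
          cyc <- top$path
          n_loops <- n_loops + n_sign_options(cyc)
          if (n_loops > max_count) {
            truncated <- TRUE
            break
          }
          cycles[[length(cycles) + 1L]] <- cyc
        }
      } else if (!in_path[v] && v > s && length(top$path) < max_len) {
        in_path[v] <- TRUE
        stack[[length(stack) + 1L]] <- list(path = c(top$path, v), nbrs = adj[[v]][adj[[v]] >= s])
      }
    }
  }

  out <- expand_sign_loops(cycles, nodes, sign_sets)
  attr(out, "truncated") <- truncated
  if (truncated) {
    warning(
      structure(
        class = c("cld_loops_truncated", "warning", "condition"),
        list(
          message = sprintf(
            "loop enumeration capped at max_count = %d; inventory is partial",
            max_count
          ),
          call = NULL
        )
      )
    )
  }
  out
}

empty_loops <- function() {
  out <- tibble(
    loop_id = integer(), nodes = list(), signs = list(),
    length = integer(), n_negative = integer(), classification = character()
  )
  class(out) <- c("cld_loops", class(out))
  attr(out, "truncated") <- FALSE
  out
}

expand_sign_loops <- function(cycles, nodes, sign_sets) {
  if (length(cycles) == 0L) {
    return(empty_loops())
  }
  rows <- list()
  for (cyc in cycles) {
    labs <- nodes[cyc]
    hops_u <- cyc
    hops_v <- c(cyc[-1L], cyc[1L])
    opts <- lapply(seq_along(hops_u), function(i) sign_sets[[paste(hops_u[i], hops_v[i])]])
    grid <- expand.grid(rev(opts), stringsAsFactors = FALSE)
    grid <- grid[, rev(seq_along(opts)), drop = FALSE] # restore hop order
    for (r in seq_len(nrow(grid))) {
      signs <- as.character(unlist(grid[r, ], use.names = FALSE))
      rows[[length(rows) + 1L]] <- list(nodes = labs, signs = signs)
    }
  }
  node_key <- vapply(rows, function(r) paste(r$nodes, collapse = "\x1f"), character(1))
  sign_key <- vapply(rows, function(r) paste(r$signs, collapse = ""), character(1))
  ord <- order(node_key, sign_key, method = "radix")
  rows <- rows[ord]
  out <- tibble(
    loop_id = seq_along(rows),
    nodes = lapply(rows, `[[`, "nodes"),
    signs = lapply(rows, `[[`, "signs"),
    length = vapply(rows, function(r) length(r$nodes), integer(1)),
    n_negative = vapply(rows, function(r) sum(r$signs == "-"), integer(1)),
  )
  out$classification <- ifelse(out$n_negative %% 2L == 0L, "reinforcing", "balancing")
  class(out) <- c("cld_loops", class(out))
  out
}

#' Classify a feedback loop as reinforcing or balancing
#'
#' Uses the sign-product rule standard in system dynamics: a loop is
#' reinforcing when its polarity product is positive, i.e. when it contains an
#' even number of negative links, and balancing otherwise. The result is
#' invariant under rotation of the cycle.
#'
#' @param signs Character vector of edge polarities around the loop, or a list
#'   of such vectors (as in the `signs` column of [enumerate_loops()] output).
#' @return `"reinforcing"` or `"balancing"` (vectorized over a list input).
#' @examples
#' classify_loop(c("+", "+", "+")) # reinforcing
#' classify_loop(c("+", "-")) # balancing
#' @export
classify_loop <- function(signs) {
  if (is.list(signs)) {
    return(vapply(signs, classify_loop, character(1)))
  }
  check_polarity(signs)
  if (sum(signs == "-") %% 2L == 0L) "reinforcing" else "balancing"
}

#' Exogenous factors of a CLD
#'
#' A factor is exogenous when nothing inside the system causes it: it has
#' in-degree zero while (typically) influencing other factors. In the workshop
#' models systemic racism is the canonical example — not caused by the mapped
#' system, yet driving many factors in it.
#'
#' @param edges Edge tibble.
#' @return Sorted character vector of exogenous factor ids.
#' @export
exogenous_nodes <- function(edges) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) == 0L) {
    return(character(0))
  }
  nodes <- sort(unique(c(edges$cause, edges$effect)))
  sort(setdiff(nodes, unique(edges$effect)))
}

#' Edges participating in feedback
#'
#' Returns the edges that lie on at least one simple directed cycle. With no
#' self-edges, an edge u -> v lies on a cycle exactly when u and v belong to
#' the same strongly connected component of size >= 2, so membership is
#' decided by an SCC decomposition rather than full enumeration; the result
#' equals the union of edges over [enumerate_loops()] with unbounded length.
#'
#' @param edges Edge tibble.
#' @return The subset of input rows on feedback loops, sorted by
#'   `(cause, effect, polarity)`; all input columns preserved.
#' @export
feedback_edges <- function(edges) {
  stopifnot(is.data.frame(edges))
  edges <- as_tibble(edges)
  if (nrow(edges) == 0L) {
    return(edges)
  }
  g <- cld_igraph(edges)
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  keep <- memb[edges$cause] == memb[edges$effect] &
    comp$csize[memb[edges$cause]] >= 2L
  out <- edges[keep, , drop = FALSE]
  arrange(out, .data$cause, .data$effect, .data$polarity)
}

# igraph view of an edge tibble (node-pair level; parallel signed edges
# collapse to one arc, which is what connectivity questions need)
cld_igraph <- function(edges, extra_nodes = character(0)) {
  nodes <- sort(unique(c(edges$cause, edges$effect, extra_nodes)))
  pairs <- distinct(tibble(from = edges$cause, to = edges$effect))
  igraph::graph_from_data_frame(pairs, directed = TRUE, vertices = nodes)
}

#' Loop inventory report
#'
#' Machine-readable summary of an enumerated loop inventory, suitable for
#' [write_report()].
#'
#' @param loops A `cld_loops` tibble from [enumerate_loops()].
#' @return Named list: `n_loops`, `n_reinforcing`, `n_balancing`, `truncated`,
#'   and `loops` (one record per loop with the node cycle, signs and class).
#' @export
loop_report <- function(loops) {
  stopifnot(inherits(loops, "cld_loops"))
  list(
    n_loops = nrow(loops),
    n_reinforcing = sum(loops$classification == "reinforcing"),
    n_balancing = sum(loops$classification == "balancing"),
    truncated = isTRUE(attr(loops, "truncated")),
    loops = lapply(seq_len(nrow(loops)), function(i) {
      list(
        nodes = loops$nodes[[i]],
        signs = loops$signs[[i]],
        classification = loops$classification[i]
      )
    })
  )
}

#' @export
tidy.cld_loops <- function(x, ...) {
  out <- as_tibble(x)
  out$nodes <- vapply(out$nodes, paste, character(1), collapse = ">")
  out$signs <- vapply(out$signs, paste, character(1), collapse = "")
  out
}

#' @export
glance.cld_loops <- function(x, ...) {
  tibble(
    n_loops = nrow(x),
    n_reinforcing = sum(x$classification == "reinforcing"),
    n_balancing = sum(x$classification == "balancing"),
    max_length = if (nrow(x) > 0L) max(x$length) else NA_integer_,
    truncated = isTRUE(attr(x, "truncated"))
  )
}
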