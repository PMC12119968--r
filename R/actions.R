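#' Action-idea nodes of an aggregate model
#'
#' Action ideas are participant-proposed interventions recorded as factors and
#' flagged in the edge list; they are the candidate leverage points of the
#' mapped system.
#'
#' @param agg A `cld_aggregate` from [union_models()].
#' @return Sorted character vector of action-idea factor ids.
#' @export
find_action_nodes <- function(agg) {
  stopifnot(inherits(agg, "cld_aggregate"))
  factors <- attr(agg, "factors")
  sort(factors$id[factors$is_action_idea])
}

#' Signed pathways from action ideas into the core model
#'
#' For each action idea, enumerates the simple directed paths (at most
#' `max_path_len` edges) through the *aggregate* graph that end at a core
#' node, and the net polarity of each. Paths traverse the full union graph,
#' not just core edges, because participants attached interventions wherever
#' they could influence the system, including through low-support linkages.
#' An action's leverage is summarized two ways — the number of distinct
#' (action, core node) pairs reached and the number of distinct pathways —
#' since either is a defensible count of "influences"; both are always
#' reported.
#'
#' When a hop's factor pair carries both polarities in the aggregate, each
#' sign assignment yields a distinct pathway.
#'
#' @param agg A `cld_aggregate` from [union_models()].
#' @param core A `cld_core` extracted from `agg`.
#' @param max_path_len Maximum pathway length in edges (default 4).
#' @return Tibble of class `cld_action_influence`: `action`, `core_node`,
#'   `path` (list of node sequences), `net_polarity`, sorted lexicographically.
#'   [glance()] reports per-run totals; attribute `per_action` holds the
#'   per-action pair/pathway counts.
#' @export
action_influence <- function(agg, core, max_path_len = 4L) {
  stopifnot(inherits(agg, "cld_aggregate"), inherits(core, "cld_core"))
  if (max_path_len < 1L) stop("max_path_len must be >= 1", call. = FALSE)
  actions <- find_action_nodes(agg)
  core_nodes <- attr(core, "nodes")
  g <- cld_igraph(agg)
  sign_map <- split(agg$polarity, paste(agg$cause, agg$effect, sep = "\x1f"))

  rows <- list()
  for (a in actions) {
    if (!a %in% igraph::V(g)$name) next
    targets <- setdiff(intersect(core_nodes, igraph::V(g)$name), a)
    if (length(targets) == 0L) next
    paths <- igraph::all_simple_paths(g,
      from = a, to = targets, mode = "out",
      cutoff = max_path_len
    )
    for (p in paths) {
      s <- igraph::V(g)$name[p]
      if (!s[length(s)] %in% core_nodes) next
      # expand over parallel signs hop by hop
      hop_signs <- lapply(seq_len(length(s) - 1L), function(i) {
        sort(sign_map[[paste(s[i], s[i + 1L], sep = "\x1f")]])
      })
      grid <- expand.grid(hop_signs, stringsAsFactors = FALSE)
      for (r in seq_len(nrow(grid))) {
        path_signs <- as.character(unlist(grid[r, ], use.names = FALSE))
        net <- polarity_product(path_signs)
        rows[[length(rows) + 1L]] <- tibble(
          action = a,
          core_node = s[length(s)],
          path = list(s),
          signs = list(path_signs),
          net_polarity = net,
          path_len = length(s) - 1L
        )
      }
    }
  }
  out <- if (length(rows) == 0L) {
    tibble(
      action = character(), core_node = character(), path = list(),
      signs = list(), net_polarity = character(), path_len = integer()
    )
  } else {
    bind_rows(rows)
  }
  key <- vapply(out$path, function(s) paste(s, collapse = "\x1f"), character(1))
  skey <- vapply(out$signs, paste, character(1), collapse = "")
  out <- out[order(out$action, out$core_node, key, skey, method = "radix"), ]
  per_action <- out |>
    group_by(.data$action) |>
    summarise(
      n_core_nodes_reached = dplyr::n_distinct(.data$core_node),
      n_pathways = n(),
      .groups = "drop"
    ) |>
    arrange(.data$action)
  class(out) <- c("cld_action_influence", class(out))
  attr(out, "per_action") <- per_action
  attr(out, "max_path_len") <- as.integer(max_path_len)
  attr(out, "n_actions") <- length(actions)
  out
}

#' @export
glance.cld_action_influence <- function(x, ...) {
  pairs <- dplyr::distinct(as_tibble(x)[, c("action", "core_node")])
  tibble(
    n_actions = attr(x, "n_actions"),
    n_actions_with_influence = dplyr::n_distinct(x$action),
    n_pairs = nrow(pairs),
    n_pathways = nrow(x),
    max_path_len = attr(x, "max_path_len")
  )
}

#' @export
tidy.cld_action_influence <- function(x, ...) {
  out <- as_tibble(x)
  out$path <- vapply(out$path, paste, character(1), collapse = ">")
  out$signs <- vapply(out$signs, paste, character(1), collapse = "")
  out
}
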