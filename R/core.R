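#' Edges causally connected to the focal variable
#'
#' An edge is causally connected to the focal problem variable when it lies on
#' a directed path that ends at the focal node (the edge sits among its
#' causes) or starts at it (the edge sits among its consequences).
#' Equivalently, edge u -> v qualifies iff v reaches the focal (or is it), or
#' the focal reaches u (or is it). Both directions are included because the
#' focal problem is both an effect and a cause in workshop models (dementia
#' drives out-of-pocket expenses as well as being driven by risk factors).
#'
#' @param edges Edge tibble.
#' @param focal Focal factor id.
#' @return The qualifying subset of input rows, sorted by
#'   `(cause, effect, polarity)`.
#' @export
causal_connectivity <- function(edges, focal = NULL) {
  stopifnot(is.data.frame(edges))
  edges <- as_tibble(edges)
  focal <- cld_focal(edges, focal)
  if (nrow(edges) == 0L) {
    return(edges)
  }
  g <- cld_igraph(edges, extra_nodes = focal)
  anc <- names(igraph::subcomponent(g, focal, mode = "in")) # reach focal (incl. focal)
  desc <- names(igraph::subcomponent(g, focal, mode = "out")) # reached from focal
  keep <- edges$effect %in% anc | edges$cause %in% desc
  arrange(edges[keep, , drop = FALSE], .data$cause, .data$effect, .data$polarity)
}

#' Extract the consensus core model
#'
#' Implements the consensus filter for multi-group CLDs: keep the edges that
#' (a) at least `min_support` groups reported, and (b) either participate in a
#' feedback loop or are causally connected to the focal problem variable —
#' where (b) is evaluated *within the surviving edge set* and iterated to a
#' fixed point, because removing an edge can break a loop or a path that
#' previously justified another edge (this is what excludes incomplete
#' feedback loops). Nodes left without any edge drop out, which removes
#' exogenous stubs.
#'
#' @param agg A `cld_aggregate` from [union_models()].
#' @param min_support Minimum number of distinct supporting groups (default 2:
#'   agreement between at least two independently built models).
#' @param focal Focal factor id (defaults to the aggregate's).
#' @return Tibble of class `cld_core`: the surviving aggregate edges plus a
#'   `reason` column (`"feedback"`, `"focal_connected"`, or `"both"`).
#'   Attributes: `focal`, `min_support`, `nodes` (sorted surviving factor
#'   ids). [glance()] reports node/edge counts and reason breakdown.
#' @examples
#' edges <- tibble::tibble(
#'   group_id = rep(c("g1", "g2"), each = 3),
#'   cause = rep(c("a", "b", "dementia_risk"), 2),
#'   effect = rep(c("b", "dementia_risk", "a"), 2),
#'   polarity = "+"
#' )
#' core <- extract_core(union_models(edges, focal = "dementia_risk"))
#' glance(core)
#' @export
extract_core <- function(agg, min_support = 2L, focal = NULL) {
  stopifnot(inherits(agg, "cld_aggregate") || inherits(agg, "cld_core"))
  if (min_support < 1L) stop("min_support must be >= 1", call. = FALSE)
  focal <- focal %||% attr(agg, "focal", exact = TRUE)
  if (is.null(focal)) stop("focal variable missing", call. = FALSE)
  all_factors <- attr(agg, "factors")
  if (!is.null(all_factors) && !focal %in% all_factors$id) {
    stop(sprintf("focal '%s' absent from aggregate", focal), call. = FALSE)
  }

  kept <- as_tibble(agg)[as_tibble(agg)$support >= min_support, , drop = FALSE]
  repeat {
    if (nrow(kept) == 0L) break
    fb_key <- edge_key(feedback_edges(kept))
    fc_key <- edge_key(causal_connectivity(kept, focal))
    keys <- edge_key(kept)
    keep <- keys %in% union(fb_key, fc_key)
    if (all(keep)) {
      kept$reason <- dplyr::case_when(
        keys %in% fb_key & keys %in% fc_key ~ "both",
        keys %in% fb_key ~ "feedback",
        TRUE ~ "focal_connected"
      )
      break
    }
    kept <- kept[keep, , drop = FALSE]
  }
  if (nrow(kept) == 0L) kept$reason <- character(0)
  kept <- arrange(kept, .data$cause, .data$effect, .data$polarity)
  # a core is also a valid aggregate-shaped edge table, so re-extraction and
  # support-based reporting work on it directly
  class(kept) <- c("cld_core", "cld_aggregate", "tbl_df", "tbl", "data.frame")
  attr(kept, "focal") <- focal
  attr(kept, "min_support") <- as.integer(min_support)
  attr(kept, "nodes") <- sort(unique(c(kept$cause, kept$effect)))
  kept
}

edge_key <- function(edges) {
  if (nrow(edges) == 0L) {
    return(character(0))
  }
  paste(edges$cause, edges$effect, edges$polarity, sep = "\x1f")
}

#' @export
glance.cld_core <- function(x, ...) {
  tibble(
    n_nodes = length(attr(x, "nodes")),
    n_edges = nrow(x),
    n_feedback = sum(x$reason == "feedback"),
    n_focal_connected = sum(x$reason == "focal_connected"),
    n_both = sum(x$reason == "both"),
    min_support = attr(x, "min_support"),
    focal = attr(x, "focal")
  )
}

#' @export
tidy.cld_core <- function(x, ...) {
  out <- as_tibble(x)
  if ("supporting_groups" %in% names(out)) {
    out$supporting_groups <- vapply(out$supporting_groups, paste, character(1), collapse = ";")
  }
  out
}

#' Core model report
#'
#' Summary of an extracted core: node and edge counts, reason breakdown,
#' support histogram, and the loop inventory of the core itself.
#'
#' @param core A `cld_core` from [extract_core()].
#' @param max_loop_len Passed to [enumerate_loops()] for the core's inventory.
#' @return Named list suitable for [write_report()].
#' @export
core_report <- function(core, max_loop_len = 12L) {
  stopifnot(inherits(core, "cld_core"))
  loops <- if (nrow(core) > 0L) enumerate_loops(core, max_len = max_loop_len) else empty_loops()
  supp <- if (nrow(core) > 0L) table(core$support) else table(integer(0))
  list(
    focal = attr(core, "focal"),
    min_support = attr(core, "min_support"),
    n_nodes = length(attr(core, "nodes")),
    n_edges = nrow(core),
    reasons = list(
      feedback = sum(core$reason == "feedback"),
      focal_connected = sum(core$reason == "focal_connected"),
      both = sum(core$reason == "both")
    ),
    support_histogram = lapply(seq_along(supp), function(i) {
      list(support = as.integer(names(supp)[i]), n_edges = as.integer(supp[i]))
    }),
    loop_inventory = loop_report(loops)
  )
}

#' Indirect-path consensus on aggregate edges
#'
#' Asks whether groups that did not draw a given edge nevertheless encoded the
#' same causal claim through intervening factors: for each aggregate edge
#' `(cause, effect, polarity)`, a group lacking the direct edge counts as
#' indirect support when its own model contains a simple directed path
#' `cause -> ... -> effect` with at least one and at most `max_intermediates`
#' intervening nodes whose net sign (product of polarities along the path)
#' equals the edge's polarity. Witness paths are recorded, and indirect
#' support never modifies [extract_core()] output — it is a separate
#' consensus report.
#'
#' @param agg A `cld_aggregate` built from `edges`.
#' @param edges The per-group edge tibble that was aggregated into `agg`.
#' @param max_intermediates Maximum number of intervening nodes on a witness
#'   path (default 2, keeping witnesses interpretable).
#' @return Tibble of class `cld_consensus`: `cause`, `effect`, `polarity`,
#'   `direct_support`, `indirect_groups` (list), `effective_support`,
#'   `witnesses` (list of per-group witness node paths), sorted by consensus
#'   gain (`effective_support - direct_support`) descending, then
#'   lexicographically.
#' @export
indirect_path_consensus <- function(agg, edges, max_intermediates = 2L) {
  stopifnot(inherits(agg, "cld_aggregate"))
  edges <- as_cld_edges(edges)
  agg_groups <- attr(agg, "group_ids")
  model_groups <- sort(unique(edges$group_id))
  missing_groups <- setdiff(agg_groups, model_groups)
  if (length(missing_groups) > 0L) {
    stop(sprintf(
      "aggregate references group '%s' absent from the supplied models",
      missing_groups[1L]
    ), call. = FALSE)
  }

  by_group <- split(edges, edges$group_id)
  group_graphs <- lapply(by_group, cld_igraph)
  # per-group signed adjacency for polarity evaluation
  group_signs <- lapply(by_group, function(e) {
    split(e$polarity, paste(e$cause, e$effect, sep = "\x1f"))
  })

  rows <- purrr::map(seq_len(nrow(agg)), function(i) {
    cause <- agg$cause[i]
    effect <- agg$effect[i]
    pol <- agg$polarity[i]
    direct <- agg$supporting_groups[[i]]
    indirect <- character(0)
    witnesses <- list()
    for (g in setdiff(agg_groups, direct)) {
      w <- witness_path(
        group_graphs[[g]], group_signs[[g]], cause, effect, pol,
        max_intermediates
      )
      if (!is.null(w)) {
        indirect <- c(indirect, g)
        witnesses[[g]] <- w
      }
    }
    tibble(
      cause = cause, effect = effect, polarity = pol,
      direct_support = length(direct),
      indirect_groups = list(sort(indirect)),
      effective_support = length(direct) + length(indirect),
      witnesses = list(witnesses)
    )
  })
  out <- bind_rows(rows) |>
    mutate(gain = .data$effective_support - .data$direct_support) |>
    arrange(dplyr::desc(.data$gain), .data$cause, .data$effect, .data$polarity) |>
    select(-"gain")
  class(out) <- c("cld_consensus", class(out))
  attr(out, "max_intermediates") <- as.integer(max_intermediates)
  out
}

# shortest sign-consistent simple path cause -> effect with 1..k intermediates
# in one group's graph; NULL when none exists
witness_path <- function(graph, sign_map, cause, effect, polarity, max_intermediates) {
  vs <- igraph::V(graph)$name
  if (!cause %in% vs || !effect %in% vs || cause == effect) {
    return(NULL)
  }
  paths <- igraph::all_simple_paths(graph,
    from = cause, to = effect,
    mode = "out", cutoff = max_intermediates + 1L
  )
  if (length(paths) == 0L) {
    return(NULL)
  }
  # deterministic preference: shortest, then lexicographic node sequence
  seqs <- lapply(paths, function(p) igraph::V(graph)$name[p])
  seqs <- seqs[vapply(seqs, length, integer(1)) >= 3L] # >=1 intermediate
  if (length(seqs) == 0L) {
    return(NULL)
  }
  key <- vapply(seqs, function(s) paste(s, collapse = "\x1f"), character(1))
  seqs <- seqs[order(vapply(seqs, length, integer(1)), key, method = "radix")]
  for (s in seqs) {
    if (path_sign_achievable(sign_map, s, polarity)) {
      return(s)
    }
  }
  NULL
}

# can the hops of node sequence `s` be signed (choosing among parallel signs
# where both exist) so the product equals `polarity`?
path_sign_achievable <- function(sign_map, s, polarity) {
  achievable <- "+"
  for (i in seq_len(length(s) - 1L)) {
    signs <- sign_map[[paste(s[i], s[i + 1L], sep = "\x1f")]]
    nxt <- unique(unlist(lapply(achievable, function(a) {
      vapply(signs, function(sg) if (a == sg) "+" else "-", character(1))
    })))
    achievable <- nxt
  }
  polarity %in% achievable
}

#' @export
glance.cld_consensus <- function(x, ...) {
  tibble(
    n_edges = nrow(x),
    n_gained = sum(x$effective_support > x$direct_support),
    total_gain = sum(x$effective_support - x$direct_support),
    mean_direct = round(mean(x$direct_support), 2),
    mean_effective = round(mean(x$effective_support), 2)
  )
}

#' @export
tidy.cld_consensus <- function(x, ...) {
  out <- as_tibble(x)
  out$indirect_groups <- vapply(out$indirect_groups, paste, character(1), collapse = ";")
  out$witnesses <- vapply(out$witnesses, function(w) {
    paste(vapply(w, paste, character(1), collapse = ">"), collapse = ";")
  }, character(1))
  out
}
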