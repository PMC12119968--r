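#' Union model across workshop groups
#'
#' Builds the union set of all edges identified by all groups. Edge identity is
#' `(cause, effect, polarity)` — the same factor pair may carry both signs, and
#' both survive as distinct aggregate edges. Each aggregate edge records the
#' set of supporting groups (`support` = number of distinct groups, the
#' consensus measure used for core extraction) and the total instance count
#' before within-group deduplication when the caller supplies raw rows.
#'
#' @param edges Edge tibble covering all groups (typically
#'   [read_group_models()] output after [canonicalize_labels()]).
#' @param focal Focal factor id (defaults to the `focal` attribute).
#' @return Tibble of class `cld_aggregate` with columns `cause`, `effect`,
#'   `polarity`, `support`, `supporting_groups` (list of character),
#'   `instance_count`, `delay`, `cause_is_action`, `effect_is_action`, sorted
#'   by `(cause, effect, polarity)`. Attributes: `focal`, `group_ids`,
#'   `factors` (merged factor table with OR-ed action flags),
#'   `total_edge_instances`. Use [glance()] for the headline counts.
#' @examples
#' edges <- tibble::tibble(
#'   group_id = c("g1", "g2"), cause = "poverty", effect = "stress",
#'   polarity = "+"
#' )
#' agg <- union_models(edges, focal = "dementia_risk")
#' glance(agg)
#' @export
union_models <- function(edges, focal = NULL) {
  edges <- as_cld_edges(edges, focal = attr(edges, "focal", exact = TRUE))
  focal <- cld_focal(edges, focal)
  if (nrow(edges) == 0L) stop("no edges to aggregate", call. = FALSE)
  group_ids <- sort(unique(edges$group_id))

  merged_factors <- cld_factors(edges, focal) |>
    group_by(.data$id) |>
    summarise(is_action_idea = any(.data$is_action_idea), .groups = "drop") |>
    arrange(.data$id)

  out <- edges |>
    group_by(.data$cause, .data$effect, .data$polarity) |>
    summarise(
      support = dplyr::n_distinct(.data$group_id),
      supporting_groups = list(sort(unique(.data$group_id))),
      instance_count = n(),
      delay = any(.data$delay),
      .groups = "drop"
    ) |>
    left_join(
      rename(merged_factors, cause = "id", cause_is_action = "is_action_idea"),
      by = "cause"
    ) |>
    left_join(
      rename(merged_factors, effect = "id", effect_is_action = "is_action_idea"),
      by = "effect"
    ) |>
    arrange(.data$cause, .data$effect, .data$polarity)

  class(out) <- c("cld_aggregate", class(out))
  attr(out, "focal") <- focal
  attr(out, "group_ids") <- group_ids
  attr(out, "factors") <- merged_factors
  attr(out, "total_edge_instances") <- nrow(edges)
  out
}

#' @export
glance.cld_aggregate <- function(x, ...) {
  factors <- attr(x, "factors")
  tibble(
    n_groups = length(attr(x, "group_ids")),
    total_edge_instances = attr(x, "total_edge_instances"),
    n_unique_combinations = nrow(x),
    n_factors = nrow(factors),
    n_action_ideas = sum(factors$is_action_idea),
    n_edges_touching_action_ideas = sum(x$cause_is_action | x$effect_is_action),
    n_edges_from_action_ideas = sum(x$cause_is_action)
  )
}

#' @export
tidy.cld_aggregate <- function(x, ...) {
  out <- as_tibble(x)
  out$supporting_groups <- vapply(
    out$supporting_groups, paste, character(1),
    collapse = ";"
  )
  out
}

#' Per-group descriptive statistics
#'
#' Counts, for each group model, its factors (edge endpoints plus the focal
#' variable), edges (unique cause/effect/polarity combinations), and action
#' ideas (factors flagged as participant-proposed interventions). The attached
#' summary reports the mean (1 decimal) and min-max range of each column, the
#' format in which multi-group workshop studies describe their models.
#'
#' @inheritParams union_models
#' @return Tibble of class `cld_group_summary`: one row per group with
#'   `group_id`, `n_factors`, `n_edges`, `n_action_ideas`. [glance()] returns
#'   the mean/min/max summary row.
#' @export
summary_stats <- function(edges, focal = NULL) {
  edges <- as_cld_edges(edges, focal = attr(edges, "focal", exact = TRUE))
  focal <- cld_focal(edges, focal)
  if (nrow(edges) == 0L) stop("no edges to summarise", call. = FALSE)
  factors <- cld_factors(edges, focal)
  fcounts <- factors |>
    group_by(.data$group_id) |>
    summarise(
      n_factors = n(),
      n_action_ideas = sum(.data$is_action_idea),
      .groups = "drop"
    )
  ecounts <- edges |>
    distinct(.data$group_id, .data$cause, .data$effect, .data$polarity) |>
    count(.data$group_id, name = "n_edges")
  out <- left_join(fcounts, ecounts, by = "group_id") |>
    mutate(n_edges = ifelse(is.na(.data$n_edges), 0L, .data$n_edges)) |>
    select("group_id", "n_factors", "n_edges", "n_action_ideas") |>
    arrange(.data$group_id)
  class(out) <- c("cld_group_summary", class(out))
  out
}

#' @export
glance.cld_group_summary <- function(x, ...) {
  stat <- function(v) {
    list(
      mean = round(mean(v), 1), min = min(v), max = max(v),
      label = sprintf("%.1f (%d-%d)", round(mean(v), 1), min(v), max(v))
    )
  }
  f <- stat(x$n_factors)
  e <- stat(x$n_edges)
  a <- stat(x$n_action_ideas)
  tibble(
    n_groups = nrow(x),
    mean_factors = f$mean, min_factors = f$min, max_factors = f$max,
    mean_edges = e$mean, min_edges = e$min, max_edges = e$max,
    mean_action_ideas = a$mean, min_action_ideas = a$min, max_action_ideas = a$max,
    factors_label = f$label, edges_label = e$label, action_ideas_label = a$label
  )
}

#' Polarity disagreements between groups
#'
#' Lists every ordered factor pair that carries both a `"+"` and a `"-"` edge
#' in the aggregate — i.e. pairs where at least one group recorded the
#' opposite sign from another (or from itself; within-group contradictions are
#' retained, not resolved).
#'
#' @param agg A `cld_aggregate` tibble from [union_models()].
#' @return Tibble with columns `cause`, `effect`, `groups_plus`,
#'   `groups_minus` (list columns of group ids), sorted lexicographically;
#'   zero rows when no pair is contested.
#' @export
polarity_conflicts <- function(agg) {
  stopifnot(inherits(agg, "cld_aggregate"))
  pairs <- as_tibble(agg) |>
    group_by(.data$cause, .data$effect) |>
    filter(dplyr::n_distinct(.data$polarity) == 2L) |>
    ungroup()
  if (nrow(pairs) == 0L) {
    return(tibble(
      cause = character(), effect = character(),
      groups_plus = list(), groups_minus = list()
    ))
  }
  pairs |>
    group_by(.data$cause, .data$effect) |>
    summarise(
      groups_plus = list(sort(unique(unlist(.data$supporting_groups[.data$polarity == "+"])))),
      groups_minus = list(sort(unique(unlist(.data$supporting_groups[.data$polarity == "-"])))),
      .groups = "drop"
    ) |>
    arrange(.data$cause, .data$effect)
}
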