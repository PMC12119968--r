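#' @importFrom rlang .data %||%
#' @importFrom dplyr arrange distinct filter group_by mutate n rename select
#'   summarise ungroup across all_of bind_rows left_join anti_join semi_join
#'   row_number pull count
#' @importFrom tibble tibble as_tibble
NULL

edge_cols <- c(
  "group_id", "cause", "effect", "polarity", "delay",
  "cause_is_action", "effect_is_action"
)

# Coerce a user-supplied edge data frame to the canonical column set,
# filling optional columns with defaults. Validates polarity values.
as_cld_edges <- function(edges, focal = NULL) {
  stopifnot(is.data.frame(edges))
  edges <- as_tibble(edges)
  required <- c("cause", "effect", "polarity")
  missing <- setdiff(required, names(edges))
  if (length(missing) > 0L) {
    stop(sprintf("missing required column '%s'", missing[1L]), call. = FALSE)
  }
  if (!"group_id" %in% names(edges)) edges$group_id <- "g1"
  if (!"delay" %in% names(edges)) edges$delay <- FALSE
  if (!"cause_is_action" %in% names(edges)) edges$cause_is_action <- FALSE
  if (!"effect_is_action" %in% names(edges)) edges$effect_is_action <- FALSE
  edges <- edges |>
    mutate(
      group_id = as.character(.data$group_id),
      cause = as.character(.data$cause),
      effect = as.character(.data$effect),
      polarity = as.character(.data$polarity),
      delay = as.logical(.data$delay),
      cause_is_action = as.logical(.data$cause_is_action),
      effect_is_action = as.logical(.data$effect_is_action)
    ) |>
    select(all_of(edge_cols))
  check_polarity(edges$polarity)
  if (!is.null(focal)) attr(edges, "focal") <- focal
  edges
}

#' Focal problem variable of a set of CLD edges
#'
#' The focal variable (here typically dementia risk) is carried as an attribute
#' on edge tibbles returned by [read_group_models()] and preserved by the
#' pipeline verbs; `cld_focal()` retrieves it, falling back to an explicit
#' argument.
#'
#' @param edges Edge tibble.
#' @param focal Optional explicit focal id overriding the attribute.
#' @return Focal factor id (length-1 character).
#' @export
cld_focal <- function(edges, focal = NULL) {
  out <- focal %||% attr(edges, "focal", exact = TRUE)
  if (is.null(out) || !nzchar(out)) {
    stop("no focal variable: supply `focal` or use edges from read_group_models()",
      call. = FALSE
    )
  }
  as.character(out)
}

#' Per-group factor table of a CLD edge list
#'
#' Factors are inferred from edge endpoints; the focal variable is a member of
#' every group's factor set even when it has no incident edge in that group.
#' A factor is an action idea in a group if it is flagged as such on any
#' incident edge endpoint there.
#'
#' @inheritParams cld_focal
#' @return Tibble with columns `group_id`, `id`, `is_action_idea`, sorted by
#'   `(group_id, id)`.
#' @export
cld_factors <- function(edges, focal = NULL) {
  edges <- as_cld_edges(edges)
  focal <- cld_focal(edges, focal)
  long <- bind_rows(
    tibble(
      group_id = edges$group_id, id = edges$cause,
      is_action_idea = edges$cause_is_action
    ),
    tibble(
      group_id = edges$group_id, id = edges$effect,
      is_action_idea = edges$effect_is_action
    ),
    tibble(
      group_id = unique(edges$group_id), id = focal,
      is_action_idea = FALSE
    )
  )
  long |>
    group_by(.data$group_id, .data$id) |>
    summarise(is_action_idea = any(.data$is_action_idea), .groups = "drop") |>
    arrange(.data$group_id, .data$id)
}

#' Standardize factor labels across group models
#'
#' Applies a synonym map (raw label to canonical id) to every edge endpoint;
#' labels without a mapping fall back to [normalize_label()]. Factors that map
#' to the same canonical id merge: their action flags are OR-ed and duplicate
#' `(cause, effect, polarity)` edges produced by the merge collapse within each
#' group (delay flags OR-ed). The operation is idempotent and preserves every
#' input edge as exactly one output edge modulo collapse of exact duplicates.
#'
#' @param edges Edge tibble (one or more groups).
#' @param synonym_map `NULL`, a two-column data frame `(raw, canonical)`, or a
#'   named character vector `canonical <- map[raw]`. See [read_synonym_map()].
#' @param focal Optional focal id; it is canonicalized too and the result
#'   carries the canonical focal as its `focal` attribute.
#' @return Edge tibble with canonical labels; attribute `label_map` records the
#'   raw-to-canonical correspondence actually applied (columns `raw`,
#'   `canonical`).
#' @examples
#' edges <- tibble::tibble(
#'   group_id = "g1", cause = c("Health Literacy", "health literacy "),
#'   effect = c("Knowledge", "Stigma"), polarity = c("+", "-")
#' )
#' canonicalize_labels(edges, focal = "Dementia Risk")
#' @export
canonicalize_labels <- function(edges, synonym_map = NULL, focal = NULL) {
  edges <- as_cld_edges(edges)
  focal <- attr(edges, "focal", exact = TRUE) %||% focal
  map <- coerce_synonym_map(synonym_map)
  canon <- function(x) {
    key <- normalize_label(x)
    hit <- match(key, names(map))
    out <- ifelse(is.na(hit), key, unname(map[hit]))
    if (any(!nzchar(out))) {
      stop(sprintf("empty canonical label for raw label '%s'", x[!nzchar(out)][1L]),
        call. = FALSE
      )
    }
    out
  }
  new_cause <- canon(edges$cause)
  new_effect <- canon(edges$effect)
  selfed <- new_cause == new_effect
  if (any(selfed)) {
    i <- which(selfed)[1L]
    stop(sprintf(
      "canonicalization creates self-edge: raw labels '%s' and '%s' on edge (%s -> %s) both map to '%s'",
      edges$cause[i], edges$effect[i], edges$cause[i], edges$effect[i], new_cause[i]
    ), call. = FALSE)
  }
  label_map <- tibble(
    raw = c(edges$cause, edges$effect),
    canonical = c(new_cause, new_effect)
  ) |>
    distinct() |>
    arrange(.data$raw, .data$canonical)

  # action-flag merge: a canonical factor is an action idea in a group if any
  # raw label merged into it was flagged
  out <- edges |>
    mutate(cause = new_cause, effect = new_effect)
  flags <- cld_action_flags(out)
  out <- out |>
    select(-"cause_is_action", -"effect_is_action") |>
    left_join(rename(flags, cause = "id", cause_is_action = "is_action_idea"),
      by = c("group_id", "cause")
    ) |>
    left_join(rename(flags, effect = "id", effect_is_action = "is_action_idea"),
      by = c("group_id", "effect")
    ) |>
    group_by(.data$group_id, .data$cause, .data$effect, .data$polarity) |>
    summarise(
      delay = any(.data$delay),
      cause_is_action = any(.data$cause_is_action),
      effect_is_action = any(.data$effect_is_action),
      .groups = "drop"
    ) |>
    select(all_of(edge_cols)) |>
    arrange(.data$group_id, .data$cause, .data$effect, .data$polarity)
  attr(out, "label_map") <- label_map
  if (!is.null(focal)) {
    canon_focal <- canon(focal)
    attr(out, "focal") <- canon_focal
  }
  out
}

# per-(group, canonical id) action flag, OR-ed over endpoints
cld_action_flags <- function(edges) {
  bind_rows(
    tibble(
      group_id = edges$group_id, id = edges$cause,
      is_action_idea = edges$cause_is_action
    ),
    tibble(
      group_id = edges$group_id, id = edges$effect,
      is_action_idea = edges$effect_is_action
    )
  ) |>
    group_by(.data$group_id, .data$id) |>
    summarise(is_action_idea = any(.data$is_action_idea), .groups = "drop")
}

coerce_synonym_map <- function(synonym_map) {
  if (is.null(synonym_map)) {
    return(character(0))
  }
  if (is.data.frame(synonym_map)) {
    stopifnot(all(c("raw", "canonical") %in% names(synonym_map)))
    map <- stats::setNames(
      as.character(synonym_map$canonical),
      normalize_label(synonym_map$raw)
    )
  } else if (is.character(synonym_map)) {
    stopifnot(!is.null(names(synonym_map)))
    map <- stats::setNames(unname(synonym_map), normalize_label(names(synonym_map)))
  } else {
    stop("synonym_map must be NULL, a data frame with columns raw/canonical, or a named character vector",
      call. = FALSE
    )
  }
  map <- map[!duplicated(cbind(names(map), map))]
  dup <- names(map)[duplicated(names(map))]
  if (length(dup) > 0L) {
    targets <- unname(map[names(map) == dup[1L]])
    stop(sprintf(
      "conflicting canonical for '%s': %s",
      dup[1L], paste(sQuote(targets), collapse = ", ")
    ), call. = FALSE)
  }
  if (any(!nzchar(trimws(map)))) {
    stop("empty canonical label in synonym map", call. = FALSE)
  }
  map
}

#' Collapse duplicate edges within one group model
#'
#' Edge identity within a group is `(cause, effect, polarity)`: the same factor
#' pair may carry both signs simultaneously and both are retained. Exact
#' duplicates collapse to one edge with delay flags OR-ed; the result is
#' independent of input order.
#'
#' @param edges Edge tibble whose rows all share one `group_id`.
#' @return Deduplicated edge tibble sorted by `(cause, effect, polarity)`.
#' @export
merge_duplicate_edges <- function(edges) {
  edges <- as_cld_edges(edges)
  if (length(unique(edges$group_id)) > 1L) {
    stop(sprintf(
      "edges span multiple group_ids (%s); merge is a within-group operation",
      paste(sQuote(sort(unique(edges$group_id))), collapse = ", ")
    ), call. = FALSE)
  }
  edges |>
    group_by(.data$group_id, .data$cause, .data$effect, .data$polarity) |>
    summarise(
      delay = any(.data$delay),
      cause_is_action = any(.data$cause_is_action),
      effect_is_action = any(.data$effect_is_action),
      .groups = "drop"
    ) |>
    select(all_of(edge_cols)) |>
    arrange(.data$cause, .data$effect, .data$polarity)
}

#' Validate group-model invariants
#'
#' Checks the structural invariants of per-group CLDs without mutating or
#' rejecting the input: violations are returned as data. Rules checked:
#' no self-edges (`self-edge`), polarity in `{+,-}` (`invalid-polarity`),
#' non-empty labels and group ids (`empty-label`, `empty-group-id`), and no
#' duplicate `(cause, effect, polarity)` rows within a group
#' (`duplicate-edge`). When an explicit `factors` table is supplied (as when a
#' model was assembled by hand rather than via [read_group_models()], which
#' derives factors from endpoints and always injects the focal), two further
#' rules apply: `focal-missing` for groups whose factor set lacks the focal
#' variable, and `endpoint-missing` for edges naming a factor absent from the
#' group's factor set.
#'
#' @param edges Edge tibble.
#' @param focal Optional focal id (defaults to the `focal` attribute if set).
#' @param factors Optional explicit factor table with columns `group_id`, `id`;
#'   default `NULL` means factors are the edge endpoints plus the focal, which
#'   satisfies the membership invariants by construction.
#' @return Tibble of violations with columns `group_id`, `rule`, `detail`;
#'   zero rows when all invariants hold.
#' @export
validate_group_models <- function(edges, focal = NULL, factors = NULL) {
  stopifnot(is.data.frame(edges))
  edges <- as_tibble(edges)
  if (!"group_id" %in% names(edges)) edges$group_id <- "g1"
  viol <- list()
  add <- function(group_id, rule, detail) {
    viol[[length(viol) + 1L]] <<- tibble(
      group_id = as.character(group_id), rule = rule, detail = detail
    )
  }
  for (i in seq_len(nrow(edges))) {
    g <- edges$group_id[i]
    if (!nzchar(trimws(g))) add(g, "empty-group-id", sprintf("row %d", i))
    if (!nzchar(trimws(edges$cause[i])) || !nzchar(trimws(edges$effect[i]))) {
      add(g, "empty-label", sprintf("row %d: (%s -> %s)", i, edges$cause[i], edges$effect[i]))
    }
    if (!edges$polarity[i] %in% c("+", "-")) {
      add(g, "invalid-polarity", sprintf("row %d: '%s'", i, edges$polarity[i]))
    }
    if (edges$cause[i] == edges$effect[i]) {
      add(g, "self-edge", sprintf("row %d: (%s -> %s)", i, edges$cause[i], edges$effect[i]))
    }
  }
  dup <- edges |>
    count(.data$group_id, .data$cause, .data$effect, .data$polarity) |>
    filter(.data$n > 1L)
  for (i in seq_len(nrow(dup))) {
    add(
      dup$group_id[i], "duplicate-edge",
      sprintf("(%s -> %s, %s) x%d", dup$cause[i], dup$effect[i], dup$polarity[i], dup$n[i])
    )
  }
  focal <- focal %||% attr(edges, "focal", exact = TRUE)
  if (!is.null(factors)) {
    factors <- as_tibble(factors)
    stopifnot(all(c("group_id", "id") %in% names(factors)))
    for (g in sort(unique(c(edges$group_id, factors$group_id)))) {
      ids <- factors$id[factors$group_id == g]
      sub <- edges[edges$group_id == g, ]
      if (!is.null(focal) && !focal %in% ids) add(g, "focal-missing", focal)
      bad <- !(sub$cause %in% ids) | !(sub$effect %in% ids)
      for (i in which(bad)) {
        add(g, "endpoint-missing", sprintf("(%s -> %s, %s)", sub$cause[i], sub$effect[i], sub$polarity[i]))
      }
    }
  }
  if (length(viol) == 0L) {
    return(tibble(group_id = character(), rule = character(), detail = character()))
  }
  arrange(bind_rows(viol), .data$group_id, .data$rule, .data$detail)
}
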