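# In-code fixtures: quick edge builders and seeded random graph/battery
# generators used across test files.

ed <- function(cause, effect, polarity = "+", group_id = "g1", delay = FALSE,
               cause_is_action = FALSE, effect_is_action = FALSE) {
  tibble::tibble(
    group_id = group_id, cause = cause, effect = effect, polarity = polarity,
    delay = delay, cause_is_action = cause_is_action,
    effect_is_action = effect_is_action
  )
}

triangle <- function(nodes = c("a", "b", "c"), signs = c("+", "+", "+"),
                     group_id = "g1") {
  ed(nodes, c(nodes[-1L], nodes[1L]), signs, group_id = group_id)
}

# random signed digraph over n nodes; occasional parallel opposite-sign pairs
random_digraph <- function(n, p_edge = 0.35, p_minus = 0.3, p_parallel = 0.08) {
  nodes <- sprintf("n%02d", seq_len(n))
  rows <- list()
  for (u in nodes) {
    for (v in nodes) {
      if (u == v || stats::runif(1) >= p_edge) next
      s <- if (stats::runif(1) < p_minus) "-" else "+"
      rows[[length(rows) + 1L]] <- ed(u, v, s)
      if (stats::runif(1) < p_parallel) {
        rows[[length(rows) + 1L]] <- ed(u, v, if (s == "+") "-" else "+")
      }
    }
  }
  if (length(rows) == 0L) {
    return(ed(character(0), character(0), character(0)))
  }
  dplyr::bind_rows(rows)
}

# small multi-group battery over a shared label pool (independent of the
# package's synthetic generator)
random_battery <- function(n_groups = 4L, n_nodes = 12L, n_rows = 18L,
                           p_minus = 0.3, p_action = 0.15, focal = "focal") {
  nodes <- c(focal, sprintf("f%02d", seq_len(n_nodes - 1L)))
  actions <- sample(setdiff(nodes, focal), max(1L, round(p_action * n_nodes)))
  groups <- lapply(seq_len(n_groups), function(g) {
    u <- sample(nodes, n_rows, replace = TRUE)
    v <- sample(nodes, n_rows, replace = TRUE)
    keep <- u != v
    ed(u[keep], v[keep],
      ifelse(stats::runif(sum(keep)) < p_minus, "-", "+"),
      group_id = sprintf("g%d", g),
      delay = stats::runif(sum(keep)) < 0.1,
      cause_is_action = u[keep] %in% actions,
      effect_is_action = v[keep] %in% actions
    )
  })
  out <- dplyr::bind_rows(groups)
  attr(out, "focal") <- focal
  out
}

demo_edges_path <- function() cld_example("workshop_demo_edges.csv")
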