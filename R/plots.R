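#' @importFrom ggplot2 ggplot aes geom_segment geom_point geom_text geom_col
#'   geom_histogram geom_boxplot labs theme_minimal scale_linetype_manual
#'   arrow unit position_dodge
NULL

# deterministic circular layout so plot output is reproducible
circle_layout <- function(ids) {
  ids <- sort(unique(ids))
  n <- length(ids)
  theta <- 2 * pi * (seq_len(n) - 1L) / max(n, 1L)
  tibble(id = ids, x = cos(theta), y = sin(theta))
}

#' Plot a signed CLD as a network diagram
#'
#' Nodes on a deterministic circular layout; solid arrows for positive links,
#' dashed for negative; the focal node (if known) is emphasized. Works for any
#' edge tibble, including `cld_core` and `cld_aggregate` objects.
#'
#' @param edges Edge tibble with `cause`, `effect`, `polarity`.
#' @param focal Optional focal id (defaults to the `focal` attribute).
#' @return A ggplot object.
#' @export
plot_cld <- function(edges, focal = NULL) {
  stopifnot(is.data.frame(edges))
  focal <- focal %||% attr(edges, "focal", exact = TRUE)
  lay <- circle_layout(c(edges$cause, edges$effect))
  seg <- as_tibble(edges) |>
    left_join(rename(lay, cause = "id", x0 = "x", y0 = "y"), by = "cause") |>
    left_join(rename(lay, effect = "id", x1 = "x", y1 = "y"), by = "effect")
  lay$is_focal <- !is.null(focal) & lay$id == (focal %||% "")
  ggplot() +
    geom_segment(
      data = seg,
      aes(
        x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
        linetype = .data$polarity
      ),
      arrow = arrow(length = unit(2, "mm")), alpha = 0.6
    ) +
    scale_linetype_manual(values = c("+" = "solid", "-" = "dashed")) +
    geom_point(data = lay, aes(.data$x, .data$y, colour = .data$is_focal), size = 2) +
    geom_text(data = lay, aes(.data$x * 1.08, .data$y * 1.08, label = .data$id), size = 2.6) +
    labs(linetype = "polarity", colour = "focal", x = NULL, y = NULL) +
    theme_minimal()
}

#' @export
autoplot.cld_core <- function(object, ...) {
  plot_cld(object) + labs(
    title = sprintf(
      "Consensus core: %d nodes, %d edges (support >= %d)",
      length(attr(object, "nodes")), nrow(object), attr(object, "min_support")
    )
  )
}

#' @export
autoplot.cld_loops <- function(object, ...) {
  df <- as_tibble(object)[, c("length", "classification")]
  ggplot(df, aes(x = factor(.data$length), fill = .data$classification)) +
    ggplot2::geom_bar(position = position_dodge(preserve = "single")) +
    labs(
      x = "loop length (nodes)", y = "number of loops", fill = NULL,
      title = "Feedback loop inventory"
    ) +
    theme_minimal()
}

#' @export
autoplot.cld_aggregate <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$support)) +
    ggplot2::geom_bar() +
    labs(
      x = "supporting groups per edge", y = "edges",
      title = "Edge support across workshop groups"
    ) +
    theme_minimal()
}

#' @export
autoplot.cld_recovery <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object)[, c("rep", "precision", "recall", "f1")],
    cols = c("precision", "recall", "f1"),
    names_to = "metric", values_to = "value"
  )
  ggplot(df, aes(x = .data$metric, y = .data$value)) +
    geom_boxplot() +
    labs(
      x = NULL, y = NULL,
      title = "Edge-level recovery of the latent core across replicates"
    ) +
    theme_minimal()
}

#' Support histogram of an aggregate or core model
#'
#' @param x A `cld_aggregate` or `cld_core`.
#' @return A ggplot object (bar chart of edge counts by support).
#' @export
plot_support_histogram <- function(x) {
  stopifnot(is.data.frame(x), "support" %in% names(x))
  ggplot(as_tibble(x), aes(x = factor(.data$support))) +
    ggplot2::geom_bar() +
    labs(x = "supporting groups", y = "edges") +
    theme_minimal()
}
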