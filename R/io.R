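#' Read per-group CLD edge lists
#'
#' Parses the exchange CSV dialect for workshop transcriptions: required
#' columns `group_id`, `cause`, `effect`, `polarity` (`"+"`/`"-"`), optional
#' `delay`, `cause_is_action`, `effect_is_action` (0/1). One group model per
#' distinct `group_id`; within-group duplicate rows are collapsed via
#' [merge_duplicate_edges()] and rows are returned sorted by `group_id` so
#' parsing is insensitive to input row order.
#'
#' @param source Path to a CSV file, or a length-1 character string containing
#'   CSV text (anything with an embedded newline is treated as literal text).
#' @param focal Label of the focal problem variable (e.g. `"dementia risk"`);
#'   normalized via [normalize_label()] and attached as the `focal` attribute.
#'   The focal factor belongs to every group's factor set (see
#'   [cld_factors()]) even if no edge in that group touches it.
#' @return Edge tibble with columns `group_id`, `cause`, `effect`, `polarity`,
#'   `delay`, `cause_is_action`, `effect_is_action` and attribute `focal`.
#' @examples
#' csv <- "group_id,cause,effect,polarity
#' g1,poverty,stress,+
#' g1,exercise,chronic disease,-"
#' read_group_models(csv, focal = "dementia risk")
#' @export
read_group_models <- function(source, focal) {
  stopifnot(is.character(source), length(source) == 1L)
  raw <- if (grepl("\n", source)) I(source) else source
  df <- tryCatch(
    readr::read_csv(raw,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE, show_col_types = FALSE
    ),
    error = function(e) stop("cannot read edge list: ", conditionMessage(e), call. = FALSE)
  )
  if (nrow(df) == 0L) stop("empty edge list", call. = FALSE)
  required <- c("group_id", "cause", "effect", "polarity")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("missing required column '%s'", missing[1L]), call. = FALSE)
  }
  bad_pol <- which(!df$polarity %in% c("+", "-"))
  if (length(bad_pol) > 0L) {
    stop(sprintf("row %d: invalid polarity '%s'", bad_pol[1L], df$polarity[bad_pol[1L]]),
      call. = FALSE
    )
  }
  if (any(is.na(df$group_id) | !nzchar(trimws(df$group_id)))) {
    stop(sprintf(
      "row %d: empty group_id",
      which(is.na(df$group_id) | !nzchar(trimws(df$group_id)))[1L]
    ), call. = FALSE)
  }
  flag <- function(x) {
    if (is.null(x)) {
      return(FALSE)
    }
    !is.na(x) & x %in% c("1", "true", "TRUE", "True")
  }
  edges <- tibble(
    group_id = df$group_id,
    cause = df$cause,
    effect = df$effect,
    polarity = df$polarity,
    delay = flag(df[["delay"]]),
    cause_is_action = flag(df[["cause_is_action"]]),
    effect_is_action = flag(df[["effect_is_action"]])
  )
  out <- edges |>
    dplyr::group_split(.data$group_id) |>
    purrr::map(merge_duplicate_edges) |>
    bind_rows() |>
    arrange(.data$group_id, .data$cause, .data$effect, .data$polarity)
  attr(out, "focal") <- normalize_label(focal)
  out
}

#' Read a factor-label synonym map
#'
#' Two-column CSV with header `raw,canonical`. Keys are normalized with
#' [normalize_label()]; duplicate identical rows collapse, while the same raw
#' label mapped to two different canonicals is an error.
#'
#' @param source Path to a CSV file or literal CSV text.
#' @return Named character vector: `canonical <- map[normalized raw]`. Empty
#'   body yields an empty map.
#' @export
read_synonym_map <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  raw <- if (grepl("\n", source)) I(source) else source
  df <- readr::read_csv(raw,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  missing <- setdiff(c("raw", "canonical"), names(df))
  if (length(missing) > 0L) {
    stop(sprintf("missing required column '%s' (expected header raw,canonical)", missing[1L]),
      call. = FALSE
    )
  }
  coerce_synonym_map(df)
}

#' Export a signed digraph as DOT or GraphML text
#'
#' Deterministic, diff-friendly exports: nodes and edges are emitted in
#' lexicographic order so the same graph always serializes to identical bytes.
#' DOT output styles negative edges dashed and double-circles the focal node;
#' GraphML output carries `polarity` (string) and, when a `support` column is
#' present, `support` (int) edge attributes plus an `is_action_idea` (boolean)
#' node attribute, and round-trips through [read_signed_graph()].
#'
#' @param edges Edge tibble (`cause`, `effect`, `polarity`, optionally
#'   `support` and action flags).
#' @param format `"dot"` or `"graphml"`.
#' @param focal Optional focal node id (defaults to the `focal` attribute).
#' @param path Optional file path; when given, the text is also written there.
#' @return The serialized graph as a length-1 character string (invisibly when
#'   `path` is given).
#' @export
write_signed_graph <- function(edges, format = c("dot", "graphml"), focal = NULL,
                               path = NULL) {
  format <- match.arg(format)
  stopifnot(is.data.frame(edges))
  edges <- as_tibble(edges)
  check_polarity(edges$polarity)
  focal <- focal %||% attr(edges, "focal", exact = TRUE)
  ord <- order(edges$cause, edges$effect, edges$polarity)
  edges <- edges[ord, ]
  has_support <- "support" %in% names(edges)
  nodes <- node_action_table(edges)
  text <- if (format == "dot") {
    dot_text(edges, nodes, focal)
  } else {
    graphml_text(edges, nodes, focal, has_support)
  }
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

node_action_table <- function(edges) {
  ca <- if ("cause_is_action" %in% names(edges)) edges$cause_is_action else FALSE
  ea <- if ("effect_is_action" %in% names(edges)) edges$effect_is_action else FALSE
  tibble(id = c(edges$cause, edges$effect), is_action_idea = c(
    rep_len(ca, nrow(edges)), rep_len(ea, nrow(edges))
  )) |>
    group_by(.data$id) |>
    summarise(is_action_idea = any(.data$is_action_idea), .groups = "drop") |>
    arrange(.data$id)
}

dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

dot_text <- function(edges, nodes, focal) {
  lines <- c("digraph cld {")
  for (i in seq_len(nrow(nodes))) {
    attrs <- character(0)
    if (!is.null(focal) && nodes$id[i] == focal) attrs <- c(attrs, "shape=doublecircle")
    if (isTRUE(nodes$is_action_idea[i])) attrs <- c(attrs, "shape=box")
    lines <- c(lines, paste0(
      "  ", dot_quote(nodes$id[i]),
      if (length(attrs) > 0L) paste0(" [", paste(attrs, collapse = ", "), "]") else "",
      ";"
    ))
  }
  for (i in seq_len(nrow(edges))) {
    attrs <- sprintf('polarity="%s"', edges$polarity[i])
    if (edges$polarity[i] == "-") attrs <- c(attrs, "style=dashed")
    if ("support" %in% names(edges)) {
      attrs <- c(attrs, sprintf('label="%d"', as.integer(edges$support[i])))
    }
    lines <- c(lines, paste0(
      "  ", dot_quote(edges$cause[i]), " -> ", dot_quote(edges$effect[i]),
      " [", paste(attrs, collapse = ", "), "];"
    ))
  }
  paste0(paste(c(lines, "}"), collapse = "\n"), "\n")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

graphml_text <- function(edges, nodes, focal, has_support) {
  head <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="d0" for="edge" attr.name="polarity" attr.type="string"/>',
    '  <key id="d1" for="node" attr.name="is_action_idea" attr.type="boolean"/>',
    if (has_support) '  <key id="d2" for="edge" attr.name="support" attr.type="int"/>',
    '  <graph id="cld" edgedefault="directed">'
  )
  node_lines <- vapply(seq_len(nrow(nodes)), function(i) {
    paste0(
      '    <node id="', xml_escape(nodes$id[i]), '">',
      '<data key="d1">', tolower(as.character(isTRUE(nodes$is_action_idea[i]))), "</data>",
      "</node>"
    )
  }, character(1))
  edge_lines <- vapply(seq_len(nrow(edges)), function(i) {
    paste0(
      '    <edge source="', xml_escape(edges$cause[i]),
      '" target="', xml_escape(edges$effect[i]), '">',
      '<data key="d0">', edges$polarity[i], "</data>",
      if (has_support) {
        paste0('<data key="d2">', as.integer(edges$support[i]), "</data>")
      } else {
        ""
      },
      "</edge>"
    )
  }, character(1))
  paste0(paste(c(head, node_lines, edge_lines, "  </graph>", "</graphml>"), collapse = "\n"), "\n")
}

#' @rdname write_signed_graph
#' @param source GraphML text or path to a GraphML file written by
#'   [write_signed_graph()].
#' @export
read_signed_graph <- function(source) {
  doc <- if (grepl("\n", source)) xml2::read_xml(source) else xml2::read_xml(paste(readLines(source), collapse = "\n"))
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, ".//key")
  key_name <- stats::setNames(
    xml2::xml_attr(keys, "attr.name"),
    xml2::xml_attr(keys, "id")
  )
  nodes <- xml2::xml_find_all(doc, ".//node")
  node_tbl <- tibble(
    id = xml2::xml_attr(nodes, "id"),
    is_action_idea = vapply(nodes, function(n) {
      d <- xml2::xml_find_all(n, "./data")
      k <- key_name[xml2::xml_attr(d, "key")]
      v <- xml2::xml_text(d)
      isTRUE(v[k == "is_action_idea"][1] == "true")
    }, logical(1))
  )
  eds <- xml2::xml_find_all(doc, ".//edge")
  get_data <- function(e, name) {
    d <- xml2::xml_find_all(e, "./data")
    k <- key_name[xml2::xml_attr(d, "key")]
    v <- xml2::xml_text(d)
    out <- v[k == name]
    if (length(out) == 0L) NA_character_ else out[1]
  }
  edge_tbl <- tibble(
    cause = xml2::xml_attr(eds, "source"),
    effect = xml2::xml_attr(eds, "target"),
    polarity = vapply(eds, get_data, character(1), name = "polarity"),
    support = suppressWarnings(as.integer(vapply(eds, get_data, character(1), name = "support")))
  )
  if (all(is.na(edge_tbl$support))) edge_tbl$support <- NULL
  edge_tbl <- edge_tbl |>
    left_join(rename(node_tbl, cause = "id", cause_is_action = "is_action_idea"), by = "cause") |>
    left_join(rename(node_tbl, effect = "id", effect_is_action = "is_action_idea"), by = "effect") |>
    arrange(.data$cause, .data$effect, .data$polarity)
  edge_tbl
}

#' Serialize a pipeline report as deterministic JSON
#'
#' All report objects are named lists (or tibbles) of counts and tables; the
#' writer preserves key order, unboxes scalars, stamps a `schema_version`
#' field, and produces identical bytes for identical input.
#'
#' @param report Named list (a report object from [core_report()],
#'   [loop_report()], [glance()] output, ...).
#' @param path Optional path to write to.
#' @return JSON text (invisibly when `path` is given).
#' @export
write_report <- function(report, path = NULL) {
  stopifnot(is.list(report))
  out <- c(list(schema_version = "1.0"), report)
  txt <- jsonlite::toJSON(out,
    auto_unbox = TRUE, digits = NA, pretty = TRUE,
    dataframe = "rows", null = "null"
  )
  txt <- paste0(as.character(txt), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}
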