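#' Run configuration for the CLD analysis pipeline
#'
#' @param focal Label of the focal problem variable (required; normalized).
#' @param min_support Consensus threshold for core extraction (default 2).
#' @param max_loop_len Maximum loop length for inventories (default 12).
#' @param max_path_len Maximum action-pathway length in edges (default 4).
#' @param max_intermediates Maximum intervening nodes for indirect-path
#'   consensus (default 2).
#' @param seed Integer seed recorded in the manifest (default 1).
#' @param output_dir Directory the pipeline writes its reports into.
#' @return List of class `cld_config`.
#' @export
cld_config <- function(focal, min_support = 2L, max_loop_len = 12L,
                       max_path_len = 4L, max_intermediates = 2L,
                       seed = 1L, output_dir = tempfile("cld_run_")) {
  if (missing(focal) || is.null(focal) || !nzchar(trimws(focal))) {
    stop("focal must be a non-empty string", call. = FALSE)
  }
  cfg <- list(
    focal = normalize_label(focal),
    min_support = as.integer(min_support),
    max_loop_len = as.integer(max_loop_len),
    max_path_len = as.integer(max_path_len),
    max_intermediates = as.integer(max_intermediates),
    seed = as.integer(seed),
    output_dir = output_dir
  )
  if (cfg$min_support < 1L) stop("min_support must be >= 1", call. = FALSE)
  if (cfg$max_loop_len < 2L) stop("max_loop_len must be >= 2", call. = FALSE)
  if (cfg$max_path_len < 1L) stop("max_path_len must be >= 1", call. = FALSE)
  if (cfg$max_intermediates < 1L) stop("max_intermediates must be >= 1", call. = FALSE)
  class(cfg) <- "cld_config"
  cfg
}

#' Read a YAML run configuration
#'
#' Recognized keys: `focal` (required), `min_support`, `max_loop_len`,
#' `max_path_len`, `max_intermediates`, `seed`, `output_dir`.
#'
#' @param path Path to a YAML file.
#' @param ... Overrides applied on top of the file's values.
#' @return A `cld_config`.
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- c(
    "focal", "min_support", "max_loop_len", "max_path_len",
    "max_intermediates", "seed", "output_dir"
  )
  do.call(cld_config, vals[intersect(names(vals), known)])
}

#' Run the full CLD consensus pipeline
#'
#' Orchestrates read -> canonicalize -> validate -> union -> loop inventory ->
#' core extraction -> indirect consensus -> action influence, writing every
#' report and graph export under one run directory together with a manifest
#' (configuration, input digests, package version). All outputs are
#' deterministic: the same inputs and configuration give byte-identical
#' reports (the log carries the only timestamps, and it is excluded from the
#' manifest).
#'
#' Validation failures (or an unreadable input) abort before any report is
#' written.
#'
#' @param edge_list Path to (or literal text of) the edge-list CSV.
#' @param config A `cld_config`.
#' @param synonym_map Optional path to (or text of) a `raw,canonical` CSV.
#' @param quiet Suppress stage log lines (default `FALSE`).
#' @return Invisibly, a list with the run directory path and the in-memory
#'   results (`edges`, `agg`, `loops`, `core`, `consensus`, `actions`).
#' @export
run_pipeline <- function(edge_list, config, synonym_map = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "cld_config"))
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
  }

  say("reading inputs")
  syn <- if (is.null(synonym_map)) NULL else read_synonym_map(synonym_map)
  edges <- read_group_models(edge_list, focal = config$focal)
  edges <- canonicalize_labels(edges, syn, focal = config$focal)
  viol <- validate_group_models(edges)
  if (nrow(viol) > 0L) {
    stop(sprintf(
      "validation failed (%d violation(s)); first: [%s] %s %s",
      nrow(viol), viol$group_id[1L], viol$rule[1L], viol$detail[1L]
    ), call. = FALSE)
  }
  if (!config$focal %in% c(edges$cause, edges$effect)) {
    stop(sprintf("focal '%s' not present in inputs", config$focal), call. = FALSE)
  }

  say("aggregating %d groups", length(unique(edges$group_id)))
  stats <- summary_stats(edges)
  agg <- union_models(edges)

  say("enumerating loops")
  loops <- enumerate_loops(feedback_edges(agg),
    max_len = config$max_loop_len
  )

  say("extracting core (min_support = %d)", config$min_support)
  core <- extract_core(agg, min_support = config$min_support)

  say("indirect-path consensus")
  consensus <- indirect_path_consensus(agg, edges,
    max_intermediates = config$max_intermediates
  )

  say("action influence")
  actions <- action_influence(agg, core, max_path_len = config$max_path_len)

  say("writing reports to %s", config$output_dir)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)

  readr::write_csv(tidy(agg), out("aggregate_edges.csv"))
  readr::write_csv(as_tibble(stats), out("group_summary.csv"))
  readr::write_csv(tidy(core), out("core_edges.csv"))
  readr::write_csv(tidy(consensus), out("consensus.csv"))
  readr::write_csv(tidy(actions), out("action_pathways.csv"))
  write_signed_graph(core, format = "dot", path = out("core.dot"))
  write_signed_graph(core, format = "graphml", path = out("core.graphml"))
  write_report(loop_report(loops), out("loops.json"))
  write_report(core_report(core, max_loop_len = config$max_loop_len), out("core.json"))
  write_report(c(
    as.list(glance(agg)),
    list(per_group = as_tibble(stats), summary = as.list(glance(stats)))
  ), out("aggregate.json"))
  write_report(as.list(glance(actions)), out("actions.json"))

  manifest <- list(
    package = "cldtools",
    version = as.character(utils::packageVersion("cldtools")),
    # output_dir is a run location, not an analysis parameter; leaving it out
    # keeps manifests byte-identical across re-runs of the same analysis
    config = unclass(config)[setdiff(names(config), "output_dir")],
    inputs = list(
      edge_list = input_digest(edge_list),
      synonym_map = if (is.null(synonym_map)) NULL else input_digest(synonym_map)
    ),
    outputs = sort(setdiff(list.files(config$output_dir), c("manifest.json", "run.log")))
  )
  write_report(manifest, out("manifest.json"))
  say("done")

  invisible(list(
    dir = config$output_dir, edges = edges, stats = stats, agg = agg,
    loops = loops, core = core, consensus = consensus, actions = actions
  ))
}

input_digest <- function(source) {
  if (grepl("\n", source)) {
    list(kind = "inline", md5 = unname(tools::md5sum(write_temp(source))), bytes = nchar(source, type = "bytes"))
  } else {
    list(kind = "file", path = source, md5 = unname(tools::md5sum(source)), bytes = file.size(source))
  }
}

write_temp <- function(text) {
  f <- tempfile()
  writeLines(text, f, sep = "")
  f
}

#' Path to the bundled demo transcription
#'
#' The package ships a transcription of one workshop group's narrated causal
#' loop diagram (reinforcing loops R1-R7, balancing loops B1-B3, the exogenous
#' systemic-racism driver, and two action ideas) as a ready-to-run fixture.
#'
#' @param file File name under the package's `extdata` (default the demo edge
#'   list).
#' @return Absolute path to the installed file.
#' @export
cld_example <- function(file = "workshop_demo_edges.csv") {
  system.file("extdata", file, package = "cldtools", mustWork = TRUE)
}
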