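#' Parameters for the synthetic multi-group CLD generator
#'
#' The generator emulates a multi-workshop group-model-building study: several
#' groups independently map one latent system, each detecting most of its
#' edges, occasionally disagreeing on a sign, and adding idiosyncratic
#' group-specific content. Defaults are calibrated so per-group factor and
#' edge counts land near the scale of community workshop CLDs (about 70
#' factors and 115 edges per group, 8 groups, 18 action ideas).
#'
#' @param n_factors Number of factors in the latent system (default 70).
#' @param n_groups Number of workshop groups (default 8).
#' @param n_core_edges Number of consensus-recoverable edges in the latent
#'   system: feedback loops through the focal variable, upstream/downstream
#'   chains, and action-idea attachments (default 66). Too small a value to
#'   host the required loop structure is an error at generation time.
#' @param n_peripheral_edges Latent edges attached to the system but on no
#'   cycle and not causally connected to the focal variable (default 36).
#' @param p_detect Probability a group records a given latent non-action edge
#'   (default 0.85).
#' @param p_detect_action Probability a group records a given action-idea edge
#'   (default 0.4; action ideas were elicited separately per workshop and
#'   overlap less across groups than system structure).
#' @param flip_prob Probability a recorded edge's polarity is flipped
#'   (default 0.02; transcription/elicitation disagreement).
#' @param noise_rate Expected number of group-specific noise edges per group
#'   (Poisson mean, default 40).
#' @param noise_pool_size Size of each group's pool of group-unique factor
#'   labels used by noise edges (default 12).
#' @param p_unique_noise Probability a noise edge uses a group-unique label for
#'   one endpoint (default 0.9); otherwise both endpoints are latent factors,
#'   which makes cross-group coincidence of noise possible as a stressor.
#' @param n_action_nodes Number of latent action-idea factors (default 18).
#' @param p_positive Probability a randomly signed latent or noise edge is
#'   `"+"` (default 0.7; elicited causal links are predominantly positive).
#' @param focal Label of the focal problem variable (default
#'   `"dementia_risk"`).
#' @param seed Default integer seed used when the generator functions are not
#'   given one explicitly.
#' @return A list of class `cld_gen_params`.
#' @export
gen_params <- function(n_factors = 70L, n_groups = 8L, n_core_edges = 66L,
                       n_peripheral_edges = 36L, p_detect = 0.85,
                       p_detect_action = 0.4, flip_prob = 0.02,
                       noise_rate = 40, noise_pool_size = 12L,
                       p_unique_noise = 0.9, n_action_nodes = 18L,
                       p_positive = 0.7, focal = "dementia_risk", seed = 1L) {
  p <- list(
    n_factors = as.integer(n_factors), n_groups = as.integer(n_groups),
    n_core_edges = as.integer(n_core_edges),
    n_peripheral_edges = as.integer(n_peripheral_edges),
    p_detect = p_detect, p_detect_action = p_detect_action,
    flip_prob = flip_prob, noise_rate = noise_rate,
    noise_pool_size = as.integer(noise_pool_size),
    p_unique_noise = p_unique_noise,
    n_action_nodes = as.integer(n_action_nodes),
    p_positive = p_positive, focal = normalize_label(focal),
    seed = as.integer(seed)
  )
  probs <- c(p$p_detect, p$p_detect_action, p$flip_prob, p$p_unique_noise, p$p_positive)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (p$noise_rate < 0) stop("noise_rate must be >= 0", call. = FALSE)
  counts <- c(p$n_factors, p$n_groups, p$n_core_edges, p$n_peripheral_edges, p$n_action_nodes)
  if (any(counts < 1L) || p$noise_pool_size < 1L) {
    stop("counts must be positive", call. = FALSE)
  }
  if (!nzchar(p$focal)) stop("focal must be non-empty", call. = FALSE)
  class(p) <- "cld_gen_params"
  p
}

rand_sign <- function(n, p_positive) {
  ifelse(stats::runif(n) < p_positive, "+", "-")
}

#' Generate a latent signed system with known structure
#'
#' Builds the ground-truth digraph the synthetic groups will observe:
#' feedback loops through the focal variable (at least one reinforcing, one
#' balancing), upstream ancestor chains (whose heads are exogenous: in-degree
#' zero), downstream descendant chains, action-idea nodes attached by outgoing
#' edges, and peripheral edges that lie on no cycle and are not causally
#' connected to the focal variable. By construction every core edge survives
#' consensus core extraction under perfect detection and every peripheral edge
#' does not, so edge-level recovery against `core_edges` is well defined.
#'
#' @param params A `cld_gen_params` list from [gen_params()].
#' @param seed Integer seed (defaults to `params$seed`); output is a
#'   deterministic function of `(params, seed)`.
#' @return List of class `cld_true_system`: `factors` (tibble `id`,
#'   `is_action_idea`, `role`), `core_edges` and `peripheral_edges` (tibbles
#'   with `cause`, `effect`, `polarity`, `delay`), and `focal`.
#' @export
generate_true_system <- function(params = gen_params(), seed = params$seed) {
  stopifnot(inherits(params, "cld_gen_params"))
  set.seed(seed)
  focal <- params$focal
  n_rest <- params$n_factors - 1L - params$n_action_nodes
  if (n_rest < 7L) {
    stop("n_factors too small for the required loop/chain structure", call. = FALSE)
  }
  n_cycle <- max(3L, round(0.22 * n_rest))
  n_anc <- max(2L, round(0.25 * n_rest))
  n_desc <- max(1L, round(0.18 * n_rest))
  n_peri <- n_rest - n_cycle - n_anc - n_desc
  if (n_peri < 1L) stop("n_factors too small for peripheral structure", call. = FALSE)

  cyc <- sprintf("loop_factor_%02d", seq_len(n_cycle))
  anc <- sprintf("upstream_%02d", seq_len(n_anc))
  desc <- sprintf("downstream_%02d", seq_len(n_desc))
  peri <- sprintf("context_%02d", seq_len(n_peri))
  act <- sprintf("action_%02d", seq_len(params$n_action_nodes))

  ce <- list() # core edge rows: cause, effect, polarity
  add <- function(cause, effect, polarity) {
    ce[[length(ce) + 1L]] <<- tibble(cause = cause, effect = effect, polarity = polarity)
  }

  # feedback loops through the focal node; first all-positive (reinforcing),
  # second with exactly one negative (balancing), rest randomly signed
  loop_sizes <- integer(0)
  left <- n_cycle
  while (left > 0L) {
    k <- min(left, if (left %% 3L == 1L && left > 3L) 2L else 3L)
    loop_sizes <- c(loop_sizes, k)
    left <- left - k
  }
  pos <- 0L
  for (li in seq_along(loop_sizes)) {
    members <- cyc[(pos + 1L):(pos + loop_sizes[li])]
    pos <- pos + loop_sizes[li]
    ring <- c(focal, members, focal)
    n_hops <- length(ring) - 1L
    signs <- if (li == 1L) {
      rep("+", n_hops)
    } else if (li == 2L) {
      s <- rep("+", n_hops)
      s[sample.int(n_hops, 1L)] <- "-"
      s
    } else {
      rand_sign(n_hops, params$p_positive)
    }
    for (h in seq_len(n_hops)) add(ring[h], ring[h + 1L], signs[h])
  }

  # upstream chains ending at the focal node or a loop factor
  chain_of <- split(anc, ceiling(seq_along(anc) / 4L))
  for (ch in chain_of) {
    target <- if (stats::runif(1) < 0.5) focal else sample(cyc, 1L)
    seq_nodes <- c(ch, target)
    for (h in seq_len(length(seq_nodes) - 1L)) {
      add(seq_nodes[h], seq_nodes[h + 1L], rand_sign(1L, params$p_positive))
    }
  }

  # downstream chains starting at the focal node
  chain_of <- split(desc, ceiling(seq_along(desc) / 4L))
  for (ch in chain_of) {
    seq_nodes <- c(focal, ch)
    for (h in seq_len(length(seq_nodes) - 1L)) {
      add(seq_nodes[h], seq_nodes[h + 1L], rand_sign(1L, params$p_positive))
    }
  }

  # one outgoing attachment per action idea, into nodes that reach the focal
  targets_pool <- c(cyc, anc, focal)
  for (a in act) {
    add(a, sample(targets_pool, 1L), rand_sign(1L, params$p_positive))
  }

  core <- bind_rows(ce)
  n_mandatory <- nrow(core)
  extra <- params$n_core_edges - n_mandatory
  if (extra < 0L) {
    stop(sprintf(
      "n_core_edges = %d cannot host the required structure (needs >= %d)",
      params$n_core_edges, n_mandatory
    ), call. = FALSE)
  }
  used_pairs <- paste(core$cause, core$effect)
  # second attachments for action ideas, then upstream cross-links
  if (extra > 0L) {
    for (a in sample(act, min(extra, length(act)))) {
      repeat {
        t <- sample(targets_pool, 1L)
        if (!paste(a, t) %in% used_pairs) break
      }
      add(a, t, rand_sign(1L, params$p_positive))
      used_pairs <- c(used_pairs, paste(a, t))
      extra <- extra - 1L
    }
  }
  cross_pool <- expand.grid(cause = anc, effect = cyc, stringsAsFactors = FALSE)
  cross_pool <- cross_pool[!paste(cross_pool$cause, cross_pool$effect) %in% used_pairs, ]
  if (extra > nrow(cross_pool)) {
    stop("n_core_edges too large for the available structure", call. = FALSE)
  }
  if (extra > 0L) {
    pick <- cross_pool[sample.int(nrow(cross_pool), extra), ]
    for (i in seq_len(nrow(pick))) {
      add(pick$cause[i], pick$effect[i], rand_sign(1L, params$p_positive))
    }
  }
  core <- bind_rows(ce)

  # peripheral edges: sources are nodes the focal cannot reach (upstream and
  # action nodes), sinks are context nodes or downstream nodes; acyclic by
  # ordering, never creating a path into the focal
  pe <- list()
  padd <- function(cause, effect, polarity) {
    pe[[length(pe) + 1L]] <<- tibble(cause = cause, effect = effect, polarity = polarity)
  }
  for (p_node in peri) {
    padd(sample(c(anc, act), 1L), p_node, rand_sign(1L, params$p_positive))
  }
  n_extra_peri <- params$n_peripheral_edges - n_peri
  if (n_extra_peri < 0L) {
    stop("n_peripheral_edges must be >= the number of peripheral factors", call. = FALSE)
  }
  peri_pairs <- bind_rows(pe)
  used_p <- paste(peri_pairs$cause, peri_pairs$effect)
  tries <- 0L
  while (n_extra_peri > 0L && tries < 10000L) {
    tries <- tries + 1L
    kind <- sample(c("into", "within", "out"), 1L)
    if (kind == "into") {
      u <- sample(c(anc, act), 1L)
      v <- sample(peri, 1L)
    } else if (kind == "within" && n_peri >= 2L) {
      ij <- sort(sample.int(n_peri, 2L))
      u <- peri[ij[1L]]
      v <- peri[ij[2L]]
    } else {
      u <- sample(peri, 1L)
      v <- sample(desc, 1L)
    }
    if (paste(u, v) %in% used_p || u == v) next
    padd(u, v, rand_sign(1L, params$p_positive))
    used_p <- c(used_p, paste(u, v))
    n_extra_peri <- n_extra_peri - 1L
  }
  peripheral <- bind_rows(pe)

  finish <- function(e) {
    e$delay <- stats::runif(nrow(e)) < 0.1
    arrange(e, .data$cause, .data$effect, .data$polarity)
  }
  factors <- tibble(
    id = c(focal, cyc, anc, desc, peri, act),
    is_action_idea = c(rep(FALSE, 1L + n_cycle + n_anc + n_desc + n_peri), rep(TRUE, length(act))),
    role = c(
      "focal", rep("loop", n_cycle), rep("upstream", n_anc),
      rep("downstream", n_desc), rep("context", n_peri), rep("action", length(act))
    )
  ) |> arrange(.data$id)

  out <- list(
    factors = factors,
    core_edges = finish(core),
    peripheral_edges = finish(peripheral),
    focal = focal
  )
  class(out) <- "cld_true_system"
  out
}

#' Sample per-group workshop models from a latent system
#'
#' Each group observes the latent system imperfectly: every latent edge is
#' included independently (probability `p_detect`, or `p_detect_action` for
#' edges leaving an action idea), each included edge's polarity flips with
#' probability `flip_prob`, and a Poisson number of group-specific noise edges
#' is added, mostly touching a group-unique label so that noise rarely
#' coincides across groups. The focal factor belongs to every group's factor
#' set. Output uses the standard edge-list columns so synthetic batteries flow
#' through the identical pipeline as real transcriptions.
#'
#' @param truth A `cld_true_system` from [generate_true_system()].
#' @param params The `cld_gen_params` used to generate it.
#' @param seed Integer seed (default `params$seed + 1`).
#' @return Edge tibble (all groups, `group_id` = `"wkshp01"`, ...) with the
#'   `focal` attribute set.
#' @export
sample_group_models <- function(truth, params = gen_params(), seed = params$seed + 1L) {
  stopifnot(inherits(truth, "cld_true_system"), inherits(params, "cld_gen_params"))
  set.seed(seed)
  latent <- bind_rows(
    mutate(truth$core_edges, tier = "core"),
    mutate(truth$peripheral_edges, tier = "peripheral")
  )
  action_ids <- truth$factors$id[truth$factors$is_action_idea]
  p_edge <- ifelse(latent$cause %in% action_ids, params$p_detect_action, params$p_detect)

  groups <- list()
  for (g in seq_len(params$n_groups)) {
    gid <- sprintf("wkshp%02d", g)
    seen <- latent[stats::runif(nrow(latent)) < p_edge, , drop = FALSE]
    if (nrow(seen) > 0L) {
      flip <- stats::runif(nrow(seen)) < params$flip_prob
      seen$polarity[flip] <- ifelse(seen$polarity[flip] == "+", "-", "+")
    }
    pool <- sprintf("%s_local_%02d", gid, seq_len(params$noise_pool_size))
    known <- unique(c(seen$cause, seen$effect, truth$focal))
    n_noise <- stats::rpois(1L, params$noise_rate)
    noise <- NULL
    if (n_noise > 0L) {
      u <- character(n_noise)
      v <- character(n_noise)
      for (i in seq_len(n_noise)) {
        a <- sample(known, 1L)
        b <- if (stats::runif(1) < params$p_unique_noise) {
          sample(pool, 1L)
        } else {
          repeat {
            b2 <- sample(known, 1L)
            if (b2 != a) break
          }
          b2
        }
        if (stats::runif(1) < 0.5) {
          u[i] <- a
          v[i] <- b
        } else {
          u[i] <- b
          v[i] <- a
        }
      }
      noise <- tibble(
        cause = u, effect = v,
        polarity = rand_sign(n_noise, params$p_positive),
        delay = FALSE, tier = "noise"
      )
    }
    ge <- bind_rows(seen, noise)
    if (nrow(ge) == 0L) {
      ge <- tibble(
        cause = character(), effect = character(), polarity = character(),
        delay = logical(), tier = character()
      )
    }
    ge <- tibble(
      group_id = gid,
      cause = ge$cause, effect = ge$effect, polarity = ge$polarity,
      delay = ge$delay,
      cause_is_action = ge$cause %in% action_ids,
      effect_is_action = ge$effect %in% action_ids
    )
    groups[[g]] <- if (nrow(ge) > 0L) merge_duplicate_edges(ge) else ge
  }
  out <- bind_rows(groups)
  attr(out, "focal") <- truth$focal
  out
}

#' Edge-level recovery of the latent core
#'
#' Sign-sensitive edge matching between an extracted consensus core and the
#' latent system's core edges: an edge counts as recovered only when cause,
#' effect and polarity all agree. Conventions for empty sets: precision is 1
#' when the extracted core is empty, recall is 1 when the latent core is
#' empty.
#'
#' @param core A `cld_core` from [extract_core()].
#' @param truth The `cld_true_system` the groups were sampled from.
#' @return One-row tibble: `n_core`, `n_truth`, `n_matched`, `precision`,
#'   `recall`, `f1`.
#' @export
recovery_metrics <- function(core, truth) {
  stopifnot(inherits(truth, "cld_true_system"))
  core_keys <- edge_key(core)
  truth_keys <- edge_key(truth$core_edges)
  n_matched <- length(intersect(core_keys, truth_keys))
  precision <- if (length(core_keys) == 0L) 1 else n_matched / length(core_keys)
  recall <- if (length(truth_keys) == 0L) 1 else n_matched / length(truth_keys)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble(
    n_core = length(core_keys), n_truth = length(truth_keys),
    n_matched = n_matched, precision = precision, recall = recall, f1 = f1
  )
}

#' Run a synthetic recovery experiment
#'
#' Repeats generate -> sample -> canonicalize -> union -> core extraction ->
#' recovery scoring over independent replicates. Deterministic given
#' `(params, seed)`: replicate r uses seeds derived arithmetically from
#' `seed`.
#'
#' @param params A `cld_gen_params`.
#' @param n_reps Number of replicates (>= 1).
#' @param seed Base integer seed (default `params$seed`).
#' @param min_support Consensus threshold passed to [extract_core()]
#'   (default 2).
#' @return Tibble of class `cld_recovery` with one row per replicate
#'   (`rep`, `n_core`, `n_truth`, `n_matched`, `precision`, `recall`, `f1`).
#'   [glance()] reports mean and median precision/recall/F1.
#' @export
run_recovery_experiment <- function(params = gen_params(), n_reps = 50L,
                                    seed = params$seed, min_support = 2L) {
  stopifnot(inherits(params, "cld_gen_params"), n_reps >= 1L)
  rows <- purrr::map(seq_len(n_reps), function(r) {
    truth <- generate_true_system(params, seed = seed + 1000L * r)
    edges <- sample_group_models(truth, params, seed = seed + 1000L * r + 500L)
    edges <- canonicalize_labels(edges, focal = truth$focal)
    agg <- union_models(edges, focal = truth$focal)
    core <- extract_core(agg, min_support = min_support)
    mutate(recovery_metrics(core, truth), rep = r, .before = 1L)
  })
  out <- bind_rows(rows)
  class(out) <- c("cld_recovery", class(out))
  attr(out, "params") <- params
  attr(out, "min_support") <- as.integer(min_support)
  out
}

#' @export
glance.cld_recovery <- function(x, ...) {
  tibble(
    n_reps = nrow(x),
    mean_precision = mean(x$precision),
    median_precision = stats::median(x$precision),
    mean_recall = mean(x$recall),
    median_recall = stats::median(x$recall),
    mean_f1 = mean(x$f1),
    median_f1 = stats::median(x$f1)
  )
}

#' @export
tidy.cld_recovery <- function(x, ...) as_tibble(x)
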