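small_params <- function(...) {
  defaults <- list(
    n_factors = 30, n_groups = 4, n_core_edges = 26, n_peripheral_edges = 12,
    n_action_nodes = 6, noise_rate = 10, noise_pool_size = 5
  )
  do.call(gen_params, utils::modifyList(defaults, list(...)))
}

test_that("the latent system satisfies its structural guarantees", {
  for (s in c(1, 9, 23)) {
    truth <- generate_true_system(gen_params(), seed = s)
    # disjoint core/peripheral edge sets
    expect_length(intersect(edge_keys_of(truth$core_edges), edge_keys_of(truth$peripheral_edges)), 0L)
    loops <- enumerate_loops(truth$core_edges, max_len = 6)
    # focal on at least one cycle; one reinforcing and one balancing loop
    expect_true(any(vapply(loops$nodes, function(n) truth$focal %in% n, logical(1))))
    expect_true(any(loops$classification == "reinforcing"))
    expect_true(any(loops$classification == "balancing"))
    # at least one exogenous factor influencing the core
    all_edges <- dplyr::bind_rows(truth$core_edges, truth$peripheral_edges)
    exo <- exogenous_nodes(all_edges)
    expect_gt(length(exo), 0L)
    expect_true(any(exo %in% truth$core_edges$cause))
    # no self-edges, focal present
    expect_false(any(all_edges$cause == all_edges$effect))
    expect_true(truth$focal %in% truth$factors$id)
  }
})

test_that("generation is deterministic in (params, seed) and sensitive to seed", {
  p <- small_params()
  a <- generate_true_system(p, seed = 5)
  b <- generate_true_system(p, seed = 5)
  expect_identical(a, b)
  c <- generate_true_system(p, seed = 6)
  expect_false(identical(edge_keys_of(a$core_edges), edge_keys_of(c$core_edges)))

  ea <- sample_group_models(a, p, seed = 7)
  eb <- sample_group_models(b, p, seed = 7)
  expect_identical(as.data.frame(ea), as.data.frame(eb))
  ec <- sample_group_models(a, p, seed = 8)
  expect_false(identical(as.data.frame(ea), as.data.frame(ec)))
})

test_that("structurally infeasible parameters are rejected", {
  expect_error(
    generate_true_system(small_params(n_core_edges = 1)),
    "n_core_edges"
  )
  expect_error(gen_params(p_detect = 1.2), "probabilities")
  expect_error(gen_params(n_groups = 0), "positive")
})

test_that("degenerate sampling parameters behave as stated", {
  p1 <- small_params(p_detect = 1, p_detect_action = 1, flip_prob = 0, noise_rate = 0)
  truth <- generate_true_system(p1, seed = 3)
  edges <- sample_group_models(truth, p1, seed = 4)
  latent_keys <- edge_keys_of(dplyr::bind_rows(truth$core_edges, truth$peripheral_edges))
  for (g in unique(edges$group_id)) {
    expect_equal(edge_keys_of(edges[edges$group_id == g, ]), latent_keys)
  }

  p0 <- small_params(p_detect = 0, p_detect_action = 0, noise_rate = 0)
  edges0 <- sample_group_models(generate_true_system(p0, seed = 3), p0, seed = 4)
  expect_equal(nrow(edges0), 0L)
  # factor sets still contain the focal
  f <- cld_factors(edges0, focal = p0$focal)
  expect_true(all(f$id == p0$focal))
})

test_that("recovery metrics follow the stated conventions", {
  p <- small_params(p_detect = 1, p_detect_action = 1, flip_prob = 0, noise_rate = 0)
  truth <- generate_true_system(p, seed = 11)
  edges <- sample_group_models(truth, p, seed = 12)
  core <- extract_core(union_models(edges, focal = truth$focal), min_support = 2)
  m <- recovery_metrics(core, truth)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 1)

  empty_core <- extract_core(union_models(edges, focal = truth$focal),
    min_support = p$n_groups + 1L
  )
  m0 <- recovery_metrics(empty_core, truth)
  expect_equal(m0$precision, 1) # empty-core convention
  expect_equal(m0$recall, 0)
  expect_equal(m0$f1, 0)
})

test_that("without sign flips core edges never conflict across groups", {
  p <- small_params(flip_prob = 0, p_unique_noise = 1)
  truth <- generate_true_system(p, seed = 13)
  edges <- sample_group_models(truth, p, seed = 14)
  agg <- union_models(edges, focal = truth$focal)
  conf <- polarity_conflicts(agg)
  core_pairs <- paste(truth$core_edges$cause, truth$core_edges$effect)
  expect_length(intersect(paste(conf$cause, conf$effect), core_pairs), 0L)
})

test_that("per-group counts land in the study's reported range at defaults", {
  p <- gen_params()
  means <- vapply(1:20, function(r) {
    truth <- generate_true_system(p, seed = 7000 + r)
    edges <- sample_group_models(truth, p, seed = 7500 + r)
    mean(summary_stats(edges)$n_factors)
  }, numeric(1))
  expect_true(all(means >= 46 & means <= 85))
})

test_that("recall does not increase with noise (in expectation)", {
  p_lo <- small_params(noise_rate = 0)
  p_hi <- small_params(noise_rate = 30)
  rec <- function(p) {
    r <- run_recovery_experiment(p, n_reps = 30, seed = 99)
    mean(r$recall)
  }
  expect_gte(rec(p_lo) + 1e-9, rec(p_hi))
})

test_that("the recovery experiment is deterministic and scored by set arithmetic", {
  p <- small_params()
  a <- run_recovery_experiment(p, n_reps = 3, seed = 17)
  b <- run_recovery_experiment(p, n_reps = 3, seed = 17)
  expect_equal(as.data.frame(a), as.data.frame(b))
  # recount one replicate by hand
  truth <- generate_true_system(p, seed = 17 + 1000)
  edges <- sample_group_models(truth, p, seed = 17 + 1500)
  edges <- canonicalize_labels(edges, focal = truth$focal)
  core <- extract_core(union_models(edges, focal = truth$focal), min_support = 2)
  inter <- length(intersect(edge_keys_of(core), edge_keys_of(truth$core_edges)))
  expect_equal(a$precision[1], inter / nrow(core))
  expect_equal(a$recall[1], inter / nrow(truth$core_edges))
})
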