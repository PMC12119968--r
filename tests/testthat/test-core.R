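make_agg <- function(edges, focal = "focal") union_models(edges, focal = focal)

test_that("a supported triangle through the focal survives with reason 'both'", {
  tri <- dplyr::bind_rows(
    triangle(c("focal", "a", "b"), group_id = "g1"),
    triangle(c("focal", "a", "b"), group_id = "g2")
  )
  core <- extract_core(make_agg(tri), min_support = 2)
  expect_equal(nrow(core), 3L)
  expect_setequal(core$reason, "both")
  g <- glance(core)
  expect_equal(g$n_nodes, 3L)
  expect_equal(g$n_edges, 3L)
})

test_that("support filtering precedes structural filtering", {
  edges <- dplyr::bind_rows(
    triangle(c("focal", "a", "b"), group_id = "g1"),
    triangle(c("focal", "a", "b"), group_id = "g2"),
    ed("a", "weak", group_id = "g1") # support 1
  )
  core <- extract_core(make_agg(edges), min_support = 2)
  expect_false("weak" %in% c(core$cause, core$effect))
  expect_equal(nrow(core), 3L)
})

test_that("edges with no cycle and no focal path are pruned to a fixed point", {
  # x -> y supported twice but disconnected from the focal and acyclic
  edges <- dplyr::bind_rows(
    triangle(c("focal", "a", "b"), group_id = "g1"),
    triangle(c("focal", "a", "b"), group_id = "g2"),
    ed("x", "y", group_id = "g1"), ed("x", "y", group_id = "g2"),
    # chain whose qualification depends on a support-1 link: w -> x2 -> focal,
    # where x2 -> focal has support 1 and w -> x2 support 2
    ed("w", "x2", group_id = "g1"), ed("w", "x2", group_id = "g2"),
    ed("x2", "focal", group_id = "g1")
  )
  core <- extract_core(make_agg(edges), min_support = 2)
  expect_setequal(unique(c(core$cause, core$effect)), c("focal", "a", "b"))
  expect_equal(nrow(core), 3L)
})

test_that("causal connectivity covers ancestors and descendants of the focal", {
  edges <- dplyr::bind_rows(
    ed("a", "b"), ed("b", "focal"), # ancestor path
    ed("focal", "c"), ed("c", "d"), # descendant path
    ed("e", "f") # disconnected
  )
  out <- causal_connectivity(edges, focal = "focal")
  expect_equal(nrow(out), 4L)
  expect_false("e" %in% out$cause)
})

test_that("core extraction equals the brute-force filter oracle on random aggregates", {
  set.seed(61)
  for (i in 1:30) {
    edges <- random_battery(
      n_groups = sample(2:4, 1), n_nodes = sample(8:14, 1),
      n_rows = sample(15:40, 1)
    )
    agg <- make_agg(edges)
    for (ms in 1:2) {
      core <- extract_core(agg, min_support = ms)
      oracle <- brute_core_filter(agg, "focal", ms)
      expect_equal(edge_keys_of(core), edge_keys_of(oracle))
    }
  }
})

test_that("cores shrink weakly with min_support and re-extraction is the identity", {
  set.seed(62)
  for (i in 1:10) {
    edges <- random_battery(n_groups = 4, n_nodes = 10, n_rows = 30)
    agg <- make_agg(edges)
    prev <- NULL
    for (ms in 1:4) {
      core <- extract_core(agg, min_support = ms)
      if (!is.null(prev)) {
        expect_true(all(edge_keys_of(core) %in% prev))
      }
      prev <- edge_keys_of(core)
      again <- extract_core(core, min_support = ms)
      expect_equal(edge_keys_of(again), edge_keys_of(core))
      expect_equal(again$reason, core$reason)
    }
  }
})

test_that("with min_support 1 a fully focal-connected input passes through unchanged", {
  edges <- dplyr::bind_rows(
    ed("a", "focal"), ed("focal", "b"), ed("b", "c"), ed("d", "a")
  )
  agg <- make_agg(edges)
  core <- extract_core(agg, min_support = 1)
  expect_equal(edge_keys_of(core), edge_keys_of(agg))
})

test_that("core soundness: every surviving edge has a verifiable witness", {
  set.seed(63)
  for (i in 1:10) {
    edges <- random_battery(n_groups = 3, n_nodes = 10, n_rows = 30)
    agg <- make_agg(edges)
    core <- extract_core(agg, min_support = 2)
    E <- as.data.frame(core)[, c("cause", "effect", "polarity")]
    for (j in seq_len(nrow(core))) {
      u <- core$cause[j]
      v <- core$effect[j]
      on_cycle <- u %in% bf_reach(E, v)
      focal_conn <- v == "focal" || "focal" %in% bf_reach(E, v) ||
        u == "focal" || u %in% bf_reach(E, "focal")
      if (core$reason[j] == "feedback") expect_true(on_cycle && !focal_conn)
      if (core$reason[j] == "focal_connected") expect_true(focal_conn && !on_cycle)
      if (core$reason[j] == "both") expect_true(on_cycle && focal_conn)
    }
  }
})

test_that("focal and parameter errors are raised", {
  agg <- make_agg(ed("a", "b"), focal = "a")
  expect_error(extract_core(agg, min_support = 0), "min_support")
  expect_error(extract_core(agg, focal = "nonexistent"), "absent")
})

test_that("core report counts agree with a recount of its own export", {
  tri <- dplyr::bind_rows(
    triangle(c("focal", "a", "b"), group_id = "g1"),
    triangle(c("focal", "a", "b"), group_id = "g2")
  )
  core <- extract_core(make_agg(tri), min_support = 2)
  rep <- core_report(core)
  expect_equal(rep$n_nodes, 3L)
  expect_equal(rep$n_edges, 3L)
  expect_equal(rep$loop_inventory$n_reinforcing, 1L)
  expect_equal(rep$support_histogram[[1]]$support, 2L)
  expect_equal(rep$support_histogram[[1]]$n_edges, 3L)
  # recount from the tidy CSV-style export
  exported <- tidy(core)
  expect_equal(rep$n_edges, nrow(exported))
  expect_equal(rep$n_nodes, length(unique(c(exported$cause, exported$effect))))

  empty <- extract_core(make_agg(ed("a", "b"), focal = "a"), min_support = 5)
  rep0 <- core_report(empty)
  expect_equal(rep0$n_edges, 0L)
  expect_equal(rep0$loop_inventory$n_loops, 0L)
})

test_that("indirect paths add consensus only when sign-consistent", {
  edges <- dplyr::bind_rows(
    ed("a", "c", "+", group_id = "g1"),
    ed("a", "b", "+", group_id = "g2"), ed("b", "c", "+", group_id = "g2"),
    ed("a", "b", "+", group_id = "g3"), ed("b", "c", "-", group_id = "g3")
  )
  agg <- union_models(edges, focal = "c")
  cons <- indirect_path_consensus(agg, edges)
  rec <- cons[cons$cause == "a" & cons$effect == "c" & cons$polarity == "+", ]
  expect_equal(rec$direct_support, 1L)
  expect_equal(rec$indirect_groups[[1]], "g2") # g3's path nets "-", no witness
  expect_equal(rec$effective_support, 2L)
  expect_equal(rec$witnesses[[1]]$g2, c("a", "b", "c"))
})

test_that("indirect consensus matches an exhaustive per-group path oracle", {
  set.seed(64)
  edges <- random_battery(n_groups = 4, n_nodes = 9, n_rows = 18)
  agg <- union_models(edges)
  max_int <- 2L
  cons <- indirect_path_consensus(agg, edges, max_intermediates = max_int)
  for (j in seq_len(nrow(cons))) {
    expected <- cons$direct_support[j]
    direct_groups <- agg$supporting_groups[[
      which(agg$cause == cons$cause[j] & agg$effect == cons$effect[j] &
        agg$polarity == cons$polarity[j])
    ]]
    for (g in setdiff(unique(edges$group_id), direct_groups)) {
      sub <- as.data.frame(edges[edges$group_id == g, c("cause", "effect", "polarity")])
      paths <- brute_signed_paths(sub, cons$cause[j], cons$effect[j], max_int + 1L)
      hit <- any(vapply(paths, function(p) {
        tail(p$nodes, 1) == cons$effect[j] && length(p$nodes) >= 3L &&
          sign_prod(p$signs) == cons$polarity[j]
      }, logical(1)))
      if (hit) expected <- expected + 1L
    }
    expect_equal(cons$effective_support[j], expected)
  }
  # every witness path exists edge-by-edge in its group and nets the polarity
  for (j in seq_len(nrow(cons))) {
    for (g in cons$indirect_groups[[j]]) {
      w <- cons$witnesses[[j]][[g]]
      sub <- edges[edges$group_id == g, ]
      hops <- cbind(w[-length(w)], w[-1])
      sign_opts <- apply(hops, 1, function(h) {
        sub$polarity[sub$cause == h[1] & sub$effect == h[2]]
      }, simplify = FALSE)
      expect_true(all(lengths(sign_opts) >= 1L))
      combos <- expand.grid(sign_opts, stringsAsFactors = FALSE)
      nets <- apply(combos, 1, function(s) sign_prod(as.character(s)))
      expect_true(cons$polarity[j] %in% nets)
    }
  }
})

test_that("aggregate/model mismatch is an error", {
  edges <- dplyr::bind_rows(ed("a", "b", group_id = "g1"), ed("a", "b", group_id = "g2"))
  agg <- union_models(edges, focal = "a")
  expect_error(
    indirect_path_consensus(agg, edges[edges$group_id == "g1", ]),
    "absent from the supplied models"
  )
})
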