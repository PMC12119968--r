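# Independent brute-force oracles, deliberately written in plain base R with
# no graph library: permutation-based cycle enumeration, BFS reachability,
# and edge-row DFS path search. These stay independent of the package's
# implementation paths (igraph SCC/reachability, bounded DFS enumerator).

perms <- function(v) {
  if (length(v) <= 1L) {
    return(list(v))
  }
  out <- list()
  for (i in seq_along(v)) {
    for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# every simple directed cycle by testing node subsets and rotations;
# sign-expanded like the implementation
brute_cycles <- function(edges, max_len = Inf) {
  nodes <- sort(unique(c(edges$cause, edges$effect)))
  n <- length(nodes)
  pair_signs <- split(edges$polarity, paste(edges$cause, edges$effect, sep = "|"))
  pair_signs <- lapply(pair_signs, function(s) sort(unique(s)))
  out <- list()
  if (n < 2L) {
    return(out)
  }
  for (k in 2:min(n, max_len)) {
    for (sub in utils::combn(nodes, k, simplify = FALSE)) {
      # canonical rotation: fix the smallest node first, permute the rest
      for (perm in perms(sub[-1L])) {
        cyc <- c(sub[1L], perm)
        ring <- c(cyc, cyc[1L])
        opts <- lapply(seq_len(k), function(i) pair_signs[[paste(ring[i], ring[i + 1L], sep = "|")]])
        if (any(vapply(opts, is.null, logical(1)))) next
        grid <- expand.grid(opts, stringsAsFactors = FALSE)
        for (r in seq_len(nrow(grid))) {
          out[[length(out) + 1L]] <- list(
            nodes = cyc,
            signs = as.character(unlist(grid[r, ], use.names = FALSE))
          )
        }
      }
    }
  }
  out
}

loop_key <- function(nodes, signs) {
  paste(paste(nodes, collapse = ","), paste(signs, collapse = ""), sep = "|")
}

impl_loop_keys <- function(loops) {
  sort(vapply(
    seq_len(nrow(loops)),
    function(i) loop_key(loops$nodes[[i]], loops$signs[[i]]), character(1)
  ))
}

brute_loop_keys <- function(cycles) {
  sort(vapply(cycles, function(c) loop_key(c$nodes, c$signs), character(1)))
}

# nodes reachable from `from` by >= 1 edge (BFS over edge rows)
bf_reach <- function(E, from) {
  seen <- character(0)
  frontier <- from
  while (length(frontier) > 0L) {
    nxt <- setdiff(unique(E$effect[E$cause %in% frontier]), seen)
    seen <- union(seen, nxt)
    frontier <- nxt
  }
  seen
}

# fixed-point consensus filter via exhaustive path/cycle tests
brute_core_filter <- function(agg, focal, min_support) {
  E <- as.data.frame(agg)[agg$support >= min_support, c("cause", "effect", "polarity")]
  repeat {
    if (nrow(E) == 0L) break
    keep <- logical(nrow(E))
    for (i in seq_len(nrow(E))) {
      u <- E$cause[i]
      v <- E$effect[i]
      on_cycle <- u %in% bf_reach(E, v)
      to_focal <- v == focal || focal %in% bf_reach(E, v)
      from_focal <- u == focal || u %in% bf_reach(E, focal)
      keep[i] <- on_cycle || to_focal || from_focal
    }
    if (all(keep)) break
    E <- E[keep, , drop = FALSE]
  }
  E[order(E$cause, E$effect, E$polarity), , drop = FALSE]
}

edge_keys_of <- function(E) {
  sort(paste(E$cause, E$effect, E$polarity, sep = "|"))
}

# all sign-resolved simple paths from `from` whose endpoint is in `targets`,
# with at most max_edges edges; DFS over edge rows, one path per sign choice
brute_signed_paths <- function(E, from, targets, max_edges) {
  res <- list()
  rec <- function(node, visited, signs) {
    if (length(signs) > 0L && node %in% targets) {
      res[[length(res) + 1L]] <<- list(nodes = visited, signs = signs)
    }
    if (length(signs) >= max_edges) {
      return()
    }
    idx <- which(E$cause == node & !(E$effect %in% visited))
    for (i in idx) {
      rec(E$effect[i], c(visited, E$effect[i]), c(signs, E$polarity[i]))
    }
  }
  rec(from, from, character(0))
  res
}

sign_prod <- function(signs) if (sum(signs == "-") %% 2L == 0L) "+" else "-"
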