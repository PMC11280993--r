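#' Brute-force reference implementations
#'
#' Slow, direct-enumeration counterparts of the incremental cost machinery,
#' kept deliberately free of shared code paths so they can serve as
#' independent cross-checks in tests and validation scripts. They enumerate
#' member pairs and probe the edge set directly.
#'
#' @name reference-oracles
NULL

# is (u, v) an edge of g? direct probe of the canonical edge matrix
ref_has_edge <- function(g, u, v) {
  if (u == v) return(FALSE)
  lo <- min(u, v); hi <- max(u, v)
  any(g$edges[, 1L] == lo & g$edges[, 2L] == hi)
}

#' @rdname reference-oracles
#' @param g An `ipgs_graph`.
#' @param A,B Integer member sets of two super nodes (`identical(A, B)` for
#'   the self pair).
#' @return `ref_pair_cost`: the half-rule encoding cost of the pair, found
#'   by counting edges over all member pairs one by one.
#' @export
ref_pair_cost <- function(g, A, B) {
  same <- setequal(A, B)
  e <- 0L; f <- 0L
  if (same) {
    A <- sort(A)
    if (length(A) >= 2L) {
      for (i in seq_len(length(A) - 1L)) for (j in (i + 1L):length(A)) {
        f <- f + 1L
        if (ref_has_edge(g, A[i], A[j])) e <- e + 1L
      }
    }
  } else {
    for (u in A) for (v in B) {
      f <- f + 1L
      if (ref_has_edge(g, u, v)) e <- e + 1L
    }
  }
  if (e == 0L) return(0)
  if (2 * e <= f) e else 1 + f - e
}

#' @rdname reference-oracles
#' @param memberships List of member sets (a partition of the nodes of `g`).
#' @param a Index into `memberships` of the super node whose cost is wanted.
#' @return `ref_node_cost`: sum of the pair costs of every pair incident to
#'   super node `a` (self pair included).
#' @export
ref_node_cost <- function(g, memberships, a) {
  tot <- 0
  for (b in seq_along(memberships)) {
    if (length(memberships[[b]]) == 0L) next
    tot <- tot + if (b == a) {
      ref_pair_cost(g, memberships[[a]], memberships[[a]])
    } else {
      ref_pair_cost(g, memberships[[a]], memberships[[b]])
    }
  }
  tot
}

#' @rdname reference-oracles
#' @return `ref_total_size`: `|E/| + |C+| + |C-|` of the half-rule encoding
#'   of the partition, summed pair by pair.
#' @export
ref_total_size <- function(g, memberships) {
  live <- which(lengths(memberships) > 0L)
  tot <- 0
  for (i in seq_along(live)) {
    for (j in i:length(live)) {
      tot <- tot + ref_pair_cost(g, memberships[[live[i]]],
                                 memberships[[live[j]]])
    }
  }
  tot
}

#' @rdname reference-oracles
#' @param a,b Indices of two distinct super nodes in `memberships`.
#' @return `ref_merge_saving`: `1 - Cost(a U b) / (Cost(a) + Cost(b))` with
#'   every cost found by exhaustive enumeration.
#' @export
ref_merge_saving <- function(g, memberships, a, b) {
  ca <- ref_node_cost(g, memberships, a)
  cb <- ref_node_cost(g, memberships, b)
  if (ca + cb == 0) stop("undefined saving: both super nodes are isolated")
  merged <- memberships
  merged[[a]] <- c(memberships[[a]], memberships[[b]])
  merged[[b]] <- integer(0)
  cu <- ref_node_cost(g, merged, a)
  1 - cu / (ca + cb)
}

#' Exhaustive best-pair greedy summarization baseline
#'
#' A small-scale reference summarizer: starting from singletons, repeatedly
#' evaluates the saving of every live super-node pair by exhaustive
#' enumeration and applies the best strictly size-reducing merge, stopping
#' when none remains. Quadratic per step and only meant for graphs of a few
#' dozen nodes, where it gives the representation size a greedy optimum of
#' the saving criterion can reach.
#'
#' @param g An `ipgs_graph`.
#' @return A list with `memberships` (final member sets) and `total_size`.
#' @export
ref_greedy_summarize <- function(g) {
  memberships <- as.list(seq_len(g$n_nodes))
  repeat {
    live <- which(lengths(memberships) > 0L)
    if (length(live) < 2L) break
    size0 <- ref_total_size(g, memberships)
    best <- NULL; best_size <- size0
    for (i in seq_len(length(live) - 1L)) {
      for (j in (i + 1L):length(live)) {
        a <- live[i]; b <- live[j]
        trial <- memberships
        trial[[a]] <- c(trial[[a]], trial[[b]])
        trial[[b]] <- integer(0)
        sz <- ref_total_size(g, trial)
        if (sz < best_size) {
          best_size <- sz
          best <- c(a, b)
        }
      }
    }
    if (is.null(best)) break
    memberships[[best[1L]]] <- c(memberships[[best[1L]]],
                                 memberships[[best[2L]]])
    memberships[[best[2L]]] <- integer(0)
  }
  list(memberships = memberships, total_size = ref_total_size(g, memberships))
}

#' Brute-force flow rates by path enumeration
#'
#' Enumerates every simple path from the target set and takes, for each node,
#' the maximum cumulative weight over all minimum-hop paths reaching it.
#' Exponential; only for graphs of a dozen nodes or so, as an oracle for
#' [flow_rates()].
#'
#' @param g An `ipgs_graph`.
#' @param targets Integer target node ids.
#' @return Named numeric vector of rates for reachable non-target nodes
#'   (targets have rate 0).
#' @export
ref_flow_rates <- function(g, targets) {
  adj <- adjacency(g)
  n <- g$n_nodes
  # BFS distances from the target set
  dist <- rep(NA_integer_, n)
  dist[targets] <- 0L
  frontier <- targets
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj$nbr[frontier])), which(!is.na(dist)))
    dist[nxt] <- dist[frontier[1L]] + 1L
    frontier <- nxt
  }
  best <- rep(-Inf, n)
  best[targets] <- 0
  walk <- function(u, acc, hops) {
    for (i in seq_along(adj$nbr[[u]])) {
      v <- adj$nbr[[u]][i]
      if (is.na(dist[v]) || dist[v] != hops + 1L) next  # stay on min-hop layers
      val <- acc + adj$w[[u]][i]
      if (val > best[v]) best[v] <<- val
      walk(v, val, hops + 1L)
    }
  }
  for (t in targets) walk(t, 0, 0L)
  reach <- which(is.finite(best))
  stats::setNames(best[reach], reach)
}
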