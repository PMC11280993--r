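#' Default merge-acceptance threshold schedule
#'
#' `theta(t) = 1 / (1 + t)`: strict early (only high-saving merges),
#' permissive late, decreasing toward 0 so that slowly improving merges are
#' still found in later iterations.
#'
#' @param t Iteration index (`>= 1`).
#' @return Numeric threshold.
#' @export
threshold_default <- function(t) 1 / (1 + t)

#' Summarizer configuration
#'
#' @param iterations Number of divide-and-merge iterations `T`.
#' @param signature_length DOPH signature length `k`. Two super nodes fall
#'   into the same candidate group with probability roughly `Jw^k`, so small
#'   `k` suits graphs with moderate neighborhood overlap and larger `k`
#'   near-duplicate structure.
#' @param seed Integer seed; all randomness (permutations, visit order)
#'   derives from it.
#' @param max_group_size Maximum candidate-group size before recursive
#'   splitting; bounds the quadratic within-group search.
#' @param weight_cap Unary-expansion cap for the DOPH signatures.
#' @param threshold Threshold schedule, a function of the iteration index.
#' @param alpha Personalization strength (used by
#'   [summarize_personalized()] only).
#' @return A list of class `ipgs_config`.
#' @export
summarizer_config <- function(iterations = 20L, signature_length = 5L,
                              seed = 42L, max_group_size = 500L,
                              weight_cap = 16L,
                              threshold = threshold_default,
                              alpha = 1) {
  stopifnot(iterations >= 1L, signature_length >= 1L, max_group_size >= 1L,
            is.function(threshold), alpha >= 0)
  structure(list(iterations = as.integer(iterations),
                 signature_length = as.integer(signature_length),
                 seed = as.integer(seed),
                 max_group_size = as.integer(max_group_size),
                 weight_cap = as.integer(weight_cap),
                 threshold = threshold, alpha = alpha),
            class = "ipgs_config")
}

# mutable summarization state shared by the iteration loop
new_state <- function(g, imp = NULL, pinned = integer(0)) {
  n <- g$n_nodes
  e <- new.env(parent = emptyenv())
  e$g <- g
  e$adj <- adjacency(g)
  e$node2super <- seq_len(n)
  e$members <- as.list(seq_len(n))
  e$sizes <- rep(1L, n)
  e$imp <- imp
  e$pinned <- rep(FALSE, n)
  e$pinned[pinned] <- TRUE
  e$cost_plain <- rep(NA_real_, n)
  e$cost_wtd <- rep(NA_real_, n)
  e
}

state_partition <- function(e) {
  structure(list(node2super = e$node2super, members = e$members,
                 sizes = e$sizes),
            class = "ipgs_partition")
}

# cost of a member set under the state; remap folds super `from` into `to`
state_cost <- function(e, members, self_id, from = NULL, to = NULL) {
  cnt <- super_tallies(members, e$adj, e$node2super, from, to)
  isum <- if (is.null(e$imp)) NULL else
    importance_sums(members, e$adj, e$node2super, e$imp, from, to)
  cost_from_tallies(cnt, self_id, length(members), e$sizes, isum)
}

state_node_cost <- function(e, a) {
  if (is.na(e$cost_plain[a])) {
    cc <- state_cost(e, e$members[[a]], a)
    e$cost_plain[a] <- cc[1L]
    e$cost_wtd[a] <- cc[2L]
  }
  c(e$cost_plain[a], e$cost_wtd[a])
}

state_merge <- function(e, a, b) {
  keep <- min(a, b); drop <- max(a, b)
  U <- c(e$members[[keep]], e$members[[drop]])
  e$node2super[e$members[[drop]]] <- keep
  e$members[[keep]] <- U
  e$members[drop] <- list(NULL)
  e$sizes[keep] <- e$sizes[keep] + e$sizes[drop]
  e$sizes[drop] <- 0L
  touched <- unique(e$node2super[unlist(e$adj$nbr[U], use.names = FALSE)])
  e$cost_plain[c(keep, drop, touched)] <- NA_real_
  e$cost_wtd[c(keep, drop, touched)] <- NA_real_
  keep
}

# plain encoding cost of the (a, b) pair in the current state
state_pair_cost <- function(e, a, b, cnt_a) {
  eab <- cnt_a[b]
  f <- e$sizes[a] * e$sizes[b]
  if (2 * eab <= f) eab else 1 + f - eab
}

#' One merge phase over the candidate groups
#'
#' Within each group, super nodes are visited in seeded-random order; each
#' still-unmerged node is paired with the group member giving the maximum
#' saving (ties toward the smallest id) and the merge is accepted iff the
#' saving reaches the iteration threshold and the realized total-size change
#' is non-positive. Pinned (target) super nodes neither initiate nor receive
#' merges. Accepted merges update the state immediately.
#'
#' @param state Internal summarizer state.
#' @param groups An `ipgs_groups` partition of the active super nodes.
#' @param theta Acceptance threshold for this iteration.
#' @param order_seed Seed for the visit order.
#' @return Number of accepted merges.
#' @keywords internal
merge_phase <- function(state, groups, theta, order_seed) {
  e <- state
  accepted <- 0L
  gi <- 0L
  for (grp in groups$groups) {
    gi <- gi + 1L
    grp <- grp[!e$pinned[grp]]
    if (length(grp) < 2L) next
    order <- with_seed(derive_seed(order_seed, gi), sample(grp))
    for (u in order) {
      if (e$sizes[u] == 0L) next  # already merged away
      partners <- grp[grp != u & e$sizes[grp] > 0L]
      if (length(partners) == 0L) next
      cu <- state_node_cost(e, u)
      cnt_u <- super_tallies(e$members[[u]], e$adj, e$node2super)
      best_v <- NA_integer_; best_s <- -Inf; best_delta <- NA_real_
      for (v in sort(partners)) {
        cv <- state_node_cost(e, v)
        denom_w <- cu[2L] + cv[2L]
        denom_p <- cu[1L] + cv[1L]
        if (denom_p == 0) next  # both isolated: undefined saving
        U <- c(e$members[[u]], e$members[[v]])
        cun <- state_cost(e, U, min(u, v), from = max(u, v), to = min(u, v))
        s <- 1 - cun[2L] / denom_w
        delta <- cun[1L] - denom_p + state_pair_cost(e, u, v, cnt_u)
        if (s > best_s + 1e-12) {
          best_v <- v; best_s <- s; best_delta <- delta
        }
      }
      if (!is.na(best_v) && best_s >= theta - 1e-12 && best_delta <= 1e-9) {
        state_merge(e, u, best_v)
        accepted <- accepted + 1L
        if (e$sizes[u] == 0L) next
        cnt_u <- super_tallies(e$members[[u]], e$adj, e$node2super)
      }
    }
  }
  accepted
}

# neighbor vector straight from the state (avoids re-deriving adjacency)
state_neighbor_vector <- function(e, a) {
  A <- e$members[[a]]
  nb <- unlist(e$adj$nbr[A], use.names = FALSE)
  if (length(nb) == 0L) {
    return(list(owner = a, ids = integer(0), w = integer(0),
                dimension = e$g$n_nodes))
  }
  wt <- as.numeric(unlist(e$adj$w[A], use.names = FALSE))
  if (!is.null(e$imp)) {
    wt <- wt * e$imp[unlist(e$adj$eid[A], use.names = FALSE)]
  }
  s <- rowsum(wt, nb)
  w <- as.integer(ceiling(s[, 1L]))
  w[w < 1L] <- 1L
  list(owner = a, ids = as.integer(rownames(s)), w = w,
       dimension = e$g$n_nodes)
}

run_summarizer <- function(g, cfg, targets = integer(0)) {
  fr <- NULL; imp <- NULL
  if (length(targets) > 0L) {
    fr <- flow_rates(g, targets)
    imp <- edge_importance(g, fr, cfg$alpha)
    targets <- fr$targets
  }
  e <- new_state(g, imp = imp, pinned = targets)
  trace <- data.frame(iteration = integer(0), merges = integer(0),
                      total_size = numeric(0))
  if (g$n_nodes > 0L) {
    for (t in seq_len(cfg$iterations)) {
      act <- which(e$sizes > 0L)
      vectors <- lapply(act, function(a) state_neighbor_vector(e, a))
      dcfg <- doph_config(k = cfg$signature_length,
                          seed = derive_seed(cfg$seed, t),
                          weight_cap = cfg$weight_cap)
      groups <- divide_groups(vectors, dcfg, cfg$max_group_size)
      merges <- merge_phase(e, groups, cfg$threshold(t),
                            derive_seed(cfg$seed, 50000 + t))
      trace <- rbind(trace, data.frame(
        iteration = t, merges = merges,
        total_size = summary_total_size(g, state_partition(e))
      ))
    }
  }
  part <- state_partition(e)
  enc <- encode_all(g, part)
  report <- compression_report(enc, g)
  structure(
    list(summary = enc$summary, corrections = enc$corrections,
         report = report, trace = trace, config = cfg,
         targets = targets, flow = fr),
    class = "ipgs_summary_result"
  )
}

#' Summarize a graph (non-personalized)
#'
#' Runs the iterative pipeline: per iteration, integer-weighted neighborhood
#' vectors of the current super nodes are hashed into DOPH signatures
#' (reseeded per iteration), equal signatures form candidate groups, and the
#' best merge of each visited group member is accepted when its saving
#' reaches the iteration threshold. After the final iteration the super
#' edges and correction sets are materialized. The result is lossless:
#' [decode_summary()] on it reproduces the input graph's edges exactly.
#'
#' @param g An `ipgs_graph`.
#' @param cfg A [summarizer_config()].
#' @return An `ipgs_summary_result` with `summary`, `corrections`, `report`
#'   (see [compression_report()]) and `trace` (per-iteration merges and
#'   total size).
#' @examples
#' g <- twins_graph(4, 3, seed = 1)
#' res <- summarize_graph(g, summarizer_config(iterations = 5, seed = 1))
#' res$report$ratio
#' @export
summarize_graph <- function(g, cfg = summarizer_config()) {
  stopifnot(inherits(g, "ipgs_graph"), inherits(cfg, "ipgs_config"))
  run_summarizer(g, cfg)
}

#' Summarize a graph around target nodes (personalized)
#'
#' As [summarize_graph()], but the influence structure around the targets is
#' preserved: cumulative flow rates from the target set are computed first,
#' neighborhood vectors and merge costs are scaled by the resulting edge
#' importance (corrections near targets become more expensive, keeping the
#' summary finer there), and target nodes are pinned — they always remain
#' singleton super nodes. The output is lossless exactly as in the
#' non-personalized variant. An empty target set degenerates to
#' [summarize_graph()] exactly.
#'
#' @param g An `ipgs_graph`.
#' @param targets Target node ids or labels (possibly empty).
#' @param cfg A [summarizer_config()]; `cfg$alpha` sets the personalization
#'   strength.
#' @return An `ipgs_summary_result`; additionally carries `targets` and the
#'   `flow` rates used.
#' @export
summarize_personalized <- function(g, targets, cfg = summarizer_config()) {
  stopifnot(inherits(g, "ipgs_graph"), inherits(cfg, "ipgs_config"))
  if (length(targets) == 0L) return(run_summarizer(g, cfg))
  if (is.character(targets)) {
    idx <- match(targets, g$labels)
    if (anyNA(idx)) stop("unknown target label: ", targets[which(is.na(idx))[1L]])
    targets <- idx
  }
  run_summarizer(g, cfg, targets = as.integer(targets))
}

#' @export
print.ipgs_summary_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<ipgs_summary_result> %d -> %d nodes, %d edges -> %d (E/ %d, C+ %d, C- %d), ratio %s\n",
    r$o_nodes, r$s_nodes, r$o_edges, r$s_edges_total, r$superedges,
    r$c_plus_size, r$c_minus_size,
    if (is.na(r$ratio)) "undefined" else sprintf("%.4f", r$ratio)))
  invisible(x)
}
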