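#' Initial all-singleton super-node partition
#'
#' Every node starts as its own super node; summarization merges super nodes
#' while the correction-set encoding keeps the representation lossless.
#'
#' @param g An `ipgs_graph`.
#' @return An object of class `ipgs_partition` with fields `node2super`
#'   (integer map node id -> super id), `members` (list, indexed by super id;
#'   `NULL` for retired ids) and `sizes` (integer member counts, 0 for
#'   retired ids).
#' @export
singleton_partition <- function(g) {
  n <- g$n_nodes
  structure(
    list(node2super = seq_len(n),
         members = as.list(seq_len(n)),
         sizes = rep(1L, n)),
    class = "ipgs_partition"
  )
}

#' Active super-node ids of a partition
#' @param part An `ipgs_partition`.
#' @return Sorted integer vector of live super-node ids.
#' @export
active_supers <- function(part) which(part$sizes > 0L)

#' @export
print.ipgs_partition <- function(x, ...) {
  cat(sprintf("<ipgs_partition> %d nodes in %d super nodes\n",
              length(x$node2super), sum(x$sizes > 0L)))
  invisible(x)
}

# tally of original edges from `members` to every super node, with optional
# remap of super id `from` to `to` (used for hypothetical merges)
super_tallies <- function(members, adj, node2super, from = NULL, to = NULL) {
  nb <- unlist(adj$nbr[members], use.names = FALSE)
  if (length(nb) == 0L) return(integer(length(node2super)))
  sup <- node2super[nb]
  if (!is.null(from)) sup[sup == from] <- to
  tabulate(sup, nbins = length(node2super))
}

# cost (and importance-weighted cost) of one super node given tallies.
# Returns c(plain, weighted); weighted == plain when impsum is NULL.
# The weighted variant multiplies each pair's encoding cost by the mean
# importance of the pair's member edges (personalized mode). Self pair:
# sums and counts are both doubled, so the importance ratio is unchanged.
cost_from_tallies <- function(cnt, self_id, msize, sizes, impsum = NULL) {
  ids <- which(cnt > 0L)
  plain <- 0; wtd <- 0
  for (b in ids) {
    if (b == self_id) {
      e <- cnt[b] / 2
      f <- msize * (msize - 1) / 2
    } else {
      e <- cnt[b]
      f <- msize * sizes[b]
    }
    cost <- if (2 * e <= f) e else 1 + f - e
    plain <- plain + cost
    if (!is.null(impsum)) wtd <- wtd + cost * impsum[b] / cnt[b]
  }
  if (is.null(impsum)) wtd <- plain
  c(plain, wtd)
}

# per-super sums of edge importance from `members`, aligned with tallies
importance_sums <- function(members, adj, node2super, imp,
                            from = NULL, to = NULL) {
  nb <- unlist(adj$nbr[members], use.names = FALSE)
  if (length(nb) == 0L) return(numeric(length(node2super)))
  sup <- node2super[nb]
  if (!is.null(from)) sup[sup == from] <- to
  iv <- imp[unlist(adj$eid[members], use.names = FALSE)]
  out <- numeric(length(node2super))
  rs <- rowsum(iv, sup)
  out[as.integer(rownames(rs))] <- rs[, 1L]
  out
}

#' Edge statistics of a super-node pair
#'
#' Counts the original edges between the members of two super nodes
#' (`e_count`, the E_AB of the encoding) and the number of possible member
#' pairs (`f_possible`, F_AB), and applies the half rule: the pair is encoded
#' as a super edge iff `e_count > f_possible / 2`, otherwise its edges go to
#' the positive correction set.
#'
#' @param g An `ipgs_graph`.
#' @param part An `ipgs_partition`.
#' @param a,b Super-node ids (`a == b` gives the self pair).
#' @return A list with `e_count`, `f_possible` and
#'   `mode` (`"SUPEREDGE"` or `"CORRECTIONS_ONLY"`).
#' @export
pair_stats <- function(g, part, a, b) {
  check_super(part, a); check_super(part, b)
  adj <- adjacency(g)
  A <- part$members[[a]]
  cnt <- super_tallies(A, adj, part$node2super)
  if (a == b) {
    e <- cnt[a] / 2
    f <- part$sizes[a] * (part$sizes[a] - 1) / 2
  } else {
    e <- cnt[b]
    f <- part$sizes[a] * part$sizes[b]
  }
  list(e_count = as.integer(e), f_possible = as.integer(f),
       mode = if (2 * e > f) "SUPEREDGE" else "CORRECTIONS_ONLY")
}

check_super <- function(part, a) {
  if (length(a) != 1L || is.na(a) || a < 1L || a > length(part$sizes) ||
      part$sizes[a] == 0L) {
    stop("unknown super-node id: ", a)
  }
  invisible(TRUE)
}

# actual member edges between super a and b (canonical rows, sorted)
member_edges <- function(g, part, a, b, adj = adjacency(g)) {
  A <- part$members[[a]]
  rows <- lapply(A, function(u) {
    v <- adj$nbr[[u]]
    v <- v[part$node2super[v] == b]
    if (a == b) v <- v[v > u]
    if (length(v)) cbind(pmin(u, v), pmax(u, v)) else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- matrix(integer(0), ncol = 2L)
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

# all possible member pairs of the super pair (canonical rows)
possible_pairs <- function(part, a, b) {
  A <- part$members[[a]]
  if (a == b) {
    if (length(A) < 2L) return(matrix(integer(0), ncol = 2L))
    t(utils::combn(sort(A), 2L))
  } else {
    B <- part$members[[b]]
    gr <- expand.grid(u = A, v = B)
    cbind(pmin(gr$u, gr$v), pmax(gr$u, gr$v))
  }
}

#' Encode one super-node pair under the half rule
#'
#' With `e_count <= f_possible / 2` the pair contributes no super edge and its
#' member edges join C+; otherwise it contributes one super edge and the
#' absent member pairs join C-. The encoding cost is `e_count` in the first
#' case and `1 + (f_possible - e_count)` in the second.
#'
#' @inheritParams pair_stats
#' @return A list with `superedge` (`NULL` or `c(a, b)`), `c_plus_add` and
#'   `c_minus_add` (canonical edge matrices), and `cost`.
#' @export
encode_pair <- function(g, part, a, b) {
  ps <- pair_stats(g, part, a, b)
  if (ps$mode == "CORRECTIONS_ONLY") {
    cp <- member_edges(g, part, a, b)
    list(superedge = NULL, c_plus_add = cp,
         c_minus_add = matrix(integer(0), ncol = 2L), cost = ps$e_count)
  } else {
    present <- member_edges(g, part, a, b)
    poss <- possible_pairs(part, a, b)
    pk <- edge_keys(present, g$n_nodes)
    ak <- edge_keys(poss, g$n_nodes)
    cm <- poss[!(ak %in% pk), , drop = FALSE]
    cm <- cm[order(cm[, 1L], cm[, 2L]), , drop = FALSE]
    list(superedge = c(min(a, b), max(a, b)),
         c_plus_add = matrix(integer(0), ncol = 2L),
         c_minus_add = cm,
         cost = 1L + ps$f_possible - ps$e_count)
  }
}

#' Representation cost contributed by one super node
#'
#' Sum over every super-node pair incident to `a` (self pair included) of the
#' pair's encoding cost under the half rule; pairs without original edges
#' contribute 0. This is the `Cost(a, S)` entering the merge-saving formula,
#' with full attribution of each shared pair cost to both endpoints.
#'
#' @inheritParams pair_stats
#' @param a Super-node id.
#' @param importance Optional per-edge importance vector (aligned with
#'   `g$edges`); when given, each pair's cost is multiplied by the mean
#'   importance of its member edges (personalized mode).
#' @return Numeric cost.
#' @export
node_cost <- function(g, part, a, importance = NULL) {
  check_super(part, a)
  adj <- adjacency(g)
  A <- part$members[[a]]
  cnt <- super_tallies(A, adj, part$node2super)
  isum <- if (is.null(importance)) NULL else
    importance_sums(A, adj, part$node2super, importance)
  cost_from_tallies(cnt, a, part$sizes[a], part$sizes, isum)[2L]
}

#' Saving of merging two super nodes
#'
#' `saving = 1 - Cost(a U b) / (Cost(a) + Cost(b))`, where `Cost(a U b)` is
#' the cost of the hypothetical merged super node with the rest of the
#' partition unchanged. Positive saving means the merge shrinks the
#' representation attributable to the pair.
#'
#' @inheritParams node_cost
#' @param a,b Distinct super-node ids.
#' @return Numeric saving (`<= 1`).
#' @export
merge_saving <- function(g, part, a, b, importance = NULL) {
  if (a == b) stop("invalid merge: a super node cannot merge with itself")
  check_super(part, a); check_super(part, b)
  adj <- adjacency(g)
  ca <- node_cost(g, part, a, importance)
  cb <- node_cost(g, part, b, importance)
  if (ca + cb == 0) stop("undefined saving: both super nodes are isolated")
  U <- c(part$members[[a]], part$members[[b]])
  cnt <- super_tallies(U, adj, part$node2super, from = max(a, b), to = min(a, b))
  isum <- if (is.null(importance)) NULL else
    importance_sums(U, adj, part$node2super, importance,
                    from = max(a, b), to = min(a, b))
  cu <- cost_from_tallies(cnt, min(a, b), length(U), part$sizes, isum)[2L]
  1 - cu / (ca + cb)
}

#' Merge two super nodes
#'
#' The surviving super id is `min(a, b)`; the partition invariant (disjoint
#' cover of all nodes) is preserved.
#'
#' @param part An `ipgs_partition`.
#' @param a,b Distinct live super-node ids.
#' @return The updated partition.
#' @export
apply_merge <- function(part, a, b) {
  if (a == b) stop("invalid merge: a super node cannot merge with itself")
  check_super(part, a); check_super(part, b)
  keep <- min(a, b); drop <- max(a, b)
  part$node2super[part$members[[drop]]] <- keep
  part$members[[keep]] <- c(part$members[[keep]], part$members[[drop]])
  part$members[drop] <- list(NULL)
  part$sizes[keep] <- part$sizes[keep] + part$sizes[drop]
  part$sizes[drop] <- 0L
  part
}

#' Virtual summary size of a partition
#'
#' `|E/| + |C+| + |C-|` under the half-rule encoding of the current
#' partition, computed without materializing the correction sets.
#'
#' @inheritParams pair_stats
#' @return Numeric total size.
#' @export
summary_total_size <- function(g, part) {
  adj <- adjacency(g)
  tot <- 0
  for (a in active_supers(part)) {
    cnt <- super_tallies(part$members[[a]], adj, part$node2super)
    ids <- which(cnt > 0L)
    for (b in ids[ids >= a]) {
      if (b == a) {
        e <- cnt[a] / 2
        f <- part$sizes[a] * (part$sizes[a] - 1) / 2
      } else {
        e <- cnt[b]
        f <- part$sizes[a] * part$sizes[b]
      }
      tot <- tot + if (2 * e <= f) e else 1 + f - e
    }
  }
  tot
}

#' Materialize the summary graph and correction sets
#'
#' Encodes every super-node pair with original edges under the half rule,
#' producing the super edges and the C+/C- correction lists that make the
#' summary lossless. Output ordering is deterministic (sorted).
#'
#' @inheritParams pair_stats
#' @return A list with `summary` (class `ipgs_summary`: `supers`, `members`,
#'   `superedges`, `labels`, `n_nodes`) and `corrections` (class
#'   `ipgs_corrections`: canonical edge matrices `c_plus`, `c_minus`).
#' @export
encode_all <- function(g, part) {
  if (length(part$node2super) != g$n_nodes) {
    stop("partition does not cover the graph's nodes")
  }
  adj <- adjacency(g)
  act <- active_supers(part)
  se <- list(); cp <- list(); cm <- list()
  for (a in act) {
    cnt <- super_tallies(part$members[[a]], adj, part$node2super)
    ids <- which(cnt > 0L)
    for (b in ids[ids >= a]) {
      if (b == a) {
        e <- cnt[a] / 2
        f <- part$sizes[a] * (part$sizes[a] - 1) / 2
      } else {
        e <- cnt[b]
        f <- part$sizes[a] * part$sizes[b]
      }
      if (2 * e <= f) {
        cp[[length(cp) + 1L]] <- member_edges(g, part, a, b, adj)
      } else {
        se[[length(se) + 1L]] <- c(a, b)
        present <- member_edges(g, part, a, b, adj)
        poss <- possible_pairs(part, a, b)
        miss <- poss[!(edge_keys(poss, g$n_nodes) %in%
                         edge_keys(present, g$n_nodes)), , drop = FALSE]
        cm[[length(cm) + 1L]] <- miss
      }
    }
  }
  bindm <- function(lst) {
    out <- do.call(rbind, lst)
    if (is.null(out) || nrow(out) == 0L) return(matrix(integer(0), ncol = 2L))
    out <- matrix(as.integer(out), ncol = 2L)
    out[order(out[, 1L], out[, 2L]), , drop = FALSE]
  }
  summary <- structure(
    list(supers = act,
         members = lapply(part$members[act], sort),
         superedges = bindm(se),
         labels = g$labels,
         n_nodes = g$n_nodes),
    class = "ipgs_summary"
  )
  corrections <- structure(
    list(c_plus = bindm(cp), c_minus = bindm(cm)),
    class = "ipgs_corrections"
  )
  list(summary = summary, corrections = corrections)
}

#' @export
print.ipgs_summary <- function(x, ...) {
  cat(sprintf("<ipgs_summary> %d super nodes over %d nodes, %d super edges\n",
              length(x$supers), x$n_nodes, nrow(x$superedges)))
  invisible(x)
}

#' Reconstruct the original graph from a summary
#'
#' Expands every super edge to all member pairs (all internal pairs for a
#' self super edge), removes the C- edges and adds the C+ edges. Exact
#' inverse of [encode_all()] for the graph's topology (edge weights are not
#' part of the summary representation).
#'
#' @param summary An `ipgs_summary`.
#' @param corrections An `ipgs_corrections`.
#' @param n_nodes Node count of the original graph.
#' @return The reconstructed (unweighted) `ipgs_graph`.
#' @export
decode_summary <- function(summary, corrections, n_nodes = summary$n_nodes) {
  n <- n_nodes
  keys <- numeric(0)
  if (nrow(summary$superedges) > 0L) {
    mem <- summary$members
    idx <- match(seq_len(max(summary$supers)), summary$supers)
    expand <- lapply(seq_len(nrow(summary$superedges)), function(i) {
      a <- summary$superedges[i, 1L]; b <- summary$superedges[i, 2L]
      A <- mem[[idx[a]]]
      if (a == b) {
        if (length(A) < 2L) stop("corrupt summary: self super edge on a singleton")
        t(utils::combn(A, 2L))
      } else {
        B <- mem[[idx[b]]]
        gr <- expand.grid(u = A, v = B)
        cbind(pmin(gr$u, gr$v), pmax(gr$u, gr$v))
      }
    })
    keys <- unique(edge_keys(do.call(rbind, expand), n))
  }
  if (nrow(corrections$c_minus) > 0L) {
    mk <- edge_keys(corrections$c_minus, n)
    if (!all(mk %in% keys)) {
      stop("corrupt summary: C- edge not implied by any super edge")
    }
    keys <- setdiff(keys, mk)
  }
  if (nrow(corrections$c_plus) > 0L) {
    pk <- edge_keys(corrections$c_plus, n)
    if (any(pk %in% keys)) {
      stop("corrupt summary: C+ edge already implied by a super edge")
    }
    keys <- c(keys, pk)
  }
  ipgs_graph(n, keys_to_edges(keys, n), labels = summary$labels)
}

#' Write a summary and its correction sets as TSV files
#'
#' Produces `<prefix>.supernodes.tsv` (`super_id`, `member_label`),
#' `<prefix>.superedges.tsv` (`super_a`, `super_b`), and
#' `<prefix>.cplus.tsv` / `<prefix>.cminus.tsv` (`label_u`, `label_v`),
#' all deterministically sorted.
#'
#' @param result A list with `summary` and `corrections` (e.g. from
#'   [encode_all()] or [summarize_graph()]).
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_summary <- function(result, prefix) {
  sg <- result$summary; co <- result$corrections
  labels <- sg$labels
  sn <- data.frame(
    super_id = rep(sg$supers, lengths(sg$members)),
    member_label = labels[unlist(sg$members, use.names = FALSE)]
  )
  sn <- sn[order(sn$super_id, sn$member_label), ]
  utils::write.table(sn, paste0(prefix, ".supernodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  se <- data.frame(super_a = sg$superedges[, 1L], super_b = sg$superedges[, 2L])
  utils::write.table(se, paste0(prefix, ".superedges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  wr_corr <- function(mat, path) {
    lu <- labels[mat[, 1L]]; lv <- labels[mat[, 2L]]
    flip <- lu > lv
    tmp <- lu[flip]; lu[flip] <- lv[flip]; lv[flip] <- tmp
    d <- data.frame(label_u = lu, label_v = lv)
    d <- d[order(d$label_u, d$label_v), , drop = FALSE]
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr_corr(co$c_plus, paste0(prefix, ".cplus.tsv"))
  wr_corr(co$c_minus, paste0(prefix, ".cminus.tsv"))
  invisible(prefix)
}

#' Read a summary written by [write_summary()]
#'
#' @param prefix Path prefix used when writing.
#' @return A list with `summary` and `corrections`, decodable with
#'   [decode_summary()].
#' @export
read_summary <- function(prefix) {
  rd <- function(suffix) {
    utils::read.table(paste0(prefix, suffix), sep = "\t", header = TRUE,
                      colClasses = "character")
  }
  sn <- rd(".supernodes.tsv")
  labels <- sn$member_label
  if (anyDuplicated(labels)) stop("corrupt summary: duplicated member label")
  n <- length(labels)
  ids <- seq_len(n)
  sup_of <- as.integer(sn$super_id)
  supers <- sort(unique(sup_of))
  members <- lapply(supers, function(s) sort(ids[sup_of == s]))
  se <- rd(".superedges.tsv")
  superedges <- cbind(as.integer(se$super_a), as.integer(se$super_b))
  if (nrow(superedges) == 0L) superedges <- matrix(integer(0), ncol = 2L)
  corr <- function(suffix) {
    d <- rd(suffix)
    if (nrow(d) == 0L) return(matrix(integer(0), ncol = 2L))
    u <- match(d$label_u, labels); v <- match(d$label_v, labels)
    if (anyNA(u) || anyNA(v)) stop("corrupt summary: unknown correction label")
    cbind(pmin(u, v), pmax(u, v))
  }
  summary <- structure(
    list(supers = supers, members = members, superedges = superedges,
         labels = labels, n_nodes = n),
    class = "ipgs_summary"
  )
  corrections <- structure(
    list(c_plus = corr(".cplus.tsv"), c_minus = corr(".cminus.tsv")),
    class = "ipgs_corrections"
  )
  list(summary = summary, corrections = corrections)
}
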