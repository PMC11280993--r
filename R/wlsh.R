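#' DOPH configuration
#'
#' @param k Signature length (number of bins), `>= 1`.
#' @param seed Integer seed driving the shared permutation.
#' @param weight_cap Maximum unary expansion per vector entry, `>= 1`.
#'   Caps the cost of representing large integer weights; entries with weight
#'   above the cap are treated as weight `weight_cap`.
#' @return A list of class `doph_config`.
#' @export
doph_config <- function(k = 5L, seed = 42L, weight_cap = 16L) {
  stopifnot(k >= 1L, weight_cap >= 1L)
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 weight_cap = as.integer(weight_cap)),
            class = "doph_config")
}

#' Integer-weighted neighborhood vector of a super node
#'
#' Entry for node `v` is the total weight of original edges from the members
#' of super node `a` to `v` (for an unweighted graph: the number of such
#' edges). With `scale` given (personalized mode), each entry is multiplied
#' by the corresponding edge-importance factor and rounded up, so entries
#' stay integers `>= 1`.
#'
#' @param g An `ipgs_graph`.
#' @param part An `ipgs_partition`.
#' @param a Super-node id.
#' @param scale Optional numeric vector of per-edge importance factors
#'   (aligned with `g$edges`), as produced by [edge_importance()].
#' @return A list with `owner`, `ids` (neighbor node ids, sorted), `w`
#'   (positive integer weights) and `dimension` (`= g$n_nodes`).
#' @export
neighbor_vector <- function(g, part, a, scale = NULL) {
  check_super(part, a)
  adj <- adjacency(g)
  A <- part$members[[a]]
  nb <- unlist(adj$nbr[A], use.names = FALSE)
  wt <- as.numeric(unlist(adj$w[A], use.names = FALSE))
  if (!is.null(scale)) {
    eid <- unlist(adj$eid[A], use.names = FALSE)
    wt <- wt * scale[eid]
  }
  if (length(nb) == 0L) {
    return(list(owner = a, ids = integer(0), w = integer(0),
                dimension = g$n_nodes))
  }
  s <- rowsum(wt, nb)
  ids <- as.integer(rownames(s))
  w <- as.integer(ceiling(s[, 1L]))
  w[w < 1L] <- 1L
  list(owner = a, ids = ids, w = w, dimension = g$n_nodes)
}

#' Weighted Jaccard similarity
#'
#' `Jw(x, y) = sum_v min(x_v, y_v) / sum_v max(x_v, y_v)` over the union of
#' supports. Reduces to the ordinary Jaccard index on binary vectors.
#'
#' @param x,y Weighted neighborhood vectors (see [neighbor_vector()]) of the
#'   same dimension.
#' @return Similarity in `[0, 1]`.
#' @export
weighted_jaccard <- function(x, y) {
  if (x$dimension != y$dimension) stop("vectors have different dimensions")
  if (length(x$ids) == 0L && length(y$ids) == 0L) {
    stop("undefined similarity: both vectors are all-zero")
  }
  ids <- union(x$ids, y$ids)
  xv <- numeric(length(ids)); yv <- numeric(length(ids))
  xv[match(x$ids, ids)] <- x$w
  yv[match(y$ids, ids)] <- y$w
  sum(pmin(xv, yv)) / sum(pmax(xv, yv))
}

#' Unary expansion of a weighted vector into binary slots
#'
#' Entry `(v, w)` occupies the `min(w, cap)` slots
#' `(v - 1) * cap + 1, ..., (v - 1) * cap + min(w, cap)` of a binary vector of
#' length `dimension * cap`. All-weight-1 vectors occupy one slot per
#' neighbor regardless of `cap`.
#'
#' @param x A weighted neighborhood vector.
#' @param cap Maximum slots per entry (`>= 1`).
#' @return A list with `slots` (sorted integer indices of set slots) and
#'   `m` (total slot-space size).
#' @export
binarize_expand <- function(x, cap) {
  stopifnot(cap >= 1L)
  cap <- as.integer(cap)
  w <- pmin(x$w, cap)
  slots <- unlist(mapply(function(v, wi) (v - 1L) * cap + seq_len(wi),
                         x$ids, w, SIMPLIFY = FALSE), use.names = FALSE)
  list(slots = sort(as.integer(slots)), m = x$dimension * cap)
}

#' Shared slot permutation for a DOPH round
#'
#' One uniformly random permutation of the slot space, reproducible from the
#' seed and shared by every vector hashed in the same round (this sharing is
#' what makes per-bin collisions estimate the weighted Jaccard similarity).
#'
#' @param m Slot-space size.
#' @param seed Integer seed.
#' @return Integer permutation vector of length `m`.
#' @export
doph_permutation <- function(m, seed) {
  with_seed(seed, sample.int(m))
}

#' Densified one-permutation hash signature
#'
#' The set slots are mapped through the shared permutation, the permuted
#' index space is divided into `k` equal bins, and each bin records the
#' smallest permuted index it contains. Empty bins borrow the value of the
#' nearest non-empty bin to the right (with wraparound) — the densification
#' step. Deterministic given (vector, k, seed).
#'
#' @param bin A binarized vector from [binarize_expand()].
#' @param cfg A [doph_config()].
#' @param perm Optional precomputed permutation from [doph_permutation()]
#'   (must have length `bin$m`); computed from `cfg$seed` when missing.
#' @return Integer vector of `k` bin values.
#' @export
doph_signature <- function(bin, cfg, perm = NULL) {
  if (length(bin$slots) == 0L) stop("empty vector: no set slots to hash")
  if (is.null(perm)) perm <- doph_permutation(bin$m, cfg$seed)
  stopifnot(length(perm) == bin$m)
  k <- cfg$k
  pos <- perm[bin$slots]
  binw <- ceiling(bin$m / k)
  idx <- (pos - 1L) %/% binw + 1L
  sig <- rep(NA_integer_, k)
  mins <- tapply(pos, idx, min)
  sig[as.integer(names(mins))] <- as.integer(mins)
  if (anyNA(sig)) {
    # borrow from the nearest non-empty bin to the right, wrapping around
    filled <- which(!is.na(sig))
    for (i in which(is.na(sig))) {
      d <- (filled - i) %% k
      sig[i] <- sig[filled[which.min(d)]]
    }
  }
  sig
}

#' Divide super nodes into candidate merge groups
#'
#' Groups are the equivalence classes of the full k-bin DOPH signature, so
#' two super nodes land in the same group with probability roughly
#' `Jw^k`. Groups larger than `max_group_size` are recursively split by
#' re-hashing their members with one more bin and a derived seed, until small
#' enough or the signatures are irreducibly identical.
#'
#' @param vectors List of weighted neighborhood vectors (one per active super
#'   node).
#' @param cfg A [doph_config()].
#' @param max_group_size Maximum group size before recursive splitting.
#' @return A list of class `ipgs_groups`: `groups` is a list of integer
#'   vectors of super-node ids partitioning the owners of `vectors`
#'   (all-zero vectors form their own singleton groups).
#' @export
divide_groups <- function(vectors, cfg, max_group_size = 500L) {
  owners <- vapply(vectors, function(v) v$owner, 1L)
  nonzero <- lengths(lapply(vectors, `[[`, "ids")) > 0L
  groups <- list()
  for (o in owners[!nonzero]) groups[[length(groups) + 1L]] <- o
  if (any(nonzero)) {
    vs <- vectors[nonzero]
    bins <- lapply(vs, binarize_expand, cap = cfg$weight_cap)
    groups <- c(groups,
                split_recursive(owners[nonzero], bins, cfg$k, cfg$seed,
                                max_group_size, depth = 0L))
  }
  structure(list(groups = groups), class = "ipgs_groups")
}

split_recursive <- function(owners, bins, k, seed, max_group_size, depth) {
  m <- bins[[1L]]$m
  perm <- doph_permutation(m, derive_seed(seed, depth))
  cfg <- doph_config(k = k, seed = seed)
  sigs <- vapply(bins, function(b)
    paste(doph_signature(b, cfg, perm), collapse = ","), "")
  out <- list()
  for (cls in split(seq_along(owners), sigs)) {
    if (length(cls) <= max_group_size || depth >= 32L) {
      out[[length(out) + 1L]] <- owners[cls]
    } else {
      sub <- split_recursive(owners[cls], bins[cls], k + 1L,
                             derive_seed(seed, depth + 101L),
                             max_group_size, depth + 1L)
      out <- c(out, sub)
    }
  }
  out
}
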