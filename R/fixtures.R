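#' Planted-partition random graph
#'
#' Nodes are split into `k` blocks (the last block absorbs any remainder);
#' each intra-block pair is an edge with probability `p_in`, each inter-block
#' pair with probability `p_out`. With `p_in > p_out` the blocks are
#' communities with overlapping neighborhoods — the compressible structure
#' graph summarization exploits.
#'
#' @param n Number of nodes.
#' @param k Number of blocks.
#' @param p_in,p_out Edge probabilities within / between blocks.
#' @param seed Integer seed (same seed, same graph).
#' @return An `ipgs_graph`.
#' @export
planted_partition <- function(n, k, p_in, p_out, seed) {
  stopifnot(n >= 1, k >= 1, p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1)
  block <- pmin(((seq_len(n) - 1L) %/% max(1L, n %/% k)) + 1L, k)
  pr <- utils::combn(n, 2L)
  p <- ifelse(block[pr[1L, ]] == block[pr[2L, ]], p_in, p_out)
  keep <- with_seed(seed, stats::runif(ncol(pr)) < p)
  ipgs_graph(n, t(pr[, keep, drop = FALSE]))
}

#' Erdos-Renyi random graph
#'
#' Every node pair is an edge independently with probability `p`.
#'
#' @param n Number of nodes.
#' @param p Edge probability.
#' @param seed Integer seed.
#' @return An `ipgs_graph`.
#' @export
erdos_renyi <- function(n, p, seed) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  if (n < 2L) return(ipgs_graph(n, NULL))
  pr <- utils::combn(n, 2L)
  keep <- with_seed(seed, stats::runif(ncol(pr)) < p)
  ipgs_graph(n, t(pr[, keep, drop = FALSE]))
}

#' Twin-pairs graph
#'
#' `n_pairs` disjoint pairs of twin nodes, the two nodes of each pair sharing
#' an identical private neighbor set of size `shared_degree`. Twins have
#' weighted Jaccard similarity 1, so they always share a DOPH signature and
#' provide guaranteed-positive-saving merges (saving 1/2 for singleton
#' twins). Node ids are shuffled under the seed.
#'
#' @param n_pairs Number of twin pairs.
#' @param shared_degree Size of each pair's shared neighbor set.
#' @param seed Integer seed (shuffles the node labelling).
#' @return An `ipgs_graph`; labels `t<i>a` / `t<i>b` for the twins of pair
#'   `i` and `n<i>_<j>` for their neighbors.
#' @export
twins_graph <- function(n_pairs, shared_degree, seed = 1L) {
  stopifnot(n_pairs >= 1, shared_degree >= 1)
  n <- n_pairs * (2L + shared_degree)
  perm <- with_seed(seed, sample.int(n))
  labels <- character(n)
  edges <- NULL
  nxt <- 1L
  for (i in seq_len(n_pairs)) {
    a <- perm[nxt]; b <- perm[nxt + 1L]
    nbrs <- perm[nxt + 1L + seq_len(shared_degree)]
    labels[a] <- sprintf("t%da", i)
    labels[b] <- sprintf("t%db", i)
    labels[nbrs] <- sprintf("n%d_%d", i, seq_len(shared_degree))
    edges <- rbind(edges, cbind(a, nbrs), cbind(b, nbrs))
    nxt <- nxt + 2L + shared_degree
  }
  ipgs_graph(n, edges, labels = labels)
}

#' Worked-example weighted graph for the personalized mode
#'
#' A 5-node weighted graph with edges A-E (weight 5), A-G (weight 4),
#' G-B (weight 5) and B-F (weight 3); the target set is `{A}`. With target A,
#' the cumulative flow rates are 5 to E, 4 to G, 9 to B (through G) and 12
#' to F (through G and B).
#'
#' @return A list with `graph` (an `ipgs_graph`) and `targets` (`"A"`).
#' @export
fig10_example <- function() {
  labels <- c("A", "E", "G", "B", "F")
  edges <- rbind(c(1L, 2L),  # A-E
                 c(1L, 3L),  # A-G
                 c(3L, 4L),  # G-B
                 c(4L, 5L))  # B-F
  g <- ipgs_graph(5L, edges, weights = c(5L, 4L, 5L, 3L), labels = labels)
  list(graph = g, targets = "A")
}
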