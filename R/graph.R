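#' Construct an undirected simple graph
#'
#' The basic container used throughout the package: a simple undirected graph
#' on nodes `1..n_nodes`, with edges stored canonically (smaller id first,
#' sorted by pair) and optional positive integer edge weights.
#'
#' @param n_nodes Number of nodes; node ids are the integers `1..n_nodes`.
#' @param edges Two-column integer matrix of edges (one row per edge, any
#'   orientation); may have zero rows.
#' @param weights Optional integer vector of positive edge weights, aligned
#'   with the rows of `edges`. `NULL` means all weights are 1.
#' @param labels Optional character vector of external node labels
#'   (`labels[i]` is the label of node `i`). Defaults to `as.character(1:n)`.
#' @return An object of class `ipgs_graph` with fields `n_nodes`, `edges`
#'   (canonical m x 2 matrix), `weights` (or `NULL`) and `labels`.
#' @examples
#' g <- ipgs_graph(3, rbind(c(1, 2), c(3, 2)))
#' g$edges
#' @export
ipgs_graph <- function(n_nodes, edges, weights = NULL, labels = NULL) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(length(n_nodes) == 1L, n_nodes >= 0L)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > n_nodes)) {
      stop("edge endpoint outside [1, n_nodes]")
    }
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    # canonical orientation: smaller id first
    flip <- edges[, 1L] > edges[, 2L]
    edges[flip, ] <- edges[flip, 2:1]
    if (!is.null(weights)) {
      weights <- as.integer(weights)
      stopifnot(length(weights) == nrow(edges))
      if (any(weights < 1L)) stop("edge weights must be integers >= 1")
    }
    ord <- order(edges[, 1L], edges[, 2L])
    edges <- edges[ord, , drop = FALSE]
    if (!is.null(weights)) weights <- weights[ord]
    if (anyDuplicated(edge_keys(edges, n_nodes))) stop("duplicate edges")
  } else {
    weights <- if (is.null(weights)) NULL else integer(0)
  }
  if (is.null(labels)) labels <- as.character(seq_len(n_nodes))
  stopifnot(length(labels) == n_nodes, !anyDuplicated(labels))
  structure(
    list(n_nodes = n_nodes, edges = edges, weights = weights,
         labels = as.character(labels)),
    class = "ipgs_graph"
  )
}

#' @export
print.ipgs_graph <- function(x, ...) {
  w <- if (is.null(x$weights)) "unweighted" else "weighted"
  cat(sprintf("<ipgs_graph> %d nodes, %d edges (%s)\n",
              x$n_nodes, nrow(x$edges), w))
  invisible(x)
}

#' Number of edges of a graph
#' @param g An `ipgs_graph`.
#' @return Integer edge count.
#' @export
n_edges <- function(g) nrow(g$edges)

# numeric key of a canonical edge (u < v); safe for n < 2^26
edge_keys <- function(edges, n) {
  if (nrow(edges) == 0L) return(numeric(0))
  (edges[, 1L] - 1) * n + edges[, 2L]
}

keys_to_edges <- function(keys, n) {
  u <- floor((keys - 1) / n) + 1
  v <- keys - (u - 1) * n
  cbind(as.integer(u), as.integer(v))
}

#' Edge weight lookup vector
#'
#' @param g An `ipgs_graph`.
#' @return Integer vector of weights aligned with `g$edges` (all 1 when the
#'   graph is unweighted).
#' @export
edge_weights <- function(g) {
  if (is.null(g$weights)) rep(1L, nrow(g$edges)) else g$weights
}

#' Adjacency list of a graph
#'
#' @param g An `ipgs_graph`.
#' @return A list with components `nbr` (list of neighbor id vectors),
#'   `w` (parallel weights) and `eid` (parallel edge row indices in
#'   `g$edges`).
#' @export
adjacency <- function(g) {
  n <- g$n_nodes
  m <- nrow(g$edges)
  ends <- c(g$edges[, 1L], g$edges[, 2L])
  other <- c(g$edges[, 2L], g$edges[, 1L])
  w <- rep(edge_weights(g), 2L)
  eid <- rep(seq_len(m), 2L)
  ord <- order(ends, other)
  ends <- ends[ord]; other <- other[ord]; w <- w[ord]; eid <- eid[ord]
  idx <- split(seq_along(ends), factor(ends, levels = seq_len(n)))
  list(
    nbr = lapply(idx, function(i) other[i]),
    w = lapply(idx, function(i) w[i]),
    eid = lapply(idx, function(i) eid[i])
  )
}

#' Test two graphs for exact equality
#'
#' Equality of node count, canonical edge set and (effective) weights;
#' labels are ignored.
#' @param a,b `ipgs_graph` objects.
#' @return `TRUE` or `FALSE`.
#' @export
graph_identical <- function(a, b) {
  a$n_nodes == b$n_nodes &&
    nrow(a$edges) == nrow(b$edges) &&
    all(a$edges == b$edges) &&
    all(edge_weights(a) == edge_weights(b))
}

#' Labelled edge table of a graph
#'
#' @param g An `ipgs_graph`.
#' @return A data.frame with character columns `u`, `v` (labels, each row
#'   sorted so `u <= v`) and integer `w`, ordered lexicographically. Useful
#'   for label-level comparisons that are independent of internal ids.
#' @export
label_edges <- function(g) {
  lu <- g$labels[g$edges[, 1L]]
  lv <- g$labels[g$edges[, 2L]]
  flip <- lu > lv
  tmp <- lu[flip]; lu[flip] <- lv[flip]; lv[flip] <- tmp
  d <- data.frame(u = lu, v = lv, w = edge_weights(g),
                  stringsAsFactors = FALSE)
  d[order(d$u, d$v), , drop = FALSE]
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a reproducible child seed < 2^31 from (seed, salt)
derive_seed <- function(seed, salt) {
  x <- (as.numeric(seed) %% 65011 + 1) * 31627 + (as.numeric(salt) %% 65011 + 1) * 7919
  as.integer(x %% 2147483629)
}
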