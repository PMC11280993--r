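# shared helpers: small constructors and independent comparisons

# weighted neighborhood vector literal
nv <- function(ids, w, dim = max(ids, 1L)) {
  list(owner = 1L, ids = as.integer(ids), w = as.integer(w),
       dimension = as.integer(dim))
}

# graph from an edge string "1-2 2-3" (ids), optional weights
g_from <- function(spec, n = NULL, w = NULL) {
  if (nchar(spec) == 0L) {
    return(ipgs_graph(if (is.null(n)) 0L else n, NULL))
  }
  pairs <- strsplit(strsplit(spec, " ")[[1L]], "-")
  ed <- do.call(rbind, lapply(pairs, as.integer))
  if (is.null(n)) n <- max(ed)
  ipgs_graph(n, ed, weights = w)
}

# label-level edge comparison (independent of internal id assignment)
expect_same_labelled_edges <- function(a, b) {
  expect_equal(label_edges(a), label_edges(b), ignore_attr = TRUE)
}

# partition literal from a list of member vectors (ids = min member)
partition_from <- function(members, n) {
  node2super <- integer(n)
  mem <- vector("list", n)
  sizes <- integer(n)
  for (m in members) {
    s <- min(m)
    node2super[m] <- s
    mem[[s]] <- as.integer(m)
    sizes[s] <- length(m)
  }
  structure(list(node2super = node2super, members = mem, sizes = sizes),
            class = "ipgs_partition")
}

# a mixed bag of small random graphs, deterministic in `seed`
random_test_graph <- function(seed, n = 50L) {
  switch((seed %% 4L) + 1L,
         erdos_renyi(n, 0.05, seed = seed),
         erdos_renyi(n, 0.2, seed = seed),
         planted_partition(n + 10L, 5L, 0.4, 0.02, seed = seed),
         twins_graph(max(2L, n %/% 8L), 3L, seed = seed))
}
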