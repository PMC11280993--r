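# weighted Jaccard, DOPH signatures, candidate grouping

test_that("weighted Jaccard matches direct evaluation and its invariants", {
  x <- nv(c(1, 2, 4), c(1, 2, 3), dim = 5)
  y <- nv(c(1, 2, 4), c(2, 1, 1), dim = 5)
  expect_equal(weighted_jaccard(x, y), 3 / 7)
  expect_equal(weighted_jaccard(y, x), 3 / 7)          # symmetry
  expect_equal(weighted_jaccard(x, x), 1)              # identity
  z <- nv(3, 2, dim = 5)
  expect_equal(weighted_jaccard(x, z), 0)              # disjoint supports
  # reduces to unweighted Jaccard on binary vectors
  a <- nv(c(1, 2, 3), c(1, 1, 1), dim = 6)
  b <- nv(c(2, 3, 4, 5), c(1, 1, 1, 1), dim = 6)
  expect_equal(weighted_jaccard(a, b), 2 / 5)
  expect_error(weighted_jaccard(nv(integer(0), integer(0), 3),
                                nv(integer(0), integer(0), 3)),
               "undefined similarity")
  expect_error(weighted_jaccard(x, nv(1, 1, dim = 9)), "dimension")
})

test_that("neighbor vectors accumulate member edge weights", {
  g <- g_from("1-3 1-4")
  p <- singleton_partition(g)
  v <- neighbor_vector(g, p, 1)
  expect_equal(v$ids, c(3L, 4L))
  expect_equal(v$w, c(1L, 1L))

  # A = {1,2} both adjacent to 3: weight accumulates to 2
  g <- g_from("1-3 2-3 2-4")
  p <- partition_from(list(c(1, 2), 3, 4), 4)
  v <- neighbor_vector(g, p, 1)
  expect_equal(v$ids, c(3L, 4L))
  expect_equal(v$w, c(2L, 1L))

  # weighted worked example: node A sees E with weight 5, G with weight 4
  fx <- fig10_example()
  p <- singleton_partition(fx$graph)
  v <- neighbor_vector(fx$graph, p, match("A", fx$graph$labels))
  lab <- fx$graph$labels[v$ids]
  expect_equal(stats::setNames(v$w, lab), c(E = 5L, G = 4L))
})

test_that("unary expansion places capped slots deterministically", {
  # {3:1}, cap 4 -> single slot at (3-1)*4 + 1
  b <- binarize_expand(nv(3, 1, dim = 4), cap = 4)
  expect_equal(b$slots, 9L)
  expect_equal(b$m, 16L)
  # {3:7}, cap 4 -> capped to 4 slots
  b <- binarize_expand(nv(3, 7, dim = 4), cap = 4)
  expect_equal(b$slots, 9:12)
  # all-weights-1 vector: one slot per neighbor regardless of cap
  b <- binarize_expand(nv(c(1, 2, 4), c(1, 1, 1), dim = 4), cap = 7)
  expect_length(b$slots, 3L)
})

test_that("DOPH signatures are deterministic, densified, and length K", {
  x <- nv(c(1, 3, 5), c(2, 1, 3), dim = 6)
  b <- binarize_expand(x, 8)
  cfg <- doph_config(k = 6, seed = 99)
  s1 <- doph_signature(b, cfg)
  s2 <- doph_signature(b, cfg)
  expect_identical(s1, s2)
  expect_length(s1, 6L)
  expect_false(anyNA(s1))
  # different seed, (almost surely) different signature
  expect_false(identical(s1, doph_signature(b, doph_config(k = 6, seed = 100))))
  # single set slot: full densification copies it into every bin
  b1 <- binarize_expand(nv(2, 1, dim = 6), 8)
  expect_length(unique(doph_signature(b1, cfg)), 1L)
  expect_error(doph_signature(list(slots = integer(0), m = 10), cfg), "empty")
})

test_that("per-bin collision rate is calibrated to the weighted Jaccard", {
  # constructed two-coordinate pairs with exact Jw 0.2 / 0.5 / 0.8
  cases <- list(
    list(x = nv(c(2, 5), c(1, 1), dim = 6), y = nv(c(2, 5), c(5, 5), dim = 6), jw = 0.2),
    list(x = nv(c(2, 5), c(1, 1), dim = 6), y = nv(c(2, 5), c(2, 2), dim = 6), jw = 0.5),
    list(x = nv(c(2, 5), c(4, 4), dim = 6), y = nv(c(2, 5), c(5, 5), dim = 6), jw = 0.8)
  )
  nrep <- 600  # lighter than the acceptance run, same construction
  for (cs in cases) {
    expect_equal(weighted_jaccard(cs$x, cs$y), cs$jw)
    bx <- binarize_expand(cs$x, 16)
    by <- binarize_expand(cs$y, 16)
    fr <- vapply(seq_len(nrep), function(s) {
      cfg <- doph_config(k = 5, seed = s)
      perm <- doph_permutation(bx$m, s)
      mean(doph_signature(bx, cfg, perm) == doph_signature(by, cfg, perm))
    }, 1)
    se <- stats::sd(fr) / sqrt(nrep)
    expect_lt(abs(mean(fr) - cs$jw), 3 * se)
  }
})

test_that("divide_groups partitions the supers and co-groups exact twins", {
  g <- twins_graph(5, 3, seed = 3)
  p <- singleton_partition(g)
  vectors <- lapply(active_supers(p), function(a) neighbor_vector(g, p, a))
  grp <- divide_groups(vectors, doph_config(k = 5, seed = 17))
  # partition of all active supers
  expect_setequal(unlist(grp$groups), active_supers(p))
  expect_equal(anyDuplicated(unlist(grp$groups)), 0L)
  # twins (Jw = 1) always share a signature, hence a group
  for (i in 1:5) {
    a <- match(sprintf("t%da", i), g$labels)
    b <- match(sprintf("t%db", i), g$labels)
    same <- any(vapply(grp$groups, function(gr) a %in% gr && b %in% gr, NA))
    expect_true(same)
  }
})

test_that("oversized groups are split recursively to the size cap", {
  g <- twins_graph(12, 2, seed = 8)
  p <- singleton_partition(g)
  vectors <- lapply(active_supers(p), function(a) neighbor_vector(g, p, a))
  grp <- divide_groups(vectors, doph_config(k = 1, seed = 2), max_group_size = 4)
  expect_setequal(unlist(grp$groups), active_supers(p))
  # only irreducible identical-signature groups may exceed the cap; twins
  # come in pairs here, so identical groups have at most a handful of nodes
  expect_true(all(lengths(grp$groups) <= 4L |
                    vapply(grp$groups, function(gr) {
                      vs <- vectors[match(gr, active_supers(p))]
                      all(vapply(vs[-1], function(v)
                        isTRUE(all.equal(weighted_jaccard(vs[[1]], v), 1)), NA))
                    }, NA)))
})

test_that("candidate grouping favors intra-community pairs on a planted partition", {
  g <- planted_partition(100, 5, 0.45, 0.02, seed = 9)
  block <- pmin(((seq_len(100) - 1L) %/% 20L) + 1L, 5L)
  p <- singleton_partition(g)
  vectors <- lapply(active_supers(p), function(a) neighbor_vector(g, p, a))
  intra <- 0; inter <- 0
  for (s in 1:8) {
    grp <- divide_groups(vectors, doph_config(k = 1, seed = s))
    for (gr in grp$groups) {
      if (length(gr) < 2L) next
      prs <- utils::combn(gr, 2L)
      same <- block[prs[1L, ]] == block[prs[2L, ]]
      intra <- intra + sum(same)
      inter <- inter + sum(!same)
    }
  }
  # fraction of co-grouped pairs that are intra-community, vs the base rate
  n_intra_pairs <- 5 * choose(20, 2)
  n_inter_pairs <- choose(100, 2) - n_intra_pairs
  expect_gt(intra / n_intra_pairs, inter / n_inter_pairs)
})
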