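# half-rule encoding, cost model, merging and exact reconstruction

test_that("pair_stats counts member edges and applies the half rule", {
  # singleton pair with an edge: e=1, f=1, super edge
  g <- g_from("1-2")
  p <- singleton_partition(g)
  ps <- pair_stats(g, p, 1, 2)
  expect_equal(ps[c("e_count", "f_possible", "mode")],
               list(e_count = 1L, f_possible = 1L, mode = "SUPEREDGE"))

  # boundary: e = f/2 exactly -> corrections, no super edge
  g <- g_from("1-3 2-4")
  p <- partition_from(list(c(1, 2), c(3, 4)), 4)
  ps <- pair_stats(g, p, 1, 3)
  expect_equal(ps$e_count, 2L)
  expect_equal(ps$f_possible, 4L)
  expect_equal(ps$mode, "CORRECTIONS_ONLY")

  # self pair: A={1,2,3} with edges 1-2, 1-3 -> e=2 > f/2=1.5
  g <- g_from("1-2 1-3")
  p <- partition_from(list(c(1, 2, 3)), 3)
  ps <- pair_stats(g, p, 1, 1)
  expect_equal(ps$e_count, 2L)
  expect_equal(ps$f_possible, 3L)
  expect_equal(ps$mode, "SUPEREDGE")

  expect_error(pair_stats(g, p, 1, 2), "unknown super")
})

test_that("encode_pair emits C+ below the boundary and a super edge plus C- above", {
  # e=2, f=4: both edges to C+
  g <- g_from("1-3 2-4")
  p <- partition_from(list(c(1, 2), c(3, 4)), 4)
  enc <- encode_pair(g, p, 1, 3)
  expect_null(enc$superedge)
  expect_equal(nrow(enc$c_plus_add), 2L)
  expect_equal(nrow(enc$c_minus_add), 0L)
  expect_equal(enc$cost, 2L)

  # e=3, f=4: super edge + 1 C-
  g <- g_from("1-3 1-4 2-4")
  p <- partition_from(list(c(1, 2), c(3, 4)), 4)
  enc <- encode_pair(g, p, 1, 3)
  expect_equal(enc$superedge, c(1, 3))
  expect_equal(enc$c_plus_add, matrix(integer(0), ncol = 2), ignore_attr = TRUE)
  expect_equal(enc$c_minus_add, cbind(2L, 3L), ignore_attr = TRUE)
  expect_equal(enc$cost, 2L)

  # e=0: zero cost, nothing emitted
  g <- ipgs_graph(5, rbind(c(1, 5), c(3, 5)))
  p <- partition_from(list(c(1, 2), c(3, 4), 5), 5)
  enc <- encode_pair(g, p, 1, 3)
  expect_null(enc$superedge)
  expect_equal(nrow(enc$c_plus_add) + nrow(enc$c_minus_add), 0L)
  expect_equal(enc$cost, 0L)
})

test_that("node_cost matches exhaustive enumeration on hand cases", {
  # singleton with 3 singleton neighbors: three e=1,f=1 super edges -> 3
  g <- g_from("1-2 1-3 1-4")
  p <- singleton_partition(g)
  expect_equal(node_cost(g, p, 1), 3)
  expect_equal(node_cost(g, p, 1), ref_node_cost(g, as.list(1:4), 1))

  # isolated node costs nothing
  g <- ipgs_graph(3, rbind(c(1, 2)))
  p <- singleton_partition(g)
  expect_equal(node_cost(g, p, 3), 0)

  # A={1,2} fully connected to {3}: one super edge -> 1
  g <- g_from("1-3 2-3")
  p <- partition_from(list(c(1, 2), 3), 3)
  expect_equal(node_cost(g, p, 1), 1)
  expect_equal(node_cost(g, p, 1),
               ref_node_cost(g, list(c(1L, 2L), integer(0), 3L), 1))
})

test_that("merge_saving reproduces the worked saving example and its error paths", {
  # twins 1,2 sharing neighbors {3,4,5}: Cost 3+3, merged 3 -> saving 1/2
  g <- g_from("1-3 1-4 1-5 2-3 2-4 2-5")
  p <- singleton_partition(g)
  expect_equal(node_cost(g, p, 1), 3)
  expect_equal(merge_saving(g, p, 1, 2), 0.5)

  # A={1,2} super-edge to {3}, merged with unrelated singleton 6: 1 - 3/2
  g <- ipgs_graph(7, rbind(c(1, 3), c(2, 3), c(6, 7)))
  p <- partition_from(list(c(1, 2), 3, 4, 5, 6, 7), 7)
  expect_equal(merge_saving(g, p, 1, 6), -0.5)

  expect_error(merge_saving(g, p, 1, 1), "invalid merge")
  # two isolated nodes: undefined saving
  expect_error(merge_saving(g, p, 4, 5), "undefined saving")
})

test_that("merge_saving agrees with the exhaustive-cost oracle on random graphs", {
  for (s in 1:8) {
    g <- erdos_renyi(10, 0.3, seed = 200 + s)
    p <- singleton_partition(g)
    # grow a random partial partition to exercise non-singleton supers
    p <- apply_merge(p, 1, 2)
    p <- apply_merge(p, 3, 4)
    act <- active_supers(p)
    mem <- lapply(seq_len(g$n_nodes), function(i)
      if (p$sizes[i] > 0L) p$members[[i]] else integer(0))
    for (i in seq_along(act)) {
      for (j in seq_along(act)) {
        if (i >= j) next
        a <- act[i]; b <- act[j]
        ref <- tryCatch(ref_merge_saving(g, mem, a, b), error = function(e) NA)
        if (is.na(ref)) {
          expect_error(merge_saving(g, p, a, b), "undefined")
        } else {
          expect_equal(merge_saving(g, p, a, b), ref)
        }
      }
    }
  }
})

test_that("apply_merge keeps the partition a disjoint cover under random merges", {
  g <- erdos_renyi(40, 0.1, seed = 11)
  p <- singleton_partition(g)
  set.seed(11)
  for (i in 1:50) {
    act <- active_supers(p)
    if (length(act) < 2L) break
    ab <- sample(act, 2)
    p <- apply_merge(p, ab[1], ab[2])
    # surviving id is the smaller of the two
    expect_gt(p$sizes[min(ab)], 0L)
    expect_equal(p$sizes[max(ab)], 0L)
  }
  # brute-force partition audit
  all_members <- sort(unlist(p$members[active_supers(p)]))
  expect_equal(all_members, 1:40)
  for (s in active_supers(p)) {
    expect_true(all(p$node2super[p$members[[s]]] == s))
  }
  expect_equal(sum(p$sizes), 40L)
})

test_that("virtual total size equals the pairwise enumeration oracle", {
  for (s in 1:5) {
    g <- erdos_renyi(12, 0.35, seed = 300 + s)
    p <- singleton_partition(g)
    p <- apply_merge(p, 1, 2); p <- apply_merge(p, 1, 3); p <- apply_merge(p, 5, 9)
    mem <- lapply(seq_len(g$n_nodes), function(i)
      if (p$sizes[i] > 0L) p$members[[i]] else integer(0))
    expect_equal(summary_total_size(g, p), ref_total_size(g, mem))
  }
})

test_that("encode_all on the identity partition reproduces the edges, with no corrections", {
  g <- erdos_renyi(15, 0.25, seed = 21)
  enc <- encode_all(g, singleton_partition(g))
  expect_equal(enc$summary$superedges, g$edges, ignore_attr = TRUE)
  expect_equal(nrow(enc$corrections$c_plus), 0L)
  expect_equal(nrow(enc$corrections$c_minus), 0L)
  expect_true(graph_identical(
    decode_summary(enc$summary, enc$corrections), g))

  # empty graph -> empty summary
  e0 <- encode_all(ipgs_graph(0L, NULL), singleton_partition(ipgs_graph(0L, NULL)))
  expect_equal(length(e0$summary$supers), 0L)
  expect_equal(nrow(e0$summary$superedges), 0L)
})

test_that("merged twins with shared neighbors compress below the raw edge count", {
  # two twin nodes over 3 shared neighbors, merged: one super edge replaces
  # six edges' worth of structure attributable to the pair
  g <- g_from("1-3 1-4 1-5 2-3 2-4 2-5")
  p <- partition_from(list(c(1, 2), 3, 4, 5), 5)
  enc <- encode_all(g, p)
  total <- nrow(enc$summary$superedges) + nrow(enc$corrections$c_plus) +
    nrow(enc$corrections$c_minus)
  expect_lt(total, n_edges(g))
  expect_equal(total, ref_total_size(g, list(c(1L, 2L), integer(0), 3L, 4L, 5L)))
  expect_true(graph_identical(decode_summary(enc$summary, enc$corrections),
                              g_from("1-3 1-4 1-5 2-3 2-4 2-5")))
})

test_that("decoding a corrupted summary fails loudly", {
  g <- g_from("1-3 2-3")
  p <- partition_from(list(c(1, 2), 3), 3)
  enc <- encode_all(g, p)
  # C- entry for an edge no super edge implies
  bad <- enc$corrections
  bad$c_minus <- rbind(bad$c_minus, c(1L, 2L))
  expect_error(decode_summary(enc$summary, bad), "corrupt")
  # C+ entry already implied by the super edge
  bad <- enc$corrections
  bad$c_plus <- rbind(bad$c_plus, c(1L, 3L))
  expect_error(decode_summary(enc$summary, bad), "corrupt")
})

test_that("half rule is auditable from every encoded output", {
  for (s in 1:6) {
    g <- random_test_graph(s, n = 24L)
    res <- summarize_graph(g, summarizer_config(iterations = 4,
                                                signature_length = 2, seed = s))
    sg <- res$summary
    sup_of <- integer(g$n_nodes)
    for (i in seq_along(sg$supers)) sup_of[sg$members[[i]]] <- sg$supers[i]
    se_keys <- paste(sg$superedges[, 1], sg$superedges[, 2])
    # recompute pair stats from the decoded (= original) graph
    part <- partition_from(sg$members, g$n_nodes)
    for (i in seq_along(sg$supers)) {
      a <- sg$supers[i]
      for (j in i:length(sg$supers)) {
        b <- sg$supers[j]
        ps <- pair_stats(g, part, a, b)
        if (ps$e_count == 0L) next
        expect_equal(paste(a, b) %in% se_keys, ps$mode == "SUPEREDGE")
      }
    }
  }
})

test_that("summary TSV serialization round trips through the decoder", {
  g <- twins_graph(3, 2, seed = 5)
  res <- summarize_graph(g, summarizer_config(iterations = 4, seed = 5))
  prefix <- file.path(withr::local_tempdir(), "run")
  write_summary(res, prefix)
  expect_true(all(file.exists(paste0(prefix, c(
    ".supernodes.tsv", ".superedges.tsv", ".cplus.tsv", ".cminus.tsv")))))
  back <- read_summary(prefix)
  dec <- decode_summary(back$summary, back$corrections)
  expect_same_labelled_edges(dec, g)
})
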