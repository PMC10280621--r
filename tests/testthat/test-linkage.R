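test_that("single linkage reproduces the worked dendrograms", {
  S <- acgt_set()
  d <- single_linkage(distance_matrix(S))
  expect_equal(d$height, c(1, 1, 1))
  expect_equal(length(d$height), 3L)

  P <- chain_outlier_set()
  dp <- single_linkage(distance_matrix(P))
  expect_equal(dp$height, c(1, 2, 4))
  # merge order: the two closest chain members, then the zero sequence,
  # then the distant all-ones outlier
  expect_setequal(c(dp$pa[[1]], dp$pb[[1]]), c("s1110000", "s1100000"))
  expect_true("s0000000" %in% c(dp$pa[[2]], dp$pb[[2]]))
  expect_true("s1111111" %in% c(dp$pa[[3]], dp$pb[[3]]))

  S2 <- seq_set(c(x = "AAAA", y = "ACCA"))
  d2 <- single_linkage(distance_matrix(S2))
  expect_equal(d2$height, 2)

  expect_error(single_linkage(distance_matrix(seq_set(c(a = "AC")))),
               "at least two")
})

test_that("heights normalize by sequence length", {
  S <- acgt_set()
  d <- normalize_heights(single_linkage(distance_matrix(S)), 4)
  expect_equal(d$height, c(0.25, 0.25, 0.25))

  dp <- normalize_heights(single_linkage(distance_matrix(chain_outlier_set())), 7)
  expect_equal(dp$height, c(1, 2, 4) / 7)

  d1 <- single_linkage(distance_matrix(S))
  expect_equal(normalize_heights(d1, 1)$height, d1$height)
  expect_error(normalize_heights(d1, 0), "positive")
})

test_that("single-linkage heights match the reference implementation", {
  set.seed(31)
  for (rep in 1:8) {
    m <- sample(4:8, 1L)
    sim <- simulate_tree_sequences(n_leaves = m, n_sites = 10, p_sub = 0.3)
    D <- distance_matrix(sim$sequences)
    mine <- single_linkage(D)
    ref <- stats::hclust(stats::as.dist(D), method = "single")
    expect_equal(mine$height, ref$height)
    expect_true(all(diff(mine$height) >= 0))
    # same flat clusterings at every k
    for (k in seq_len(m)) {
      expect_true(same_partition(
        cut_by_count(mine, k),
        stats::cutree(ref, k = k)))
    }
  }
})

test_that("the labeled linkage tree is a valid in-set-labeled cladogram", {
  P <- chain_outlier_set()
  ll <- labeled_single_linkage(P)
  expect_length(validate_cladogram(ll$tree, P), 0L)
  expect_true(all(ll$tree$labels %in% P$seqs))
  w <- parsimony_weight(ll$tree)
  expect_equal(w, 9)
  # no labeling of this shape can reach the MST weight 7
  expect_gte(w, fitch_min_weight(ll$tree, alphabet = P$alphabet))
  expect_equal(fitch_min_weight(ll$tree, alphabet = P$alphabet), 8L)

  S <- acgt_set()
  lls <- labeled_single_linkage(S)
  expect_length(validate_cladogram(lls$tree, S), 0L)
  ws <- parsimony_weight(lls$tree)
  expect_gte(ws, 3)  # MST weight lower-bounds nothing here, but Fitch does
  expect_equal(fitch_min_weight(lls$tree, alphabet = S$alphabet), 3L)

  S2 <- seq_set(c(x = "AAAA", y = "ACCA"))
  ll2 <- labeled_single_linkage(S2)
  expect_equal(parsimony_weight(ll2$tree), 2)
  expect_setequal(ll2$tree$leaves, c("x", "y"))
})

test_that("heuristic labeling is never better than the Fitch optimum", {
  set.seed(37)
  for (rep in 1:10) {
    m <- sample(3:7, 1L)
    sim <- simulate_tree_sequences(n_leaves = m, n_sites = 9, p_sub = 0.25)
    S <- sim$sequences
    ll <- labeled_single_linkage(S)
    expect_length(validate_cladogram(ll$tree, S), 0L)
    expect_true(all(ll$tree$labels %in% S$seqs))
    expect_gte(parsimony_weight(ll$tree),
               fitch_min_weight(ll$tree, alphabet = S$alphabet))
  }
})

test_that("dendrogram threshold cuts equal MST component cuts", {
  set.seed(41)
  for (rep in 1:8) {
    m <- sample(4:8, 1L)
    sim <- simulate_tree_sequences(n_leaves = m, n_sites = 10, p_sub = 0.3)
    D <- distance_matrix(sim$sequences)
    dend <- single_linkage(D)
    mst <- minimum_spanning_tree(complete_graph(sim$sequences))
    for (t in c(-1, 0, sort(unique(c(dend$height))), max(D) + 1,
                stats::runif(2, 0, max(D)))) {
      expect_true(same_partition(cut_by_threshold(dend, t),
                                 mst_component_cut(mst, t)))
    }
  }
})
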