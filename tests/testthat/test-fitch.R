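test_that("small-parsimony DP reproduces hand-checked topologies", {
  P <- chain_outlier_set()
  # the single-linkage shape of the chain-plus-outlier set
  topo <- newick_topology(
    "(((s1110000,s1100000),s0000000),s1111111);", P)
  w <- fitch_min_weight(topo, P, per_site = TRUE)
  expect_equal(as.integer(w), 8L)
  expect_equal(attr(w, "site_changes"), c(1L, 1L, 2L, 1L, 1L, 1L, 1L))

  S <- acgt_set()
  topo2 <- newick_topology("((ACGT,ACCT),(ACCG,CCGT));", S)
  w2 <- fitch_min_weight(topo2, S, per_site = TRUE)
  expect_equal(as.integer(w2), 4L)
  expect_equal(attr(w2, "site_changes"), c(1L, 0L, 2L, 1L))

  # a cherry needs exactly the pairwise distance
  S2 <- seq_set(c(x = "ACGT", y = "CAGT"))
  cherry <- newick_topology("(x,y);", S2)
  expect_equal(fitch_min_weight(cherry, S2), hamming_distance("ACGT", "CAGT"))

  # identical leaves: zero changes, all labels identical
  S3 <- seq_set(c(a = "AAA", b = "AAA", c = "AAA"))
  star <- newick_topology("((a,b),c);", S3)
  expect_equal(fitch_min_weight(star, S3), 0L)
  lab <- fitch_label(star, S3)
  expect_true(all(lab$labels == "AAA"))
})

test_that("DP minimum equals exhaustive enumeration on small instances", {
  set.seed(19)
  alph_pool <- list(c("0", "1"), c("A", "C", "G"), c("A", "C", "G", "T"))
  for (rep in 1:12) {
    alphabet <- alph_pool[[sample.int(3, 1L)]]
    n_sites <- sample(2:4, 1L)
    sim <- simulate_tree_sequences(n_leaves = 4, n_sites = n_sites,
                                   alphabet = alphabet, p_sub = 0.4)
    # score a random 4-leaf binary topology (3 internal nodes)
    topos <- parsclust:::.all_topologies(sim$sequences$ids)
    topo <- parsclust:::.topology_cladogram(
      topos[[sample.int(length(topos), 1L)]], sim$sequences)
    expect_identical(
      fitch_min_weight(topo, alphabet = alphabet),
      exhaustive_min_labeling(topo, alphabet = alphabet))
  }

  # multifurcating shapes are handled exactly too
  S <- seq_set(c(a = "ACG", b = "AAG", c = "CCG", d = "CAT", e = "ACT"))
  star <- parsclust:::new_cladogram(
    data.frame(parent = rep("r", 5L), child = c("a", "b", "c", "d", "e")),
    c(S$seqs, r = NA_character_), "r", S$ids)
  expect_identical(fitch_min_weight(star, S),
                   exhaustive_min_labeling(star, S))
  mixed <- parsclust:::new_cladogram(
    data.frame(parent = c("r", "r", "r", "u", "u", "u"),
               child = c("a", "b", "u", "c", "d", "e")),
    c(S$seqs, r = NA_character_, u = NA_character_), "r", S$ids)
  expect_identical(fitch_min_weight(mixed, S),
                   exhaustive_min_labeling(mixed, S))
})

test_that("fitch_label attains the DP minimum deterministically", {
  set.seed(23)
  for (rep in 1:10) {
    m <- sample(3:6, 1L)
    sim <- simulate_tree_sequences(n_leaves = m, n_sites = 8, p_sub = 0.3)
    ll <- labeled_single_linkage(sim$sequences)
    relab <- fitch_label(ll$tree, alphabet = sim$sequences$alphabet)
    expect_equal(parsimony_weight(relab),
                 fitch_min_weight(ll$tree,
                                  alphabet = sim$sequences$alphabet))
    relab2 <- fitch_label(ll$tree, alphabet = sim$sequences$alphabet)
    expect_identical(relab$labels, relab2$labels)
  }

  # cherry traceback: weight is the pairwise distance and the internal
  # label takes the sitewise lexicographically smallest optimal state
  S2 <- seq_set(c(x = "ACGT", y = "CAGT"))
  cherry <- fitch_label(newick_topology("(x,y);", S2), S2)
  expect_equal(parsimony_weight(cherry), 2)
  internal <- setdiff(names(cherry$labels), cherry$leaves)
  expect_equal(unname(cherry$labels[internal]), "AAGT")
})

test_that("DP minimum agrees with an independent phylogenetics library", {
  skip_if_not_installed("phangorn")
  set.seed(29)
  for (rep in 1:5) {
    m <- sample(4:6, 1L)
    sim <- simulate_tree_sequences(n_leaves = m, n_sites = 10, p_sub = 0.25)
    S <- sim$sequences
    topos <- parsclust:::.all_topologies(S$ids)
    topo <- topos[[sample.int(length(topos), 1L)]]
    clado <- parsclust:::.topology_cladogram(topo, S)
    phy <- ape::as.phylo(fitch_label(clado, alphabet = S$alphabet))
    dat <- phangorn::phyDat(parsclust:::.seq_chars(S), type = "USER",
                            levels = S$alphabet)
    expect_equal(fitch_min_weight(clado, alphabet = S$alphabet),
                 as.integer(phangorn::parsimony(phy, dat,
                                                method = "fitch")))
  }
})

test_that("unlabeled leaves are rejected", {
  S <- acgt_set()
  topo <- newick_topology("((ACGT,ACCT),(ACCG,CCGT));", S)
  topo$labels[["ACGT"]] <- NA_character_
  expect_error(fitch_min_weight(topo), "leaf")
})
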