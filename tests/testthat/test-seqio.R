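test_that("read_fasta keeps record order and enforces alignment invariants", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ACGT", "ACGT", ">ACCT", "ACCT", ">ACCG", "ACCG",
               ">CCGT", "CCGT"), fa)
  S <- read_fasta(fa)
  expect_s3_class(S, "seq_set")
  expect_equal(S$ids, c("ACGT", "ACCT", "ACCG", "CCGT"))
  expect_equal(S$n, 4L)
  expect_equal(length(S), 4L)
  expect_equal(S$alphabet, c("A", "C", "G", "T"))

  one <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">only", "acgt"), one)
  S1 <- read_fasta(one)
  expect_equal(length(S1), 1L)
  expect_equal(unname(S1$seqs), "ACGT")  # upper-cased on read

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGTA"), bad)
  expect_error(read_fasta(bad), "equal length")

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "ACCT"), dup)
  expect_error(read_fasta(dup), "duplicate")

  expect_error(read_fasta(fa, alphabet = c("A", "C", "G")),
               "outside the declared alphabet")
})

test_that("newick export round-trips through a standard reader", {
  S <- acgt_set()
  cl <- mst_to_cladogram(minimum_spanning_tree(complete_graph(S)))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(cl, f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, S$ids)
  expect_equal(sum(phy$edge.length), 3)

  # re-writing the re-read tree reproduces the file: lossless round-trip
  f2 <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(phy, file = f2)
  expect_identical(readLines(f), readLines(f2))

  # reimported labeled tree has the same parsimony weight
  expect_equal(parsimony_weight(as_cladogram(phy, S)), 3)

  # two-leaf cladogram: branch lengths sum to the pairwise distance
  S2 <- seq_set(c(x = "AAAA", y = "ACCA"))
  cl2 <- mst_to_cladogram(minimum_spanning_tree(complete_graph(S2)))
  f3 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(cl2, f3)
  phy2 <- ape::read.tree(f3)
  expect_equal(sum(phy2$edge.length), hamming_distance("AAAA", "ACCA"))
})

test_that("linkage tables follow the 0-based merge-matrix convention", {
  S <- acgt_set()
  d <- single_linkage(distance_matrix(S))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_linkage_table(d, f)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$height, c(1, 1, 1))
  expect_true(all(diff(tab$height) >= 0))
  expect_true(all(tab$cluster1 >= 0 & tab$cluster2 >= 0))
  expect_equal(tab$size[nrow(tab)], 4L)
  # new clusters are indexed |S| + i - 1 in creation order
  expect_true(all(tab$cluster1 < 4 + seq_len(3) - 1))

  S2 <- seq_set(c(x = "AAAA", y = "ACCA"))
  d2 <- single_linkage(distance_matrix(S2))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_linkage_table(d2, f2)
  tab2 <- utils::read.delim(f2)
  expect_equal(nrow(tab2), 1L)
  expect_equal(tab2$height, 2)
  expect_equal(sort(c(tab2$cluster1, tab2$cluster2)), c(0, 1))
})

test_that("distance-matrix and cluster TSV exports read back unchanged", {
  S <- chain_outlier_set()
  D <- distance_matrix(S)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(D, f)
  back <- as.matrix(utils::read.delim(f, row.names = 1L,
                                      check.names = FALSE))
  expect_equal(unname(back), unname(D))

  cl <- cut_by_count(single_linkage(D), 2L)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_clusters(cl, f2)
  back2 <- utils::read.delim(f2)
  expect_equal(back2$id, names(cl))
  expect_equal(back2$cluster, unname(cl))
})
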