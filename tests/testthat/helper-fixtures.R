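# Shared fixtures and tiny independent oracles, all built in code.

# the four-sequence DNA example
acgt_set <- function() {
  seq_set(c(ACGT = "ACGT", ACCT = "ACCT", ACCG = "ACCG", CCGT = "CCGT"))
}

# the four binary sequences of the chain-plus-outlier counterexample
# (a chain at small Hamming steps plus a maximally distant outlier)
chain_outlier_set <- function() {
  seq_set(c(s1111111 = "1111111", s1110000 = "1110000",
            s1100000 = "1100000", s0000000 = "0000000"),
          alphabet = c("0", "1"))
}

# build a cladogram topology from a Newick string, leaves labeled from S
newick_topology <- function(text, S) {
  as_cladogram(ape::read.tree(text = text), S)
}

# independent brute-force minimum spanning tree weight: enumerate all
# (m-1)-edge subsets of the complete graph and keep the spanning ones
brute_mst_weight <- function(D) {
  ids <- rownames(D)
  m <- length(ids)
  pairs <- t(utils::combn(m, 2L))
  w <- D[pairs]
  best <- Inf
  for (sel in utils::combn(nrow(pairs), m - 1L, simplify = FALSE)) {
    parent <- seq_len(m)
    find <- function(i) {
      while (parent[[i]] != i) i <- parent[[i]]
      i
    }
    ok <- TRUE
    for (e in sel) {
      ri <- find(pairs[e, 1L])
      rj <- find(pairs[e, 2L])
      if (ri == rj) {
        ok <- FALSE
        break
      }
      parent[[ri]] <- rj
    }
    if (ok) best <- min(best, sum(w[sel]))
  }
  best
}

# random partition of ids into at most kmax blocks
random_partition <- function(ids, kmax = 3L) {
  stats::setNames(sample.int(kmax, length(ids), replace = TRUE), ids)
}

# connected components of the MST after deleting edges heavier than t
mst_component_cut <- function(mst, t) {
  keep <- mst$edges$weight <= t
  parent <- stats::setNames(seq_along(mst$vertices), mst$vertices)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  for (k in which(keep)) {
    ri <- find(match(mst$edges$from[[k]], mst$vertices))
    rj <- find(match(mst$edges$to[[k]], mst$vertices))
    if (ri != rj) parent[[ri]] <- rj
  }
  comp <- vapply(seq_along(mst$vertices), find, integer(1L))
  stats::setNames(match(comp, unique(comp)), mst$vertices)
}

# do two named cluster vectors induce the same partition?
same_partition <- function(a, b) {
  b <- b[names(a)]
  identical(unname(match(a, unique(a))), unname(match(b, unique(b))))
}
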