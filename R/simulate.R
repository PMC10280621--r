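# Synthetic fixtures: sequences evolved along a random tree, and
# adversarial "chain plus distant outlier" instances on which the
# single-linkage tree shape provably cannot match the MST parsimony.

#' Simulate sequences evolved along a random tree
#'
#' Draws a rooted binary topology by uniform stepwise leaf addition, a
#' root sequence uniform over the alphabet, and mutates each site
#' independently along every edge with the given per-site substitution
#' probability (a mutated site moves to a uniformly chosen different
#' state). The generating tree is returned fully labeled, so its
#' parsimony weight upper-bounds the optimum for the leaf set.
#'
#' @param n_leaves Number of leaves (>= 2), default 6.
#' @param n_sites Alignment length, default 10.
#' @param alphabet State set (>= 2 symbols), default `A`, `C`, `G`, `T`.
#' @param p_sub Per-site substitution probability per edge in `[0, 1]`,
#'   default 0.1.
#' @param seed Optional integer; when given, `set.seed(seed)` makes the
#'   output bit-for-bit reproducible.
#' @return List with `sequences` (a [seq_set()] of the leaves, declared
#'   over the full alphabet) and `tree` (the generating `cladogram`).
#' @export
simulate_tree_sequences <- function(n_leaves = 6L, n_sites = 10L,
                                    alphabet = c("A", "C", "G", "T"),
                                    p_sub = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  alphabet <- sort(unique(toupper(as.character(alphabet))), method = "radix")
  if (n_leaves < 2L || n_sites < 1L || length(alphabet) < 2L ||
      p_sub < 0 || p_sub > 1) {
    stop("degenerate simulation configuration", call. = FALSE)
  }
  ids <- sprintf("t%d", seq_len(n_leaves))

  # random rooted binary topology by stepwise addition
  mat <- matrix(c("R1", ids[[1L]], "R1", ids[[2L]]), 2L, 2L, byrow = TRUE)
  root <- "R1"
  nint <- 1L
  for (x in ids[-(1:2)]) {
    newid <- sprintf("R%d", nint + 1L)
    pos <- sample.int(nrow(mat) + 1L, 1L)
    if (pos > nrow(mat)) {
      mat <- rbind(mat, c(newid, root), c(newid, x))
      root <- newid
    } else {
      p <- mat[pos, 1L]
      c0 <- mat[pos, 2L]
      mat <- rbind(mat[-pos, , drop = FALSE],
                   c(p, newid), c(newid, c0), c(newid, x))
    }
    nint <- nint + 1L
  }

  mutate <- function(chars) {
    hit <- which(stats::runif(n_sites) < p_sub)
    for (i in hit) {
      chars[[i]] <- sample(setdiff(alphabet, chars[[i]]), 1L)
    }
    chars
  }
  ch <- split(mat[, 2L], mat[, 1L])
  labels <- list()
  labels[[root]] <- sample(alphabet, n_sites, replace = TRUE)
  walk <- function(nd) {
    for (cc in ch[[nd]]) {
      labels[[cc]] <<- mutate(labels[[nd]])
      if (!is.null(ch[[cc]])) walk(cc)
    }
  }
  walk(root)
  labstr <- vapply(labels, paste, character(1L), collapse = "")
  tree <- new_cladogram(
    data.frame(parent = mat[, 1L], child = mat[, 2L]),
    labstr, root = root, leaves = ids
  )
  S <- seq_set(labstr[ids], ids = ids, alphabet = alphabet)
  list(sequences = S, tree = tree)
}

#' Adversarial chain-plus-outlier instance
#'
#' Builds a binary-alphabet set on which the single-linkage tree shape
#' admits no labeling as light as the minimum spanning tree: a chain of
#' prefix-of-ones sequences descending in small Hamming steps (ones
#' counts `chain_length, chain_length - 1, ..., 2, 0`) preceded by the
#' all-ones outlier, which sits at distance `n` from the all-zeros end.
#' `make_demarcation_instance(3, 7)` reproduces the four binary
#' sequences `1111111, 1110000, 1100000, 0000000`; the MST weight of
#' every instance equals `n`.
#'
#' @param chain_length Number of chain sequences (>= 3).
#' @param n Sequence length, strictly greater than `chain_length`.
#' @return A [seq_set()] over `{0, 1}`, ids equal to the sequences.
#' @export
make_demarcation_instance <- function(chain_length = 3L, n = 7L) {
  if (chain_length < 3L) stop("chain_length must be >= 3", call. = FALSE)
  if (n <= chain_length) {
    stop("n must exceed chain_length so the all-ones outlier is distinct ",
         "from the chain", call. = FALSE)
  }
  ones <- c(n, chain_length:2, 0L)
  seqs <- vapply(ones, function(k) {
    paste0(strrep("1", k), strrep("0", n - k))
  }, character(1L))
  seq_set(seqs, ids = seqs, alphabet = c("0", "1"))
}
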