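# Brute-force ground truth at desk scale.
#
# Large parsimony is NP-complete, but for a handful of leaves every rooted
# binary leaf-labeled topology can be enumerated ((2m-3)!! of them via
# stepwise leaf insertion) and scored exactly by small-parsimony DP.
# Binary enumeration suffices for the optimum: contracting an edge of a
# multifurcating tree never lowers the weight below some binary
# resolution with a zero-length edge, so the binary minimum is global.
# Size guards refuse oversized instances rather than grind.

# all rooted binary leaf-labeled topologies on the given ids, as lists
# with a parent/child edge matrix and a root id
.all_topologies <- function(ids) {
  stopifnot(length(ids) >= 2L)
  base <- list(list(
    mat = matrix(c("R1", ids[[1L]], "R1", ids[[2L]]), 2L, 2L, byrow = TRUE),
    root = "R1", nint = 1L
  ))
  trees <- base
  for (x in ids[-(1:2)]) {
    cnt <- 0L
    out <- list()
    for (tr in trees) {
      newid <- sprintf("R%d", tr$nint + 1L)
      ne <- nrow(tr$mat)
      for (e in seq_len(ne)) {        # graft onto an existing edge
        p <- tr$mat[e, 1L]
        c0 <- tr$mat[e, 2L]
        mat <- rbind(tr$mat[-e, , drop = FALSE],
                     c(p, newid), c(newid, c0), c(newid, x))
        cnt <- cnt + 1L
        out[[cnt]] <- list(mat = mat, root = tr$root, nint = tr$nint + 1L)
      }
      mat <- rbind(tr$mat, c(newid, tr$root), c(newid, x))  # above the root
      cnt <- cnt + 1L
      out[[cnt]] <- list(mat = mat, root = newid, nint = tr$nint + 1L)
    }
    trees <- out
  }
  trees
}

.topology_cladogram <- function(topo, S) {
  labels <- stats::setNames(rep(NA_character_, topo$nint),
                            sprintf("R%d", seq_len(topo$nint)))
  labels <- c(S$seqs, labels)
  new_cladogram(
    data.frame(parent = topo$mat[, 1L], child = topo$mat[, 2L]),
    labels, root = topo$root, leaves = S$ids
  )
}

#' Exhaustive search for the most parsimonious tree
#'
#' Enumerates every rooted binary leaf-labeled topology on the sequence
#' set and scores each with [fitch_min_weight()] (exact for a fixed
#' topology), returning the global optimum. Intended as a ground-truth
#' oracle at desk scale only.
#'
#' @param S A [seq_set()].
#' @param max_leaves Refusal bound on the leaf count (default 8).
#' @return An `oracle_result`: list with `weight` (the optimal parsimony
#'   length), `tree` (one optimal fully labeled `cladogram`) and
#'   `n_topologies` (search-space size inspected).
#' @export
most_parsimonious_tree <- function(S, max_leaves = 8L) {
  stopifnot(inherits(S, "seq_set"))
  m <- length(S$ids)
  if (m > max_leaves) {
    stop("refusing exhaustive search over ", m, " leaves (bound ",
         max_leaves, "): the topology count grows as (2m-3)!!",
         call. = FALSE)
  }
  if (m == 1L) {
    tree <- new_cladogram(data.frame(parent = character(),
                                     child = character()),
                          S$seqs, root = S$ids, leaves = S$ids)
    return(structure(list(weight = 0L, tree = tree, n_topologies = 1L),
                     class = "oracle_result"))
  }
  topos <- .all_topologies(S$ids)
  best_w <- Inf
  best <- NULL
  for (topo in topos) {
    cl <- .topology_cladogram(topo, S)
    w <- fitch_min_weight(cl, alphabet = S$alphabet)
    if (w < best_w) {
      best_w <- w
      best <- cl
    }
  }
  structure(
    list(weight = as.integer(best_w),
         tree = fitch_label(best, alphabet = S$alphabet),
         n_topologies = length(topos)),
    class = "oracle_result"
  )
}

#' @export
print.oracle_result <- function(x, ...) {
  cat(sprintf("oracle_result: optimal parsimony weight %d (%d topologies)\n",
              x$weight, x$n_topologies))
  invisible(x)
}

#' Exhaustive minimum labeling of a fixed topology
#'
#' Direct enumeration of every assignment of alphabet states to the
#' internal nodes, site by site (exact for Hamming distance, where sites
#' decompose). Serves as an independent check of [fitch_min_weight()]:
#' it never runs the dynamic program.
#'
#' @inheritParams fitch_min_weight
#' @param max_assignments Refusal bound on per-site assignments
#'   (`|alphabet| ^ internal nodes`), default `2^20`.
#' @return Non-negative integer: the true minimum total weight.
#' @export
exhaustive_min_labeling <- function(topology, S = NULL, alphabet = NULL,
                                    max_assignments = 2^20) {
  topology <- .require_leaf_labels(topology, S)
  if (nrow(topology$edges) == 0L) return(0L)
  A <- .fitch_alphabet(topology, S, alphabet)
  nodes <- .clado_nodes(topology)
  internal <- setdiff(nodes, topology$leaves)
  k <- length(internal)
  if (length(A)^k > max_assignments) {
    stop("refusing enumeration of ", length(A), "^", k, " assignments",
         call. = FALSE)
  }
  n <- nchar(topology$labels[[topology$leaves[[1L]]]])
  leafchars <- lapply(topology$labels[topology$leaves],
                      function(s) match(strsplit(s, "", fixed = TRUE)[[1L]],
                                        A))
  if (k == 0L) {
    fn <- .get_metric("hamming")
    return(as.integer(sum(mapply(fn, topology$labels[topology$edges$parent],
                                 topology$labels[topology$edges$child]))))
  }
  grid <- as.matrix(expand.grid(rep(list(seq_along(A)), k),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- internal
  total <- 0L
  for (s in seq_len(n)) {
    state <- function(nd) {
      if (nd %in% internal) grid[, nd] else leafchars[[nd]][[s]]
    }
    cost <- numeric(nrow(grid))
    for (e in seq_len(nrow(topology$edges))) {
      cost <- cost + (state(topology$edges$parent[[e]]) !=
                        state(topology$edges$child[[e]]))
    }
    total <- total + min(cost)
  }
  as.integer(total)
}

#' Site-wise parsimony lower bound
#'
#' For each alignment site, any tree connecting all observed states needs
#' at least (number of distinct observed states - 1) changes; the sum
#' over sites lower-bounds the optimal parsimony length and certifies
#' oracle results when attained.
#'
#' @param S A [seq_set()].
#' @return Non-negative integer.
#' @export
parsimony_lower_bound <- function(S) {
  stopifnot(inherits(S, "seq_set"))
  chars <- .seq_chars(S)
  as.integer(sum(apply(chars, 2L, function(col) length(unique(col)) - 1L)))
}
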