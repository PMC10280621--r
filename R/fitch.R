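# Small parsimony on a fixed topology: optimal internal labeling under
# unordered, multistate, reversible characters.
#
# Implemented as uniform-cost dynamic programming (cost 0 for keeping a
# state along an edge, 1 for any change), which reduces to the classical
# Fitch procedure on binary nodes and handles multifurcations exactly --
# the MST-derived cladograms can be multifurcating. Sites are independent
# under Hamming distance, so per-site DP is exact for the whole alignment.

.require_leaf_labels <- function(topology, S) {
  stopifnot(inherits(topology, "cladogram"))
  if (!is.null(S)) {
    stopifnot(inherits(S, "seq_set"))
    miss <- setdiff(topology$leaves, S$ids)
    if (length(miss)) {
      stop("leaves without a sequence: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    topology$labels[topology$leaves] <- S$seqs[topology$leaves]
  }
  labs <- topology$labels[topology$leaves]
  if (anyNA(labs) || !all(topology$leaves %in% names(topology$labels))) {
    stop("every leaf must carry a sequence label", call. = FALSE)
  }
  topology
}

.fitch_alphabet <- function(topology, S, alphabet) {
  if (!is.null(alphabet)) {
    return(sort(unique(toupper(as.character(alphabet))), method = "radix"))
  }
  if (!is.null(S)) return(S$alphabet)
  sort(unique(unlist(strsplit(topology$labels[topology$leaves], "",
                              fixed = TRUE))), method = "radix")
}

.postorder_nodes <- function(x) {
  ch <- split(x$edges$child, x$edges$parent)
  out <- character(0)
  rec <- function(nd) {
    kids <- ch[[nd]]
    for (cc in kids) rec(cc)
    out <<- c(out, nd)
  }
  rec(x$root)
  out
}

# bottom-up pass; returns per-node state-cost matrices (|alphabet| x sites)
.fitch_dp <- function(topology, A) {
  BIG <- 1e6
  k <- length(A)
  n <- nchar(topology$labels[[topology$leaves[[1L]]]])
  ch <- split(topology$edges$child, topology$edges$parent)
  post <- .postorder_nodes(topology)
  cost <- vector("list", length(post))
  names(cost) <- post
  for (nd in post) {
    kids <- ch[[nd]]
    if (is.null(kids)) {
      m <- matrix(BIG, k, n)
      chars <- strsplit(topology$labels[[nd]], "", fixed = TRUE)[[1L]]
      idx <- match(chars, A)
      if (anyNA(idx)) {
        stop("leaf ", nd, " uses symbols outside the alphabet", call. = FALSE)
      }
      m[cbind(idx, seq_len(n))] <- 0
    } else {
      m <- matrix(0, k, n)
      for (cc in kids) {
        cm <- cost[[cc]]
        colmin <- do.call(pmin, asplit(cm, 1L))
        m <- m + pmin(cm, matrix(colmin + 1, k, n, byrow = TRUE))
      }
    }
    cost[[nd]] <- m
  }
  list(cost = cost, alphabet = A, n = n, children = ch, post = post)
}

#' Minimum small-parsimony weight of a fixed topology
#'
#' Computes the minimum of [parsimony_weight()] over all assignments of
#' alphabet sequences to the internal nodes of a fixed leaf-labeled
#' topology, by exact per-site uniform-cost dynamic programming.
#'
#' @param topology A `cladogram`; only its shape and leaf labels are used.
#' @param S Optional [seq_set()] supplying leaf sequences by id (required
#'   if the topology's leaves are unlabeled).
#' @param alphabet Optional state set; defaults to the alphabet of `S` or
#'   the symbols observed at the leaves.
#' @param per_site If `TRUE`, attach the per-site minimal change counts as
#'   attribute `"site_changes"`.
#' @return Non-negative integer: the minimal total number of changes.
#' @export
fitch_min_weight <- function(topology, S = NULL, alphabet = NULL,
                             per_site = FALSE) {
  topology <- .require_leaf_labels(topology, S)
  if (nrow(topology$edges) == 0L) return(0L)
  A <- .fitch_alphabet(topology, S, alphabet)
  dp <- .fitch_dp(topology, A)
  site_min <- do.call(pmin, asplit(dp$cost[[topology$root]], 1L))
  total <- as.integer(sum(site_min))
  if (per_site) attr(total, "site_changes") <- as.integer(site_min)
  total
}

#' Optimally relabel the internal nodes of a topology
#'
#' Runs the same dynamic program as [fitch_min_weight()] and then resolves
#' one optimal labeling by a deterministic top-down traceback: the root
#' takes the lexicographically smallest optimal state per site, and every
#' other node keeps its parent's state whenever that is optimal, falling
#' back to the lexicographically smallest optimal state.
#'
#' @inheritParams fitch_min_weight
#' @return A fully labeled `cladogram` whose [parsimony_weight()] equals
#'   `fitch_min_weight(topology, S)`.
#' @export
fitch_label <- function(topology, S = NULL, alphabet = NULL) {
  topology <- .require_leaf_labels(topology, S)
  if (nrow(topology$edges) == 0L) return(topology)
  A <- .fitch_alphabet(topology, S, alphabet)
  dp <- .fitch_dp(topology, A)
  n <- dp$n
  k <- length(A)
  state <- list()  # per-node integer vector of state indices per site

  rootcost <- dp$cost[[topology$root]]
  state[[topology$root]] <- max.col(-t(rootcost), ties.method = "first")
  # preorder: reversed postorder visits parents before children
  for (nd in rev(dp$post)) {
    ps <- state[[nd]]
    for (cc in dp$children[[nd]]) {
      cm <- dp$cost[[cc]]
      colmin <- do.call(pmin, asplit(cm, 1L))
      keep_cost <- cm[cbind(ps, seq_len(n))]
      st <- ifelse(keep_cost <= colmin + 1, ps,
                   max.col(-t(cm), ties.method = "first"))
      state[[cc]] <- st
    }
  }
  labels <- topology$labels
  leafset <- topology$leaves
  for (nd in names(state)) {
    if (!(nd %in% leafset)) {
      labels[[nd]] <- paste(A[state[[nd]]], collapse = "")
    }
  }
  new_cladogram(topology$edges, labels, topology$root, topology$leaves)
}
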