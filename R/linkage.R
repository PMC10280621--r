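# Single-linkage agglomerative clustering, plain and label-assigning.
#
# The plain variant is the textbook algorithm: repeatedly merge the two
# clusters with the smallest between-cluster distance, where the
# between-cluster (linkage) distance is the minimum pairwise distance
# between members. The label-assigning variant additionally records, at
# each merge, the member pair realizing that minimum and uses it to label
# the merged clusters' nodes, so the merge tree doubles as a cladogram
# whose labels all belong to the input set.
#
# Ties are broken lexicographically (C collation) on the clusters'
# smallest member ids, and within a merge on the sorted member id pair,
# making the whole construction deterministic. The agglomeration is the
# naive O(m^3) scan, ample at the scales this package targets.

.agglomerate <- function(D) {
  ids <- rownames(D)
  m <- length(ids)
  if (m < 2L) stop("clustering needs at least two sequences", call. = FALSE)
  rk <- .lex_rank(ids)

  members <- lapply(seq_len(m), function(i) i)   # member row indices
  codes <- -seq_len(m)                           # hclust-style codes
  reprs <- rk                                    # rank of smallest member id

  merge <- matrix(0L, m - 1L, 2L)
  height <- numeric(m - 1L)
  sizes <- integer(m - 1L)
  pa <- character(m - 1L)
  pb <- character(m - 1L)
  ca <- integer(m - 1L)
  cb <- integer(m - 1L)

  for (step in seq_len(m - 1L)) {
    nc <- length(members)
    best <- NULL
    for (i in seq_len(nc - 1L)) {
      for (j in (i + 1L):nc) {
        sub <- D[members[[i]], members[[j]], drop = FALSE]
        dij <- min(sub)
        key <- c(dij, min(reprs[[i]], reprs[[j]]), max(reprs[[i]], reprs[[j]]))
        if (is.null(best) ||
            key[1L] < best$key[1L] ||
            (key[1L] == best$key[1L] &&
             (key[2L] < best$key[2L] ||
              (key[2L] == best$key[2L] && key[3L] < best$key[3L])))) {
          best <- list(key = key, i = i, j = j, d = dij)
        }
      }
    }
    i <- best$i
    j <- best$j
    # member pair realizing the single-linkage minimum, tie-broken on the
    # sorted id pair
    sub <- D[members[[i]], members[[j]], drop = FALSE]
    hit <- which(sub == best$d, arr.ind = TRUE)
    cand_a <- members[[i]][hit[, 1L]]
    cand_b <- members[[j]][hit[, 2L]]
    lo <- pmin(rk[cand_a], rk[cand_b])
    hi <- pmax(rk[cand_a], rk[cand_b])
    pick <- order(lo, hi, method = "radix")[[1L]]

    merge[step, ] <- sort(c(codes[[i]], codes[[j]]))
    height[[step]] <- best$d
    sizes[[step]] <- length(members[[i]]) + length(members[[j]])
    ca[[step]] <- codes[[i]]
    cb[[step]] <- codes[[j]]
    pa[[step]] <- ids[[cand_a[[pick]]]]
    pb[[step]] <- ids[[cand_b[[pick]]]]

    members[[i]] <- c(members[[i]], members[[j]])
    codes[[i]] <- step
    reprs[[i]] <- min(reprs[[i]], reprs[[j]])
    members[[j]] <- NULL
    codes <- codes[-j]
    reprs <- reprs[-j]
  }
  list(labels = ids, merge = merge, height = height, sizes = sizes,
       ca = ca, cb = cb, pa = pa, pb = pb)
}

#' Single-linkage hierarchical clustering
#'
#' Standard agglomerative clustering under the single-linkage rule: the
#' distance between two clusters is the smallest pairwise distance
#' between their members.
#'
#' @param D Square symmetric distance matrix with id dimnames, as from
#'   [distance_matrix()].
#' @return An `sl_dendrogram`: list with `labels`, an hclust-convention
#'   `merge` matrix, the non-decreasing `height` vector (raw distance
#'   units), `sizes` of the newly formed clusters, and the merge
#'   provenance (`ca`, `cb`, `pa`, `pb`: cluster codes and the member
#'   pair realizing each minimum).
#' @examples
#' S <- seq_set(c(ACGT = "ACGT", ACCT = "ACCT", ACCG = "ACCG", CCGT = "CCGT"))
#' single_linkage(distance_matrix(S))$height # 1 1 1
#' @export
single_linkage <- function(D) {
  if (is.null(rownames(D)) || !is.matrix(D)) {
    stop("D must be a matrix with id dimnames", call. = FALSE)
  }
  res <- .agglomerate(D)
  structure(res, class = "sl_dendrogram")
}

#' @export
print.sl_dendrogram <- function(x, ...) {
  cat(sprintf("sl_dendrogram: %d leaves, %d merges, heights [%s]\n",
              length(x$labels), length(x$height),
              paste(signif(x$height, 4L), collapse = ", ")))
  invisible(x)
}

#' Normalize dendrogram heights by sequence length
#'
#' Divides every merge height by the alignment length `n`, the convention
#' used to put dendrograms of different-length alignments on a common
#' 0 to 1 scale.
#'
#' @param dend An `sl_dendrogram`.
#' @param n Sequence length (sites), at least 1.
#' @return The dendrogram with scaled heights; merge order is unchanged.
#' @export
normalize_heights <- function(dend, n) {
  stopifnot(inherits(dend, "sl_dendrogram"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive sequence length", call. = FALSE)
  }
  dend$height <- dend$height / n
  attr(dend, "normalized_by") <- n
  dend
}

#' @export
as.hclust.sl_dendrogram <- function(x, ...) {
  ord <- integer(0)
  walk <- function(code) {
    if (code < 0L) {
      ord <<- c(ord, -code)
    } else {
      walk(x$merge[code, 1L])
      walk(x$merge[code, 2L])
    }
  }
  walk(nrow(x$merge))
  structure(
    list(merge = x$merge, height = x$height, order = ord,
         labels = x$labels, method = "single", call = match.call(),
         dist.method = "hamming"),
    class = "hclust"
  )
}

#' @export
as.phylo.sl_dendrogram <- function(x, ...) {
  ape::as.phylo(as.hclust.sl_dendrogram(x))
}

#' Single-linkage clustering with in-set node labels
#'
#' Runs single-linkage agglomeration and simultaneously assigns sequence
#' labels to the merge tree's nodes: when two clusters merge, the member
#' pair realizing the single-linkage minimum labels them -- a singleton
#' keeps its own point, a non-singleton cluster's node is labeled by its
#' member of that pair. All labels therefore lie in the input set, and
#' the merge tree is a valid cladogram whose [parsimony_weight()] can be
#' compared with the MST bound. The final merged cluster (the root) is
#' never labeled by the agglomeration itself; it inherits the label of
#' its larger child (ties broken toward the lexicographically smaller
#' member id of the last minimum pair), a documented convention recorded
#' in the provenance table.
#'
#' @param S A [seq_set()] with at least two sequences.
#' @param metric Metric name or function (default `"hamming"`).
#' @return A `labeled_linkage`: list with `tree` (fully labeled
#'   `cladogram`), `dendrogram` (the matching [single_linkage()] result)
#'   and `provenance` (one row per merge: node, children, minimum pair,
#'   height).
#' @examples
#' S <- seq_set(c(A = "1111111", B = "1110000", C = "1100000", D = "0000000"),
#'              alphabet = c("0", "1"))
#' ll <- labeled_single_linkage(S)
#' parsimony_weight(ll$tree) # 9: worse than the MST weight 7
#' @export
labeled_single_linkage <- function(S, metric = "hamming") {
  stopifnot(inherits(S, "seq_set"))
  if (length(S$ids) < 2L) {
    stop("clustering needs at least two sequences", call. = FALSE)
  }
  D <- distance_matrix(S, metric)
  agg <- .agglomerate(D)
  dend <- structure(agg, class = "sl_dendrogram")

  node_of <- function(code) {
    if (code < 0L) agg$labels[[-code]] else sprintf("m%d", code)
  }
  nsteps <- length(agg$height)
  labels <- stats::setNames(unname(S$seqs[agg$labels]), agg$labels)
  ep <- character(0)
  ec <- character(0)
  for (step in seq_len(nsteps)) {
    parent <- sprintf("m%d", step)
    na <- node_of(agg$ca[[step]])
    nb <- node_of(agg$cb[[step]])
    ep <- c(ep, parent, parent)
    ec <- c(ec, na, nb)
    # label the two participating clusters from the minimum pair; leaves
    # already carry their own point
    if (agg$ca[[step]] > 0L) labels[[na]] <- S$seqs[[agg$pa[[step]]]]
    if (agg$cb[[step]] > 0L) labels[[nb]] <- S$seqs[[agg$pb[[step]]]]
    labels[[parent]] <- NA_character_
  }
  # root convention (the agglomeration never labels the final cluster)
  last <- nsteps
  size_a <- if (agg$ca[[last]] < 0L) 1L else agg$sizes[[agg$ca[[last]]]]
  size_b <- if (agg$cb[[last]] < 0L) 1L else agg$sizes[[agg$cb[[last]]]]
  root <- sprintf("m%d", last)
  root_from <- if (size_a > size_b) "a"
  else if (size_b > size_a) "b"
  else if (.lex_min(c(agg$pa[[last]], agg$pb[[last]])) == agg$pa[[last]]) "a"
  else "b"
  labels[[root]] <- if (root_from == "a") {
    labels[[node_of(agg$ca[[last]])]]
  } else {
    labels[[node_of(agg$cb[[last]])]]
  }

  tree <- new_cladogram(data.frame(parent = ep, child = ec),
                        labels, root = root, leaves = agg$labels)
  provenance <- data.frame(
    node = sprintf("m%d", seq_len(nsteps)),
    child_a = vapply(agg$ca, node_of, character(1L)),
    child_b = vapply(agg$cb, node_of, character(1L)),
    pair_a = agg$pa,
    pair_b = agg$pb,
    height = agg$height,
    size = agg$sizes
  )
  provenance$root_rule <- c(rep(NA_character_, nsteps - 1L),
                            sprintf("inherits child_%s", root_from))
  structure(list(tree = tree, dendrogram = dend, provenance = provenance),
            class = "labeled_linkage")
}

#' @export
print.labeled_linkage <- function(x, ...) {
  cat(sprintf(
    "labeled_linkage: %d leaves, heuristic parsimony weight %g\n",
    length(x$dendrogram$labels), parsimony_weight(x$tree)))
  invisible(x)
}
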