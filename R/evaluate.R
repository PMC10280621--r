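# Flat clusterings out of trees, and partition agreement by F-score.
#
# A clustering is a named integer vector mapping every id to a cluster
# index, with indices contiguous from 1 in order of first appearance.

.canon_clusters <- function(cl) {
  stats::setNames(match(cl, unique(cl)), names(cl))
}

# connected components of a set of undirected edges over `nodes`
.components <- function(nodes, ep, ec) {
  idx <- stats::setNames(seq_along(nodes), nodes)
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  for (k in seq_along(ep)) {
    ri <- find(idx[[ep[[k]]]])
    rj <- find(idx[[ec[[k]]]])
    if (ri != rj) parent[[ri]] <- rj
  }
  stats::setNames(vapply(seq_along(nodes), find, integer(1L)), nodes)
}

#' Cut a dendrogram at a height threshold
#'
#' Ids connected by merges at height at most `t` share a cluster. This is
#' the classical single-linkage flat cut, equivalent to deleting every
#' MST edge heavier than `t` and taking connected components.
#'
#' @param dend An `sl_dendrogram` (normalized or raw heights; `t` is on
#'   the same scale).
#' @param t Height threshold.
#' @return Named integer vector id -> cluster index.
#' @export
cut_by_threshold <- function(dend, t) {
  stopifnot(inherits(dend, "sl_dendrogram"))
  .canon_clusters(stats::cutree(stats::as.hclust(dend), h = t))
}

#' Cut a tree into k flat clusters
#'
#' For dendrograms, undoes the last `k - 1` merges (the standard
#' [stats::cutree()] count cut). For cladograms, removes edges in
#' decreasing weight order (ties broken deterministically) until the
#' leaves fall into exactly `k` components; since a removal never splits
#' off more than one leaf-bearing component at a time, every `k` up to
#' the leaf count is reached exactly. A depth-based alternative cuts all
#' edges crossing a root distance chosen to get as close to `k` clusters
#' as possible, warning when `k` itself is unreachable.
#'
#' @param tree An `sl_dendrogram` or a `cladogram`.
#' @param k Requested number of clusters, between 1 and the leaf count.
#' @param ... Passed to methods.
#' @return Named integer vector id -> cluster index.
#' @export
cut_by_count <- function(tree, k, ...) UseMethod("cut_by_count")

#' @export
cut_by_count.sl_dendrogram <- function(tree, k, ...) {
  m <- length(tree$labels)
  if (k < 1L || k > m) stop("k must be in 1..", m, call. = FALSE)
  .canon_clusters(stats::cutree(stats::as.hclust(tree), k = k))
}

#' @rdname cut_by_count
#' @param method `"weight"` (default) removes the heaviest edges;
#'   `"depth"` cuts edges crossing a root-distance level.
#' @param metric Metric for label-derived edge weights.
#' @export
cut_by_count.cladogram <- function(tree, k, method = c("weight", "depth"),
                                   metric = "hamming", ...) {
  method <- match.arg(method)
  m <- length(tree$leaves)
  if (k < 1L || k > m) stop("k must be in 1..", m, call. = FALSE)
  edges <- tree$edges
  labs <- tree$labels[.clado_nodes(tree)]
  if (!anyNA(labs)) {
    fn <- .get_metric(metric)
    w <- mapply(fn, tree$labels[edges$parent], tree$labels[edges$child])
  } else if (!is.null(edges$length)) {
    w <- edges$length
  } else {
    stop("cladogram has neither full labels nor stored branch lengths",
         call. = FALSE)
  }
  nodes <- .clado_nodes(tree)
  if (method == "weight") {
    ord <- order(-w, .lex_rank(edges$parent, nodes),
                 .lex_rank(edges$child, nodes), method = "radix")
    ndrop <- k - 1L
    repeat {
      keep <- setdiff(seq_len(nrow(edges)), ord[seq_len(ndrop)])
      comp <- .components(nodes, edges$parent[keep], edges$child[keep])
      cl <- .canon_clusters(comp[tree$leaves])
      if (max(cl) >= k || ndrop == nrow(edges)) break
      ndrop <- ndrop + 1L   # a cut stranded a leafless component; keep going
    }
    return(cl)
  }
  # depth variant: node depth = summed edge weight from the root; cutting
  # at level t removes edges reaching strictly deeper than t
  depth <- stats::setNames(numeric(length(nodes)), nodes)
  ch <- split(seq_len(nrow(edges)), edges$parent)
  walk <- function(nd) {
    for (ei in ch[[nd]]) {
      cc <- edges$child[[ei]]
      depth[[cc]] <<- depth[[nd]] + w[[ei]]
      walk(cc)
    }
  }
  walk(tree$root)
  cand <- sort(unique(depth), method = "radix")
  best <- NULL
  for (t in cand) {
    keep <- which(depth[edges$child] <= t)
    comp <- .components(nodes, edges$parent[keep], edges$child[keep])
    cl <- .canon_clusters(comp[tree$leaves])
    nk <- max(cl)
    if (is.null(best) || abs(nk - k) < abs(best$nk - k)) {
      best <- list(cl = cl, nk = nk)
    }
    if (nk == k) break
  }
  if (best$nk != k) {
    warning("requested k = ", k, " not achievable by depth cut; returning ",
            best$nk, " clusters")
  }
  best$cl
}

#' F-score agreement between two clusterings
#'
#' Compares two partitions of the same ids. The default `"pairwise"`
#' variant is the pair-counting F1: with TP the number of unordered id
#' pairs co-clustered in both partitions and pA, pB the co-clustered pair
#' counts of each partition, F = 2 TP / (pA + pB) (defined as 1 when both
#' partitions are all singletons). It is symmetric, equals 1 exactly on
#' identical partitions, and is invariant under cluster relabeling. The
#' `"matching"` variant is the cluster-matching F-measure
#' sum_i (|c_i|/N) max_j F1(c_i, c'_j), symmetrized by averaging both
#' directions.
#'
#' @param A,B Named integer vectors over the same id set (as returned by
#'   [cut_by_threshold()] / [cut_by_count()]).
#' @param variant `"pairwise"` (default) or `"matching"`.
#' @return A number in `[0, 1]`.
#' @export
fscore <- function(A, B, variant = c("pairwise", "matching")) {
  variant <- match.arg(variant)
  if (is.null(names(A)) || is.null(names(B)) ||
      !setequal(names(A), names(B)) || length(A) != length(B)) {
    stop("A and B must be clusterings of the same id set", call. = FALSE)
  }
  B <- B[names(A)]
  if (length(A) == 1L) return(1)
  if (variant == "pairwise") {
    up <- upper.tri(matrix(0, length(A), length(A)))
    coA <- outer(A, A, "==")[up]
    coB <- outer(B, B, "==")[up]
    pA <- sum(coA)
    pB <- sum(coB)
    tp <- sum(coA & coB)
    if (pA + pB == 0L) return(1)
    return(2 * tp / (pA + pB))
  }
  one_way <- function(X, Y) {
    n <- length(X)
    xs <- split(names(X), X)
    ys <- split(names(Y), Y)
    sum(vapply(xs, function(cx) {
      f1 <- vapply(ys, function(cy) {
        2 * length(intersect(cx, cy)) / (length(cx) + length(cy))
      }, numeric(1L))
      length(cx) / n * max(f1)
    }, numeric(1L)))
  }
  (one_way(A, B) + one_way(B, A)) / 2
}
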