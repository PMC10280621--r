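# Minimum spanning tree of the complete sequence graph.
#
# Kruskal with a fully deterministic total order on edges: sort by
# (weight, lexicographic id pair). Several MSTs usually exist (the
# four-sequence DNA example has three equal first picks); the tie-break
# makes output reproducible. The MST weight itself is unique regardless.

#' Minimum spanning tree of a weighted sequence graph
#'
#' @param G A [complete_graph()] result (any connected `seq_graph` works).
#' @return A `spanning_tree`: list with `vertices`, `sequences`, `edges`
#'   (data frame `from`, `to`, `weight`), `root` (the lexicographically
#'   smallest vertex id, used to orient the tree downstream) and `weight`
#'   (total edge weight).
#' @examples
#' S <- seq_set(c(ACGT = "ACGT", ACCT = "ACCT", ACCG = "ACCG", CCGT = "CCGT"))
#' minimum_spanning_tree(complete_graph(S))$weight # 3
#' @export
minimum_spanning_tree <- function(G) {
  stopifnot(inherits(G, "seq_graph"))
  v <- G$vertices
  if (length(v) == 0L) stop("empty graph", call. = FALSE)
  if (length(v) == 1L) {
    return(structure(
      list(vertices = v, sequences = G$sequences,
           edges = data.frame(from = character(), to = character(),
                              weight = numeric()),
           root = v, weight = 0),
      class = "spanning_tree"
    ))
  }
  e <- G$edges
  rf <- .lex_rank(e$from, v)
  rt <- .lex_rank(e$to, v)
  a <- pmin(rf, rt)
  b <- pmax(rf, rt)
  ord <- order(e$weight, a, b, method = "radix")

  parent <- seq_along(v)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  vid <- stats::setNames(seq_along(v), v)
  keep <- integer(0)
  for (k in ord) {
    ri <- find(vid[[e$from[[k]]]])
    rj <- find(vid[[e$to[[k]]]])
    if (ri != rj) {
      parent[[ri]] <- rj
      keep <- c(keep, k)
      if (length(keep) == length(v) - 1L) break
    }
  }
  if (length(keep) != length(v) - 1L) {
    stop("graph is not connected", call. = FALSE)
  }
  edges <- e[keep, , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(vertices = v, sequences = G$sequences, edges = edges,
         root = .lex_min(v), weight = sum(edges$weight)),
    class = "spanning_tree"
  )
}

#' Total weight of a tree
#'
#' For a spanning tree, the sum of its edge weights; for a cladogram, the
#' parsimony length (see [parsimony_weight()]).
#'
#' @param tree A `spanning_tree` or `cladogram`.
#' @param ... Passed on to methods.
#' @return Non-negative number.
#' @export
tree_weight <- function(tree, ...) UseMethod("tree_weight")

#' @export
tree_weight.spanning_tree <- function(tree, ...) sum(tree$edges$weight)

#' @export
tree_weight.cladogram <- function(tree, ...) parsimony_weight(tree, ...)

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf("spanning_tree: %d vertices, weight %g, root %s\n",
              length(x$vertices), x$weight, x$root))
  invisible(x)
}
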