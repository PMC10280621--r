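# Rooted labeled trees (cladograms) and the MST-to-cladogram construction.
#
# A cladogram here is a rooted tree whose leaves are in bijection with the
# input sequence set and whose every node carries a sequence label (possibly
# a hypothetical ancestor outside the observed set). Its parsimony length is
# the sum over edges of the distance between the endpoint labels.

new_cladogram <- function(edges, labels, root, leaves) {
  structure(
    list(edges = edges, labels = labels, root = root, leaves = leaves),
    class = "cladogram"
  )
}

.clado_nodes <- function(x) {
  unique(c(x$root, x$edges$parent, x$edges$child))
}

.children_map <- function(x) {
  split(x$edges$child, factor(x$edges$parent, levels = unique(x$edges$parent)))
}

#' @export
print.cladogram <- function(x, ...) {
  nl <- x$labels[.clado_nodes(x)]
  cat(sprintf("cladogram: %d leaves, %d nodes, root %s%s\n",
              length(x$leaves), length(.clado_nodes(x)), x$root,
              if (anyNA(nl)) " (internal labels incomplete)" else
                sprintf(", parsimony weight %g", parsimony_weight(x))))
  invisible(x)
}

#' Parsimony length of a labeled tree
#'
#' Sums, over all edges of the cladogram, the distance between the
#' sequences labeling the edge's endpoints. Zero-weight pendant edges
#' (identical labels) contribute nothing.
#'
#' @param tree A fully labeled `cladogram`.
#' @param metric Metric name or function (default `"hamming"`).
#' @return Non-negative number.
#' @export
parsimony_weight <- function(tree, metric = "hamming") {
  stopifnot(inherits(tree, "cladogram"))
  nodes <- .clado_nodes(tree)
  labs <- tree$labels[nodes]
  if (anyNA(labs) || !all(nodes %in% names(tree$labels))) {
    stop("cladogram has unlabeled nodes; label them (e.g. with fitch_label) ",
         "before computing a parsimony weight", call. = FALSE)
  }
  if (nrow(tree$edges) == 0L) return(0)
  fn <- .get_metric(metric)
  sum(mapply(fn, tree$labels[tree$edges$parent],
             tree$labels[tree$edges$child]))
}

#' Convert a minimum spanning tree into a parsimonious cladogram
#'
#' Rebuilds a spanning tree of the sequence graph as a rooted cladogram of
#' identical total weight in which every original vertex appears as a
#' leaf. The tree is oriented away from its designated root and peeled
#' iteratively: each current leaf attaches below (a copy of) its
#' predecessor, and the first time a vertex serves as a predecessor it
#' receives a zero-weight pendant edge to its own leaf copy, so internal
#' labels all belong to the input set and the zero edges add no weight.
#' Vertices of degree greater than two yield multifurcations; no
#' binarization is performed.
#'
#' @param tree A [minimum_spanning_tree()] result.
#' @return A fully labeled `cladogram` with
#'   `parsimony_weight(result) == tree_weight(tree)`.
#' @examples
#' S <- seq_set(c(ACGT = "ACGT", ACCT = "ACCT", ACCG = "ACCG", CCGT = "CCGT"))
#' cl <- mst_to_cladogram(minimum_spanning_tree(complete_graph(S)))
#' parsimony_weight(cl) # 3
#' @export
mst_to_cladogram <- function(tree) {
  stopifnot(inherits(tree, "spanning_tree"))
  v <- tree$vertices
  labels <- tree$sequences[v]
  if (length(v) == 1L) {
    return(new_cladogram(
      data.frame(parent = character(), child = character()),
      labels, root = v, leaves = v
    ))
  }

  # orient edges away from the root
  adj <- list()
  for (k in seq_len(nrow(tree$edges))) {
    f <- tree$edges$from[[k]]
    t <- tree$edges$to[[k]]
    adj[[f]] <- c(adj[[f]], t)
    adj[[t]] <- c(adj[[t]], f)
  }
  parent <- stats::setNames(rep(NA_character_, length(v)), v)
  seen <- stats::setNames(logical(length(v)), v)
  queue <- tree$root
  seen[[tree$root]] <- TRUE
  while (length(queue)) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    for (nb in adj[[cur]]) {
      if (!seen[[nb]]) {
        seen[[nb]] <- TRUE
        parent[[nb]] <- cur
        queue <- c(queue, nb)
      }
    }
  }

  kidcount <- stats::setNames(integer(length(v)), v)
  tab <- table(parent[!is.na(parent)])
  kidcount[names(tab)] <- as.integer(tab)

  anc <- function(id) paste0(id, ".anc")
  repr <- stats::setNames(v, v)   # current output node standing for vertex
  has_anc <- stats::setNames(logical(length(v)), v)
  ep <- character(0)
  ec <- character(0)
  remaining <- v
  while (length(remaining) > 1L) {
    L <- sort(remaining[kidcount[remaining] == 0L], method = "radix")
    P <- sort(unique(parent[L]), method = "radix")
    for (p in P) {
      if (!has_anc[[p]]) {
        a <- anc(p)
        labels[[a]] <- tree$sequences[[p]]
        ep <- c(ep, a)            # zero-weight pendant: identical labels
        ec <- c(ec, repr[[p]])
        repr[[p]] <- a
        has_anc[[p]] <- TRUE
      }
    }
    for (u in L) {
      pu <- parent[[u]]
      ep <- c(ep, repr[[pu]])
      ec <- c(ec, repr[[u]])
      kidcount[[pu]] <- kidcount[[pu]] - 1L
    }
    remaining <- setdiff(remaining, L)
  }
  new_cladogram(
    data.frame(parent = ep, child = ec),
    labels, root = repr[[tree$root]], leaves = v
  )
}

#' Validate a cladogram against a sequence set
#'
#' Checks that the leaves are in bijection with the sequence set, that
#' leaf labels match their sequences, that all labels have the alignment
#' length, and that the edges form a single rooted tree. Violations are
#' reported, not thrown.
#'
#' @param tree A `cladogram`.
#' @param S The [seq_set()] its leaves should represent.
#' @return Character vector of violations; empty when valid.
#' @export
validate_cladogram <- function(tree, S) {
  stopifnot(inherits(tree, "cladogram"), inherits(S, "seq_set"))
  bad <- character(0)
  if (!setequal(tree$leaves, S$ids)) {
    bad <- c(bad, sprintf(
      "leaf set does not match sequence ids (missing: %s; extra: %s)",
      paste(setdiff(S$ids, tree$leaves), collapse = ","),
      paste(setdiff(tree$leaves, S$ids), collapse = ",")))
  }
  for (id in intersect(tree$leaves, S$ids)) {
    lab <- tree$labels[[id]]
    if (is.na(lab) || lab != S$seqs[[id]]) {
      bad <- c(bad, sprintf("leaf %s label differs from its sequence", id))
    }
  }
  labs <- tree$labels[!is.na(tree$labels)]
  wrong <- names(labs)[nchar(labs) != S$n]
  if (length(wrong)) {
    bad <- c(bad, sprintf("labels with length != %d: %s", S$n,
                          paste(wrong, collapse = ",")))
  }
  nodes <- .clado_nodes(tree)
  if (nrow(tree$edges) != length(nodes) - 1L) {
    bad <- c(bad, "edge count is not node count - 1")
  }
  if (anyDuplicated(tree$edges$child) ||
      tree$root %in% tree$edges$child) {
    bad <- c(bad, "some node has more than one parent (or the root has one)")
  }
  reach <- tree$root
  frontier <- tree$root
  ch <- split(tree$edges$child, tree$edges$parent)
  while (length(frontier)) {
    nxt <- unlist(ch[intersect(frontier, names(ch))], use.names = FALSE)
    nxt <- setdiff(nxt, reach)
    reach <- c(reach, nxt)
    frontier <- nxt
  }
  if (!setequal(reach, nodes)) {
    bad <- c(bad, "not all nodes are reachable from the root")
  }
  bad
}

#' Convert a cladogram to an ape phylo object
#'
#' Tips keep their sequence ids; internal nodes are named by the id of the
#' set member carrying the same label when there is one, otherwise by the
#' node id. Edge lengths are metric distances between endpoint labels when
#' the tree is fully labeled.
#'
#' @param x A `cladogram` with at least two leaves.
#' @param metric Metric used for edge lengths.
#' @param ... Unused.
#' @return An object of class `phylo`.
#' @export
as.phylo.cladogram <- function(x, metric = "hamming", ...) {
  tips <- x$leaves
  nt <- length(tips)
  if (nt < 2L) stop("phylo conversion needs at least two leaves",
                    call. = FALSE)
  ch <- split(x$edges$child, x$edges$parent)
  internal <- character(0)
  epre <- character(0)   # edges in depth-first (cladewise) order
  ecre <- character(0)
  pre <- function(nd) {
    if (!(nd %in% tips)) {
      internal <<- c(internal, nd)
      for (cc in ch[[nd]]) {
        epre <<- c(epre, nd)
        ecre <<- c(ecre, cc)
        pre(cc)
      }
    }
  }
  pre(x$root)
  num <- stats::setNames(c(seq_len(nt), nt + seq_along(internal)),
                         c(tips, internal))
  edge <- cbind(unname(num[epre]), unname(num[ecre]))

  labs <- x$labels[c(tips, internal)]
  elen <- NULL
  if (!anyNA(labs)) {
    fn <- .get_metric(metric)
    elen <- unname(mapply(fn, x$labels[epre], x$labels[ecre]))
  }
  leaf_seq <- x$labels[tips]
  owner <- stats::setNames(tips, leaf_seq)[!duplicated(leaf_seq)]
  node_name <- vapply(internal, function(nd) {
    lab <- x$labels[[nd]]
    if (!is.na(lab) && !is.na(owner[lab])) unname(owner[[lab]]) else nd
  }, character(1L))

  phy <- list(edge = edge, tip.label = tips, Nnode = length(internal),
              node.label = unname(node_name))
  if (!is.null(elen)) phy$edge.length <- elen
  class(phy) <- "phylo"
  phy
}

#' Build a cladogram from an ape phylo topology
#'
#' Imports a tree (for example read from Newick) as a `cladogram`. Leaf
#' labels are filled from `S` by tip name when given; internal nodes are
#' labeled from `S` when their Newick name matches a sequence id,
#' otherwise left unlabeled (use [fitch_label()] to complete them). Branch
#' lengths, when present, are kept in `edges$length`.
#'
#' @param phy An ape `phylo` object.
#' @param S Optional [seq_set()] supplying sequences by id.
#' @return A `cladogram`.
#' @export
as_cladogram <- function(phy, S = NULL) {
  stopifnot(inherits(phy, "phylo"))
  nt <- length(phy$tip.label)
  ids <- c(phy$tip.label,
           vapply(seq_len(phy$Nnode), function(i) sprintf("h%d", i),
                  character(1L)))
  edges <- data.frame(parent = ids[phy$edge[, 1L]],
                      child = ids[phy$edge[, 2L]])
  if (!is.null(phy$edge.length)) edges$length <- phy$edge.length
  labels <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(S)) {
    miss <- setdiff(phy$tip.label, S$ids)
    if (length(miss)) {
      stop("tips without a sequence: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    labels[phy$tip.label] <- S$seqs[phy$tip.label]
    if (!is.null(phy$node.label)) {
      hit <- phy$node.label %in% S$ids
      labels[ids[nt + which(hit)]] <- S$seqs[phy$node.label[hit]]
    }
  }
  new_cladogram(edges, labels, root = ids[[nt + 1L]],
                leaves = phy$tip.label)
}
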