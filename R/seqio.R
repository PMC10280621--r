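#' Aligned sequence sets
#'
#' A `seq_set` bundles aligned, equal-length sequences over a finite
#' alphabet: the input object of every analysis in the package. Sequences
#' are upper-cased on construction so that Hamming comparisons are
#' case-insensitive; gap or ambiguity symbols (`-`, `N`, ...) are ordinary
#' alphabet states and count as mismatches against any other state.
#'
#' @param seqs Character vector of sequences, all of the same length.
#' @param ids Character vector of unique, non-empty identifiers; defaults
#'   to `names(seqs)`.
#' @param alphabet Character vector of permitted symbols, or `"infer"`
#'   (default) to use the set of symbols observed in `seqs`.
#'
#' @return An object of class `seq_set` with fields `ids`, `seqs` (named
#'   by id), `n` (alignment length in sites) and `alphabet`.
#' @examples
#' seq_set(c(a = "ACGT", b = "ACCT", c = "ACCG", d = "CCGT"))
#' @export
seq_set <- function(seqs, ids = names(seqs), alphabet = "infer") {
  force(ids)
  seqs <- toupper(as.character(seqs))
  if (length(seqs) < 1L) {
    stop("a seq_set needs at least one sequence", call. = FALSE)
  }
  if (is.null(ids)) {
    stop("sequence identifiers are required", call. = FALSE)
  }
  ids <- as.character(ids)
  if (length(ids) != length(seqs) || anyNA(ids) || any(!nzchar(ids))) {
    stop("every sequence needs a non-empty identifier", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences must be aligned to equal length (found lengths ",
         paste(sort(unique(lens)), collapse = ", "), ")", call. = FALSE)
  }
  n <- lens[[1L]]
  if (n < 1L) stop("sequences must have length >= 1", call. = FALSE)
  observed <- sort(unique(unlist(strsplit(seqs, "", fixed = TRUE))),
                   method = "radix")
  if (identical(alphabet, "infer")) {
    alphabet <- observed
  } else {
    alphabet <- sort(unique(toupper(as.character(alphabet))), method = "radix")
    bad <- setdiff(observed, alphabet)
    if (length(bad)) {
      stop("symbols outside the declared alphabet: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(ids = ids, seqs = stats::setNames(seqs, ids), n = n,
         alphabet = alphabet),
    class = "seq_set"
  )
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("seq_set: %d sequences of length %d over {%s}\n",
              length(x$ids), x$n, paste(x$alphabet, collapse = ",")))
  show <- utils::head(x$ids, 6L)
  for (id in show) cat(sprintf("  %s  %s\n", id, x$seqs[[id]]))
  if (length(x$ids) > 6L) cat(sprintf("  ... %d more\n", length(x$ids) - 6L))
  invisible(x)
}

#' @export
length.seq_set <- function(x) length(x$ids)

# sites-by-record character matrix view (rows = records)
.seq_chars <- function(S) {
  m <- do.call(rbind, strsplit(unname(S$seqs), "", fixed = TRUE))
  rownames(m) <- S$ids
  m
}

#' Read an aligned FASTA file
#'
#' Reads a FASTA file into a [seq_set()]. Record order follows file order;
#' the identifier is the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @inheritParams seq_set
#' @return A [seq_set()].
#' @export
read_fasta <- function(path, alphabet = "infer") {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) < 1L) stop("no FASTA records in ", path, call. = FALSE)
  ids <- vapply(strsplit(names(ss), "[ \t]+"), `[[`, character(1L), 1L)
  seq_set(as.character(ss), ids = ids, alphabet = alphabet)
}

#' Write a seq_set to FASTA
#'
#' @param S A [seq_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(S, path) {
  stopifnot(inherits(S, "seq_set"))
  Biostrings::writeXStringSet(Biostrings::BStringSet(S$seqs), path)
  invisible(path)
}

# quote a label for Newick if it contains reserved characters
.newick_safe <- function(x) {
  bad <- grepl("[][():;,'\"[:space:]]", x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}

#' Write a tree as Newick
#'
#' Writes a cladogram or single-linkage dendrogram to a Newick file.
#' Branch lengths are the edge distance contributions: for cladograms the
#' distance between the endpoint labels (optionally divided by the
#' sequence length), for dendrograms the merge-height differences.
#' Internal node names carry the identifier of the sequence labeling the
#' node when that sequence belongs to the input set, otherwise a
#' synthesized node id.
#'
#' @param tree A [mst_to_cladogram()]-style cladogram or a
#'   [single_linkage()] dendrogram.
#' @param path Output file path.
#' @param lengths `"raw"` (default) or `"normalized"` (divide by the
#'   sequence length, cladograms only).
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, lengths = c("raw", "normalized")) {
  lengths <- match.arg(lengths)
  phy <- ape::as.phylo(tree)
  if (lengths == "normalized" && !is.null(phy$edge.length)) {
    if (!inherits(tree, "cladogram")) {
      stop("normalized branch lengths apply to cladograms; ",
           "use normalize_heights() on dendrograms", call. = FALSE)
    }
    n <- nchar(tree$labels[[tree$leaves[[1L]]]])
    phy$edge.length <- phy$edge.length / n
  }
  phy$tip.label <- .newick_safe(phy$tip.label)
  if (!is.null(phy$node.label)) phy$node.label <- .newick_safe(phy$node.label)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write a linkage table
#'
#' Emits the merge history of a dendrogram as a TSV in the widely used
#' linkage-matrix convention: original points are indexed `0..m-1` in
#' label order, the i-th newly created cluster is indexed `m + i - 1`,
#' and each of the `m - 1` rows gives the two merged cluster indices, the
#' merge height, and the size of the new cluster.
#'
#' @param dendrogram A [single_linkage()] dendrogram.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_linkage_table <- function(dendrogram, path) {
  stopifnot(inherits(dendrogram, "sl_dendrogram"))
  m <- length(dendrogram$labels)
  code2idx <- function(v) ifelse(v < 0L, -v - 1L, m + v - 1L)
  tab <- data.frame(
    cluster1 = code2idx(dendrogram$merge[, 1L]),
    cluster2 = code2idx(dendrogram$merge[, 2L]),
    height = dendrogram$height,
    size = dendrogram$sizes
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix as TSV
#'
#' @param D A square distance matrix with id dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path) {
  utils::write.table(as.data.frame(D), path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Write a flat clustering as TSV
#'
#' @param clustering Named integer vector mapping id to cluster index.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clustering, path) {
  utils::write.table(
    data.frame(id = names(clustering), cluster = unname(clustering)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
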