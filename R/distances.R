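# Pairwise distances on aligned sequences and the complete weighted graph.
#
# Metrics live in a small registry keyed by name so alternatives satisfying
# the three distance axioms can plug in; "hamming" is the default and the
# only built-in. Hamming distances are exact integers; normalized values
# are derived on demand and never stored.

.metrics <- new.env(parent = emptyenv())

#' Register a sequence metric
#'
#' @param name Metric name.
#' @param fn Function of two equal-length sequences returning a
#'   non-negative number; it must satisfy the distance axioms.
#' @return `name`, invisibly.
#' @export
register_metric <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .metrics)
  invisible(name)
}

.get_metric <- function(name) {
  if (is.function(name)) return(name)
  if (!exists(name, envir = .metrics, inherits = FALSE)) {
    stop("unknown metric: ", name, call. = FALSE)
  }
  get(name, envir = .metrics, inherits = FALSE)
}

#' Hamming distance between two sequences
#'
#' Counts the positions at which two equal-length sequences differ.
#'
#' @param x,y Character scalars of equal length.
#' @return Non-negative integer; 0 if and only if `x == y`.
#' @examples
#' hamming_distance("ACGT", "ACCT") # 1
#' @export
hamming_distance <- function(x, y) {
  x <- toupper(x)
  y <- toupper(y)
  if (nchar(x) != nchar(y)) {
    stop("sequences differ in length (", nchar(x), " vs ", nchar(y), ")",
         call. = FALSE)
  }
  sum(strsplit(x, "", fixed = TRUE)[[1L]] != strsplit(y, "", fixed = TRUE)[[1L]])
}

#' Pairwise distance matrix of a sequence set
#'
#' @param S A [seq_set()].
#' @param metric Metric name (see [register_metric()]) or a function.
#' @return Square symmetric numeric matrix with zero diagonal, dimnames
#'   the sequence ids, entry order matching record order.
#' @export
distance_matrix <- function(S, metric = "hamming") {
  stopifnot(inherits(S, "seq_set"))
  m <- length(S$ids)
  D <- matrix(0, m, m, dimnames = list(S$ids, S$ids))
  if (m == 1L) return(D)
  if (identical(metric, "hamming")) {
    chars <- .seq_chars(S)
    for (i in seq_len(m - 1L)) {
      ci <- chars[i, ]
      for (j in (i + 1L):m) {
        D[i, j] <- D[j, i] <- sum(ci != chars[j, ])
      }
    }
  } else {
    fn <- .get_metric(metric)
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        D[i, j] <- D[j, i] <- fn(S$seqs[[i]], S$seqs[[j]])
      }
    }
  }
  D
}

#' Complete weighted graph of a sequence set
#'
#' Builds the complete graph on the ids of `S`, each edge weighted by the
#' chosen metric between its endpoint sequences.
#'
#' @inheritParams distance_matrix
#' @return A `seq_graph`: list with `vertices`, `sequences` (named by id)
#'   and an `edges` data frame (`from`, `to`, `weight`) with one row per
#'   unordered pair in record order.
#' @export
complete_graph <- function(S, metric = "hamming") {
  stopifnot(inherits(S, "seq_set"))
  D <- distance_matrix(S, metric)
  m <- length(S$ids)
  if (m >= 2L) {
    pairs <- t(utils::combn(m, 2L))
    edges <- data.frame(
      from = S$ids[pairs[, 1L]],
      to = S$ids[pairs[, 2L]],
      weight = D[pairs]
    )
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
  }
  structure(
    list(vertices = S$ids, sequences = S$seqs, edges = edges,
         metric = if (is.character(metric)) metric else "custom"),
    class = "seq_graph"
  )
}

#' @export
print.seq_graph <- function(x, ...) {
  cat(sprintf("seq_graph: %d vertices, %d edges (%s metric)\n",
              length(x$vertices), nrow(x$edges), x$metric))
  invisible(x)
}

# locale-independent rank of character vectors (C-collation), used for
# every lexicographic tie-break in the package
.lex_rank <- function(x, universe = x) {
  match(x, sort(unique(universe), method = "radix"))
}

# smallest element under C-collation
.lex_min <- function(x) sort(x, method = "radix")[[1L]]

assign("hamming", hamming_distance, envir = .metrics)
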