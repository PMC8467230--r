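# Pairwise global alignment statistics.
#
# All pairwise comparisons in the package use one alignment model: global
# alignment with unit mismatch and unit gap costs, minimising cost and,
# among cost-optimal alignments, maximising matched columns (which pins
# down the match/mismatch/gap column counts uniquely; see src/align.cpp).

.nw_counts <- function(a, b) {
  st <- nw_stats_cpp(a, b)
  la <- nchar(a); lb <- nchar(b)
  matches <- st[["matches"]]
  mismatches <- la + lb - 2L * matches - st[["cost"]]
  list(cost = st[["cost"]], matches = matches, mismatches = mismatches,
       aligned_cols = matches + mismatches,       # gap-free columns
       alignment_length = matches + st[["cost"]])
}

#' Pairwise sequence identity
#'
#' Identity of a global unit-cost alignment. With the default
#' `"shorter"` denominator (the convention of greedy identity clustering
#' tools) identity is matched columns divided by the length of the
#' shorter sequence; `"alignment"` divides by alignment length instead.
#'
#' @param a,b non-empty DNA strings.
#' @param denominator `"shorter"` or `"alignment"`.
#' @return fraction in `[0, 1]`; symmetric in `a` and `b`.
#' @export
pairwise_identity <- function(a, b, denominator = c("shorter", "alignment")) {
  denominator <- match.arg(denominator)
  stopifnot(nzchar(a), nzchar(b))
  if (a == b) return(1)
  cnt <- .nw_counts(a, b)
  den <- if (denominator == "shorter") min(nchar(a), nchar(b)) else cnt$alignment_length
  cnt$matches / den
}

#' Pairwise uncorrected p-distance
#'
#' Proportion of mismatched columns among gap-free columns (pairwise
#' deletion) of a global unit-cost alignment.
#'
#' @param a,b non-empty DNA strings.
#' @return fraction in `[0, 1]`; symmetric.
#' @export
pairwise_p_distance <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  if (a == b) return(0)
  cnt <- .nw_counts(a, b)
  if (cnt$aligned_cols == 0L)
    stop("degenerate alignment: no gap-free columns")
  cnt$mismatches / cnt$aligned_cols
}

#' Pairwise p-distance matrix
#'
#' @param seqs character vector of DNA strings.
#' @param labels sequence labels (default `names(seqs)` or indices).
#' @param method `"pairwise"` (default): each pair aligned and scored
#'   with pairwise deletion; `"complete"`: all sequences star-aligned
#'   jointly, columns containing any gap discarded for every pair.
#' @return symmetric numeric matrix with zero diagonal and the labels as
#'   dimnames.
#' @export
p_distance_matrix <- function(seqs, labels = NULL,
                              method = c("pairwise", "complete")) {
  method <- match.arg(method)
  n <- length(seqs)
  if (is.null(labels)) labels <- if (!is.null(names(seqs))) names(seqs) else as.character(seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n < 2L) return(D)
  if (method == "pairwise") {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- pairwise_p_distance(seqs[[i]], seqs[[j]])
    return(D)
  }
  aln <- star_align(seqs)
  M <- do.call(rbind, strsplit(aln, ""))
  keep <- colSums(M == "-") == 0L
  M <- M[, keep, drop = FALSE]
  if (ncol(M) == 0L) stop("complete deletion removed every column")
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- mean(M[i, ] != M[j, ])
  D
}
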