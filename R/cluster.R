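# Greedy identity clustering, star alignment and majority-rule consensus.
#
# The clustering reproduces the documented behaviour of greedy identity
# clustering tools: sequences sorted longest-first (ties by id) and each
# assigned to the first existing cluster whose *representative* it
# matches at >= the identity threshold, else founding a new cluster.
# Identity uses the shorter-sequence denominator by default (the same
# tools' convention).

#' Greedy identity clustering
#'
#' @param reads non-empty sequence record frame.
#' @param threshold identity threshold in (0, 1] (default 0.97).
#' @param denominator identity denominator, see [pairwise_identity()].
#' @return object of class `rdna_clusters`: list of clusters, each a list
#'   with `representative` (one-row frame), `members` (frame, joining
#'   order, representative included) and `size`. Clusters partition the
#'   input. Deterministic given the input.
#' @export
greedy_cluster <- function(reads, threshold = 0.97,
                           denominator = c("shorter", "alignment")) {
  denominator <- match.arg(denominator)
  stopifnot(is.data.frame(reads), nrow(reads) > 0L)
  ord <- order(-nchar(reads$seq), reads$id, method = "radix")
  rs <- reads[ord, , drop = FALSE]
  # identical sequences share one identity outcome: process unique
  # sequences (first-appearance order) and fan assignments back out
  first <- !duplicated(rs$seq)
  ukey <- match(rs$seq, rs$seq[first])
  u_seqs <- rs$seq[first]
  reps <- character(0)
  assign_u <- integer(length(u_seqs))
  for (u in seq_along(u_seqs)) {
    s <- u_seqs[u]
    placed <- 0L
    for (ci in seq_along(reps)) {
      if (pairwise_identity(reps[ci], s, denominator) >= threshold) {
        placed <- ci; break
      }
    }
    if (!placed) { reps <- c(reps, s); placed <- length(reps) }
    assign_u[u] <- placed
  }
  cl_of_row <- assign_u[ukey]
  clusters <- lapply(seq_along(reps), function(ci) {
    mem <- rs[cl_of_row == ci, , drop = FALSE]
    rep_row <- mem[match(reps[ci], mem$seq), , drop = FALSE]
    list(representative = rep_row, members = mem, size = nrow(mem))
  })
  structure(clusters, class = "rdna_clusters")
}

#' @export
print.rdna_clusters <- function(x, ...) {
  sizes <- vapply(x, `[[`, integer(1), "size")
  cat(length(x), "clusters;", sum(sizes), "reads; sizes:",
      paste(sort(sizes, decreasing = TRUE), collapse = ", "), "\n")
  invisible(x)
}

# Star alignment: every sequence aligned pairwise to the reference;
# columns merged on reference coordinates with member-specific
# insertions stacked (padded with gaps). Rows come back equal length,
# in input order, with attribute "ref" = reference index.
star_align <- function(seqs, ref = 1L) {
  seqs <- as.character(seqs)
  n <- length(seqs)
  refseq <- seqs[[ref]]
  Lr <- nchar(refseq)
  mem_chars <- vector("list", n)
  mem_ins <- vector("list", n)
  ins_len <- integer(Lr + 1L)  # slot i+1: insertion after ref position i (0..Lr)
  ref_chars <- strsplit(refseq, "")[[1]]
  for (k in seq_len(n)) {
    if (seqs[[k]] == refseq) {
      mem_chars[[k]] <- ref_chars
      mem_ins[[k]] <- list()
      next
    }
    al <- nw_align_cpp(refseq, seqs[[k]])
    ra <- strsplit(al$aligned_a, "")[[1]]
    rb <- strsplit(al$aligned_b, "")[[1]]
    mask <- ra != "-"
    chars <- rb[mask]
    ins <- list()
    if (any(!mask)) {
      pos_at <- cumsum(mask)
      ins <- lapply(split(rb[!mask], pos_at[!mask]), paste, collapse = "")
    }
    mem_chars[[k]] <- chars
    mem_ins[[k]] <- ins
    for (key in names(ins)) {
      i <- as.integer(key)
      ins_len[i + 1L] <- max(ins_len[i + 1L], nchar(ins[[key]]))
    }
  }
  ins_pos <- which(ins_len > 0L)  # slots needing an insertion block
  rows <- vapply(seq_len(n), function(k) {
    chars <- mem_chars[[k]]
    if (!length(ins_pos)) return(paste(chars, collapse = ""))
    ins <- mem_ins[[k]]
    pieces <- character(2L * length(ins_pos) + 1L)
    prev <- 0L  # last ref position emitted
    pi <- 1L
    for (slot in ins_pos) {
      at <- slot - 1L  # insertion after ref position `at`
      pieces[pi] <- paste(chars[seq_len(at - prev) + prev], collapse = "")
      s <- ins[[as.character(at)]]
      if (is.null(s)) s <- ""
      pieces[pi + 1L] <- paste0(s, strrep("-", ins_len[slot] - nchar(s)))
      prev <- at
      pi <- pi + 2L
    }
    pieces[pi] <- if (prev < Lr) paste(chars[(prev + 1L):Lr], collapse = "") else ""
    paste(pieces, collapse = "")
  }, character(1))
  attr(rows, "ref") <- ref
  rows
}

#' Align the members of a cluster
#'
#' Star alignment of all member reads against the cluster representative:
#' members are aligned pairwise to the representative and merged on its
#' coordinates, stacking member-specific insertions.
#'
#' @param cluster one cluster from [greedy_cluster()].
#' @return character vector of equal-length gapped rows, one per member
#'   (member order), with attribute `ref` giving the representative row.
#' @export
align_cluster <- function(cluster) {
  ref <- match(cluster$representative$id, cluster$members$id)
  star_align(cluster$members$seq, ref = ref)
}

#' Majority-rule consensus of aligned sequences
#'
#' Per column, the highest-scoring symbol over `{A, C, G, T, N, -}` wins
#' (optionally weighted); ties break toward the reference row's symbol,
#' then alphabetically. Columns whose winner is the gap are deleted; the
#' result is ungapped.
#'
#' @param aligned character vector of equal-length gapped rows.
#' @param weights optional per-row weights (default uniform).
#' @param ref reference row index for tie-breaking (defaults to the
#'   `ref` attribute set by [align_cluster()], else 1).
#' @return ungapped consensus DNA string.
#' @export
majority_consensus <- function(aligned, weights = NULL, ref = NULL) {
  if (!length(aligned)) stop("empty alignment")
  if (length(unique(nchar(aligned))) != 1L)
    stop("aligned rows must share one length")
  if (is.null(ref)) ref <- attr(aligned, "ref")
  if (is.null(ref)) ref <- 1L
  if (is.null(weights)) weights <- rep(1, length(aligned))
  M <- do.call(rbind, strsplit(aligned, ""))
  syms <- c("A", "C", "G", "T", "N", "-")
  score <- vapply(syms, function(s) colSums(weights * (M == s)),
                  numeric(ncol(M)))
  if (ncol(M) == 1L) score <- matrix(score, nrow = 1L,
                                     dimnames = list(NULL, syms))
  refrow <- M[ref, ]
  out <- vapply(seq_len(ncol(M)), function(j) {
    sc <- score[j, ]
    top <- syms[sc == max(sc)]
    if (refrow[j] %in% top) refrow[j] else top[1L]
  }, character(1))
  paste(out[out != "-"], collapse = "")
}

#' Cluster reads and call one consensus per cluster
#'
#' Runs [greedy_cluster()], star-aligns each cluster and calls a
#' majority-rule consensus. Consensus ids follow the `<sample>-C<k>`
#' convention with clusters numbered by decreasing size (ties keep
#' formation order).
#'
#' @param reads non-empty sequence record frame.
#' @param sample sample name used in consensus ids.
#' @param region region label (`"ITS"` or `"LSU"`).
#' @param threshold,denominator see [greedy_cluster()].
#' @return list with `consensus` (frame: `id`, `seq`, `n_reads`,
#'   `region`, `sample`), `assignments` (frame: `read_id`,
#'   `consensus_id`) and `clusters` (size-ordered `rdna_clusters`).
#' @export
cluster_consensus <- function(reads, sample = "S", region = "ITS",
                              threshold = 0.97,
                              denominator = c("shorter", "alignment")) {
  denominator <- match.arg(denominator)
  cl <- greedy_cluster(reads, threshold, denominator)
  sizes <- vapply(cl, `[[`, integer(1), "size")
  ord <- order(-sizes, method = "radix")
  cl <- structure(cl[ord], class = "rdna_clusters")
  cons <- vapply(cl, function(cc) majority_consensus(align_cluster(cc)),
                 character(1))
  ids <- paste0(sample, "-C", seq_along(cl))
  assignments <- data.frame(
    read_id = unlist(lapply(cl, function(cc) cc$members$id)),
    consensus_id = rep(ids, vapply(cl, `[[`, integer(1), "size")),
    stringsAsFactors = FALSE)
  list(consensus = data.frame(id = ids, seq = cons,
                              n_reads = vapply(cl, `[[`, integer(1), "size"),
                              region = region, sample = sample,
                              stringsAsFactors = FALSE),
       assignments = assignments,
       clusters = cl)
}

#' Select the major (most-read) consensus
#'
#' The cluster consensus with the most reads corresponds to the major
#' rDNA variant within the genome and is the recommended basis for
#' species identification. Ties break toward the lowest cluster index.
#'
#' @param consensus consensus frame from [cluster_consensus()] (ordered
#'   by cluster index).
#' @return the selected one-row frame.
#' @export
select_major <- function(consensus) {
  if (is.null(consensus) || nrow(consensus) == 0L)
    stop("no consensus records to select from")
  consensus[which.max(consensus$n_reads), , drop = FALSE]
}
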