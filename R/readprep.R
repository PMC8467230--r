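# CCS-level quality filtering, dual-barcode demultiplexing and length
# filtering. Each filter partitions its input: kept plus discarded always
# equals the number of reads in.

#' CCS quality filter
#'
#' Keeps reads with at least `min_subreads` subreads and predicted read
#' quality at least `min_rq` (both inclusive). Reads lacking either
#' metadata field fail the filter.
#'
#' @param reads sequence record frame with `np` and `rq` columns.
#' @param min_subreads,min_rq inclusive thresholds.
#' @return list with `kept` and `discarded` record frames.
#' @export
ccs_filter <- function(reads, min_subreads = 5L, min_rq = 0.99) {
  if (nrow(reads) == 0L) return(list(kept = reads, discarded = reads))
  ok <- !is.na(reads$np) & !is.na(reads$rq) &
    reads$np >= min_subreads & reads$rq >= min_rq
  list(kept = reads[ok, , drop = FALSE],
       discarded = reads[!ok, , drop = FALSE])
}

#' Length filter
#'
#' @param reads sequence record frame.
#' @param min_len,max_len inclusive length bounds in bp.
#' @return list with `kept` and `discarded` record frames.
#' @export
length_filter <- function(reads, min_len = 1000L, max_len = 2000L) {
  if (nrow(reads) == 0L) return(list(kept = reads, discarded = reads))
  len <- nchar(reads$seq)
  ok <- len >= min_len & len <= max_len
  list(kept = reads[ok, , drop = FALSE],
       discarded = reads[!ok, , drop = FALSE])
}

#' Match a barcode against a read end
#'
#' Hamming comparison (no indels) of the barcode against the terminal
#' window of its own length: the 5' prefix (`end = "5p"`) or 3' suffix
#' (`end = "3p"`) of the read.
#'
#' @param seq read sequence.
#' @param barcode barcode sequence (shorter than `seq`).
#' @param max_mm maximum mismatches allowed (inclusive).
#' @param end which read end to compare.
#' @return list with `match` (logical) and `mismatches` (integer; `NA`
#'   when the read is shorter than the barcode).
#' @export
match_barcode <- function(seq, barcode, max_mm = 3L, end = c("5p", "3p")) {
  end <- match.arg(end)
  lb <- nchar(barcode)
  if (nchar(seq) < lb) return(list(match = FALSE, mismatches = NA_integer_))
  win <- if (end == "5p") substr(seq, 1L, lb)
         else substr(seq, nchar(seq) - lb + 1L, nchar(seq))
  mm <- sum(utf8ToInt(win) != utf8ToInt(barcode))
  list(match = mm <= max_mm, mismatches = mm)
}

#' Demultiplex reads by dual terminal barcodes
#'
#' A read in forward orientation is `fwd_barcode + insert +
#' reverse_complement(rev_barcode)`. Both orientations of every read are
#' tested against every sample's pair; a pair matches when the forward
#' barcode fits the 5' end and the reverse complement of the reverse
#' barcode fits the 3' end, each within `max_mm` Hamming mismatches
#' (budget applied per barcode, not summed). A read is assigned iff
#' exactly one (sample, orientation) combination matches; reads matching
#' several are conservatively discarded as ambiguous. Assigned reads are
#' orientation-normalised and barcode-trimmed.
#'
#' @param reads sequence record frame.
#' @param barcode_map data.frame with columns `sample`, `fwd_barcode`,
#'   `rev_barcode` (see [read_barcode_map()]).
#' @param max_mm per-barcode mismatch budget.
#' @return list with `assigned` (record frame with a `sample` column) and
#'   `discards`, a list of record frames `unassigned` and `ambiguous`.
#' @export
demultiplex <- function(reads, barcode_map, max_mm = 3L) {
  bm <- .check_barcode_map(barcode_map)
  if (nrow(bm) == 0L) stop("barcode map is empty")
  lf <- nchar(bm$fwd_barcode); lr <- nchar(bm$rev_barcode)
  if (length(unique(lf)) > 1L || length(unique(lr)) > 1L)
    stop("all forward (and all reverse) barcodes must share one length")
  lf <- lf[1L]; lr <- lr[1L]
  Fm <- do.call(rbind, lapply(bm$fwd_barcode, utf8ToInt))
  Rm <- do.call(rbind, lapply(reverse_complement(bm$rev_barcode), utf8ToInt))

  n <- nrow(reads)
  asg <- reads[0, , drop = FALSE]; asg$sample <- character(0)
  if (n == 0L)
    return(list(assigned = asg,
                discards = list(unassigned = reads, ambiguous = reads)))

  sample_hit <- rep(NA_character_, n)
  norm_seq <- rep(NA_character_, n)
  n_hits <- integer(n)
  for (i in seq_len(n)) {
    s_fwd <- reads$seq[i]
    if (nchar(s_fwd) < lf + lr + 1L) next
    for (orient in 1:2) {
      s <- if (orient == 1L) s_fwd else reverse_complement(s_fwd)
      p <- utf8ToInt(substr(s, 1L, lf))
      q <- utf8ToInt(substr(s, nchar(s) - lr + 1L, nchar(s)))
      mmF <- rowSums(Fm != matrix(p, nrow(Fm), lf, byrow = TRUE))
      mmR <- rowSums(Rm != matrix(q, nrow(Rm), lr, byrow = TRUE))
      hit <- which(mmF <= max_mm & mmR <= max_mm)
      if (length(hit)) {
        n_hits[i] <- n_hits[i] + length(hit)
        sample_hit[i] <- bm$sample[hit[1L]]
        norm_seq[i] <- substr(s, lf + 1L, nchar(s) - lr)
      }
    }
  }
  ok <- n_hits == 1L
  asg <- reads[ok, , drop = FALSE]
  asg$seq <- norm_seq[ok]
  asg$sample <- sample_hit[ok]
  list(assigned = asg,
       discards = list(unassigned = reads[n_hits == 0L, , drop = FALSE],
                       ambiguous = reads[n_hits > 1L, , drop = FALSE]))
}
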