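# Cleaving full-length amplicons into the ITS and D1-D2 LSU barcodes at
# the ITS4 priming site. ITS4 primes the reverse strand, so the site
# searched on the forward strand is the primer's reverse complement. The
# matched window itself is removed from both parts (it is invariant by
# construction and carries no signal). Coordinates are 0-based half-open.

#' Locate the ITS4 priming site on the forward strand
#'
#' Scans every offset for the primer's binding site (the reverse
#' complement of `primer`) and returns the minimum-mismatch position,
#' ties broken leftmost.
#'
#' @param seq forward-strand DNA string.
#' @param primer primer sequence (e.g. ITS4, `TCCTCCGCTTATTGATATGC`).
#' @param max_mm maximum Hamming mismatches at the best site.
#' @return list with 0-based half-open `start`, `end` and `mismatches`,
#'   or `NULL` when no site is within `max_mm`.
#' @export
locate_primer <- function(seq, primer = "TCCTCCGCTTATTGATATGC", max_mm = 3L) {
  site <- reverse_complement(toupper(primer))
  mm <- hamming_scan_cpp(seq, site)
  if (!length(mm)) return(NULL)
  best <- which.min(mm)
  if (mm[best] > max_mm) return(NULL)
  list(start = best - 1L, end = best - 1L + nchar(site),
       mismatches = mm[best])
}

#' Split an amplicon into ITS and LSU parts
#'
#' Cuts an orientation-normalised amplicon at the ITS4 priming site:
#' `its_part` is everything before the site, `lsu_part` everything after
#' it; the matched window is excluded from both. Either part may be an
#' empty string (site at a read end); callers discard those per region.
#'
#' @param seq forward-strand amplicon sequence (a string, or a one-row
#'   sequence record frame).
#' @param primer,max_mm see [locate_primer()].
#' @return list with `its_part`, `lsu_part`, `site_start`, `site_end`,
#'   `mismatches`, or `NULL` when no site is found.
#' @export
split_amplicon <- function(seq, primer = "TCCTCCGCTTATTGATATGC", max_mm = 3L) {
  if (is.data.frame(seq)) seq <- seq$seq[1L]
  hit <- locate_primer(seq, primer, max_mm)
  if (is.null(hit)) return(NULL)
  list(its_part = substr(seq, 1L, hit$start),
       lsu_part = substr(seq, hit$end + 1L, nchar(seq)),
       site_start = hit$start, site_end = hit$end,
       mismatches = hit$mismatches)
}
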