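# Sequence record I/O and pipeline configuration.
#
# Reads travel as plain data.frames ("sequence record frames") with columns
#   id      unique identifier (first whitespace-separated header token)
#   seq     uppercase IUPAC DNA string
#   np      number of CCS subreads (NA when absent)
#   rq      predicted read quality in [0,1] (NA when absent)
# Per-read CCS metadata is carried in FASTA/FASTQ headers as
# "np=<int> rq=<float>" tokens, mirroring PacBio header conventions.

#' Construct a sequence record frame
#'
#' @param id character vector of unique ids.
#' @param seq character vector of DNA sequences (uppercased on input).
#' @param np integer vector of subread counts, or `NA`.
#' @param rq numeric vector of read qualities in `[0, 1]`, or `NA`.
#' @param sample optional character vector of sample assignments.
#' @return data.frame with columns `id`, `seq`, `np`, `rq` (and `sample`
#'   when supplied).
#' @export
seq_records <- function(id, seq, np = NA_integer_, rq = NA_real_,
                        sample = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (anyDuplicated(id)) stop("sequence ids must be unique")
  if (length(seq) && any(!nzchar(seq))) stop("empty sequence for id ", id[!nzchar(seq)][1])
  bad <- grepl("[^ACGTN-]", seq)
  if (any(bad)) stop("non-IUPAC characters in sequence ", id[bad][1])
  rq <- as.numeric(rq)
  if (any(!is.na(rq) & (rq < 0 | rq > 1))) stop("read quality must lie in [0, 1]")
  n <- length(id)
  df <- data.frame(id = id, seq = seq,
                   np = rep_len(as.integer(np), n),
                   rq = rep_len(rq, n),
                   stringsAsFactors = FALSE)
  if (!is.null(sample)) df$sample <- as.character(sample)
  df
}

.guess_format <- function(path) {
  if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) return("fastq")
  if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) return("fasta")
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character())
  if (length(first) && startsWith(first, "@")) "fastq" else "fasta"
}

.parse_header_token <- function(headers, key) {
  m <- regmatches(headers, regexpr(paste0("\\b", key, "=[^[:space:]]+"), headers))
  out <- rep(NA_character_, length(headers))
  hit <- grepl(paste0("\\b", key, "="), headers)
  out[hit] <- sub(paste0("^", key, "="), "", m)
  out
}

#' Read sequences from FASTA or FASTQ
#'
#' Headers may carry per-read CCS metadata as `np=<int> rq=<float>`
#' tokens; these populate the `np` and `rq` columns. FASTQ per-base
#' qualities are not used (the single `rq` scalar is the quality model).
#'
#' @param path input file.
#' @param format `"auto"` (default, by extension then content), `"fasta"`
#'   or `"fastq"`.
#' @return sequence record frame (see [seq_records()]); empty files yield
#'   a zero-row frame.
#' @export
read_fastx <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .guess_format(path)
  if (file.size(path) == 0)
    return(seq_records(character(), character()))
  x <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop("failed to parse ", path, " as ", format,
                             ": ", conditionMessage(e), call. = FALSE))
  headers <- names(x)
  if (is.null(headers)) headers <- rep("", length(x))
  ids <- sub("[[:space:]].*$", "", headers)
  np <- suppressWarnings(as.integer(.parse_header_token(headers, "np")))
  rq <- suppressWarnings(as.numeric(.parse_header_token(headers, "rq")))
  smp <- .parse_header_token(headers, "sample")
  out <- seq_records(ids, as.character(x), np = np, rq = rq)
  if (any(!is.na(smp))) out$sample <- smp
  out
}

.format_header <- function(records) {
  h <- records$id
  add <- function(h, key, val) {
    has <- !is.na(val)
    h[has] <- paste0(h[has], " ", key, "=", val[has])
    h
  }
  if (!is.null(records$np)) h <- add(h, "np", records$np)
  if (!is.null(records$rq)) h <- add(h, "rq", format(records$rq, trim = TRUE, digits = 6))
  if (!is.null(records$sample)) h <- add(h, "sample", records$sample)
  h
}

#' Write sequences to FASTA or FASTQ
#'
#' Metadata columns (`np`, `rq`, `sample`) are emitted as `key=value`
#' header tokens so that [read_fastx()] round-trips them. For FASTQ a
#' flat per-base quality string is derived from `rq` (Phred-scaled,
#' capped at Q93); `rq` itself still travels in the header.
#'
#' @param records sequence record frame.
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_fastx <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::BStringSet(records$seq)
  names(x) <- .format_header(records)
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path, format = "fasta", width = 80L)
  } else {
    rq <- if (is.null(records$rq)) rep(NA_real_, nrow(records)) else records$rq
    q <- ifelse(is.na(rq), 40L,
                pmin(93L, as.integer(round(-10 * log10(pmax(1 - rq, 1e-10))))))
    qual <- Biostrings::BStringSet(vapply(seq_len(nrow(records)), function(i) {
      strrep(rawToChar(as.raw(q[i] + 33L)), nchar(records$seq[i]))
    }, character(1)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  }
  invisible(path)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of IUPAC DNA strings.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  if (!length(x)) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Pipeline configuration
#'
#' Bundles the tunable thresholds of the amplicon pipeline. Defaults
#' follow the protocol the pipeline models: CCS reads require at least
#' five subreads and predicted quality >= 0.99; sample barcodes tolerate
#' at most three mismatches; only amplicons of 1000--2000 bp are kept;
#' clustering uses 97% identity; the haplotype network tolerance epsilon
#' is 0; region cleaving is anchored on the ITS4 priming site.
#'
#' @param min_subreads minimum CCS subread count (inclusive).
#' @param min_read_quality minimum predicted read quality (inclusive).
#' @param max_barcode_mismatches per-barcode Hamming mismatch budget.
#' @param min_len,max_len inclusive amplicon length bounds in bp.
#' @param cluster_identity greedy clustering identity threshold in (0, 1].
#' @param epsilon non-negative integer tolerance for the haplotype network.
#' @param primer_its4 ITS4 primer sequence (its reverse complement is the
#'   binding site searched on the forward strand).
#' @param max_primer_mismatches mismatch budget for the primer site.
#' @param identity_denominator `"shorter"` (default; matches the greedy
#'   clustering tool's convention) or `"alignment"`.
#' @param rng_seed integer seed used by pipeline stages that randomise.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_subreads = 5L, min_read_quality = 0.99,
                            max_barcode_mismatches = 3L,
                            min_len = 1000L, max_len = 2000L,
                            cluster_identity = 0.97, epsilon = 0L,
                            primer_its4 = "TCCTCCGCTTATTGATATGC",
                            max_primer_mismatches = 3L,
                            identity_denominator = c("shorter", "alignment"),
                            rng_seed = 1L) {
  identity_denominator <- match.arg(identity_denominator)
  stopifnot(cluster_identity > 0, cluster_identity <= 1,
            min_len < max_len, min_subreads >= 0, epsilon >= 0,
            max_barcode_mismatches >= 0, max_primer_mismatches >= 0,
            min_read_quality >= 0, min_read_quality <= 1)
  structure(list(
    min_subreads = as.integer(min_subreads),
    min_read_quality = min_read_quality,
    max_barcode_mismatches = as.integer(max_barcode_mismatches),
    min_len = as.integer(min_len), max_len = as.integer(max_len),
    cluster_identity = cluster_identity, epsilon = as.integer(epsilon),
    primer_its4 = toupper(primer_its4),
    max_primer_mismatches = as.integer(max_primer_mismatches),
    identity_denominator = identity_denominator,
    rng_seed = as.integer(rng_seed)
  ), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Amplicon pipeline configuration\n")
  cat(sprintf("  CCS filter      : np >= %d, rq >= %g\n", x$min_subreads, x$min_read_quality))
  cat(sprintf("  demultiplexing  : <= %d mismatches per barcode\n", x$max_barcode_mismatches))
  cat(sprintf("  length filter   : [%d, %d] bp\n", x$min_len, x$max_len))
  cat(sprintf("  primer (ITS4)   : %s (<= %d mismatches)\n", x$primer_its4, x$max_primer_mismatches))
  cat(sprintf("  clustering      : %.0f%% identity (%s denominator)\n",
              100 * x$cluster_identity, x$identity_denominator))
  cat(sprintf("  network epsilon : %d\n", x$epsilon))
  invisible(x)
}

#' Read a barcode map
#'
#' @param path TSV with header columns `sample`, `fwd_barcode`,
#'   `rev_barcode` and optionally `species`.
#' @return data.frame; barcode pairs are checked for uniqueness.
#' @export
read_barcode_map <- function(path) {
  bm <- read.delim(path, stringsAsFactors = FALSE)
  .check_barcode_map(bm)
}

.check_barcode_map <- function(bm) {
  need <- c("sample", "fwd_barcode", "rev_barcode")
  if (!all(need %in% names(bm)))
    stop("barcode map needs columns: ", paste(need, collapse = ", "))
  bm$fwd_barcode <- toupper(bm$fwd_barcode)
  bm$rev_barcode <- toupper(bm$rev_barcode)
  if (any(!nzchar(bm$fwd_barcode)) || any(!nzchar(bm$rev_barcode)))
    stop("barcodes must be non-empty")
  if (anyDuplicated(paste(bm$fwd_barcode, bm$rev_barcode)))
    stop("duplicated (fwd, rev) barcode combination in map")
  if (anyDuplicated(bm$sample)) stop("duplicated sample in barcode map")
  bm
}

# deterministic TSV writer (fixed numeric formatting, no quoting)
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), "-", formatC(v, digits = 6, format = "g")))
  df[] <- lapply(df, function(v) ifelse(is.na(v), "-", as.character(v)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
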