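test_that("CCS filter boundaries are inclusive and missing metadata fails", {
  reads <- seq_records(paste0("r", 1:5), rep("ACGT", 5),
                       np = c(5L, 4L, 5L, 100L, NA),
                       rq = c(0.99, 0.999, 0.9899, 0.99, 0.999))
  out <- ccs_filter(reads, 5L, 0.99)
  expect_setequal(out$kept$id, c("r1", "r4"))
  expect_setequal(out$discarded$id, c("r2", "r3", "r5"))
  empty <- ccs_filter(reads[0, ], 5L, 0.99)
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(nrow(empty$discarded), 0L)
})

test_that("length filter keeps the inclusive 1000-2000 bp window", {
  lens <- c(999L, 1000L, 1500L, 2000L, 2001L)
  reads <- seq_records(paste0("r", lens), vapply(lens, rand_dna, character(1)))
  out <- length_filter(reads, 1000L, 2000L)
  expect_setequal(out$kept$id, c("r1000", "r1500", "r2000"))
  expect_setequal(out$discarded$id, c("r999", "r2001"))
})

test_that("barcode matching is Hamming over the terminal window", {
  set.seed(31)
  bc <- rand_dna(16)
  insert <- rand_dna(100)
  seq5 <- paste0(bc, insert)
  expect_equal(match_barcode(seq5, bc, 3L), list(match = TRUE, mismatches = 0L))
  flip <- function(b, k) {
    ch <- strsplit(b, "")[[1]]
    ch[seq_len(k)] <- chartr("ACGT", "TGCA", ch[seq_len(k)])
    paste(ch, collapse = "")
  }
  expect_true(match_barcode(paste0(flip(bc, 3), insert), bc, 3L)$match)
  expect_false(match_barcode(paste0(flip(bc, 4), insert), bc, 3L)$match)
  # 3' end compares the suffix
  seq3 <- paste0(insert, bc)
  expect_true(match_barcode(seq3, bc, 0L, end = "3p")$match)
  expect_false(match_barcode("ACG", bc, 3L)$match)
})

make_demux_fixture <- function(n_samples = 4, n_reads = 60, err_per_bc = 0,
                               seed = 17) {
  set.seed(seed)
  bm <- make_barcodes(paste0("S", seq_len(n_samples)))
  truth <- sample(bm$sample, n_reads, replace = TRUE)
  corrupt <- function(b, k) {
    if (k == 0) return(b)
    ch <- strsplit(b, "")[[1]]
    pos <- sample(seq_along(ch), k)
    ch[pos] <- vapply(ch[pos], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    paste(ch, collapse = "")
  }
  seqs <- vapply(truth, function(s) {
    row <- bm[bm$sample == s, ]
    tagged <- paste0(corrupt(row$fwd_barcode, err_per_bc), rand_dna(120),
                     reverse_complement(corrupt(row$rev_barcode, err_per_bc)))
    if (runif(1) < 0.5) reverse_complement(tagged) else tagged
  }, character(1))
  list(reads = seq_records(sprintf("r%03d", seq_len(n_reads)), seqs),
       truth = truth, bm = bm)
}

test_that("demultiplexing assigns, trims and orientation-normalises", {
  fx <- make_demux_fixture()
  out <- demultiplex(fx$reads, fx$bm)
  expect_equal(nrow(out$assigned), length(fx$truth))
  expect_equal(out$assigned$sample,
               fx$truth[match(out$assigned$id, fx$reads$id)])
  expect_true(all(nchar(out$assigned$seq) == 120L))
})

test_that("demultiplexing tolerates up to 3 errors per barcode, not 4", {
  fx3 <- make_demux_fixture(err_per_bc = 3, seed = 23)
  out3 <- demultiplex(fx3$reads, fx3$bm)
  expect_equal(out3$assigned$sample,
               fx3$truth[match(out3$assigned$id, fx3$reads$id)])
  expect_equal(nrow(out3$discards$unassigned), 0L)
  fx4 <- make_demux_fixture(err_per_bc = 4, seed = 23)
  out4 <- demultiplex(fx4$reads, fx4$bm)
  expect_equal(nrow(out4$assigned), 0L)
  expect_equal(nrow(out4$discards$unassigned), nrow(fx4$reads))
})

test_that("demultiplexing is orientation-invariant and partitions input", {
  fx <- make_demux_fixture(seed = 29)
  out <- demultiplex(fx$reads, fx$bm)
  flipped <- fx$reads
  flipped$seq <- reverse_complement(flipped$seq)
  out2 <- demultiplex(flipped, fx$bm)
  a <- out$assigned[order(out$assigned$id), c("id", "sample", "seq")]
  b <- out2$assigned[order(out2$assigned$id), c("id", "sample", "seq")]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
  expect_equal(nrow(out$assigned) + nrow(out$discards$unassigned) +
                 nrow(out$discards$ambiguous), nrow(fx$reads))
})

test_that("reads matching several samples are discarded as ambiguous", {
  set.seed(41)
  f1 <- rand_dna(16); r1 <- rand_dna(16); r2 <- rand_dna(16)
  bm <- data.frame(sample = c("A", "B"),
                   fwd_barcode = c(f1, f1),
                   rev_barcode = c(r1, r1),
                   stringsAsFactors = FALSE)
  bm$rev_barcode[2] <- {  # within 2 mismatches of r1: both samples match
    ch <- strsplit(r1, "")[[1]]
    ch[1:2] <- chartr("ACGT", "TGCA", ch[1:2])
    paste(ch, collapse = "")
  }
  read <- seq_records("x", paste0(f1, rand_dna(100), reverse_complement(r1)))
  out <- demultiplex(read, bm, max_mm = 3L)
  expect_equal(nrow(out$assigned), 0L)
  expect_equal(out$discards$ambiguous$id, "x")
})
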