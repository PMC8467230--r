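test_that("identity matches its definition on constructed cases", {
  set.seed(61)
  a <- rand_dna(100)
  expect_equal(pairwise_identity(a, a), 1)
  b <- a
  for (p in c(10, 50, 90)) substr(b, p, p) <- chartr("ACGT", "TGCA", substr(b, p, p))
  expect_equal(pairwise_identity(a, b), 0.97)
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
})

test_that("identity and p-distance agree with the DP oracle on random pairs", {
  set.seed(62)
  for (i in 1:60) {
    a <- rand_dna(sample(5:30, 1))
    b <- if (i %% 3 == 0) rand_dna(sample(5:30, 1)) else
      mutate_haplotype(a, runif(1, 0, 0.2))
    expect_equal(pairwise_identity(a, b), oracle_identity(a, b))
    expect_equal(pairwise_p_distance(a, b), oracle_p_distance(a, b))
  }
})

test_that("greedy clustering separates variants beyond the identity radius", {
  set.seed(63)
  major <- rand_dna(400)
  ten <- seq_records(sprintf("r%02d", 1:10), rep(major, 10))
  cl <- greedy_cluster(ten, 0.97)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$size, 10L)

  minor <- mutate_haplotype(major, 0.05, seed = 1)
  reads <- seq_records(sprintf("r%02d", 1:13),
                       c(rep(major, 8), rep(minor, 5)))
  cl2 <- greedy_cluster(reads, 0.97)
  expect_length(cl2, 2L)
  expect_setequal(vapply(cl2, `[[`, integer(1), "size"), c(8L, 5L))

  near <- mutate_haplotype(major, 0.01, seed = 2)
  cl3 <- greedy_cluster(seq_records(c("a", "b"), c(major, near)), 0.97)
  expect_length(cl3, 1L)
})

test_that("clusters partition the input and shrink monotonically in threshold", {
  set.seed(64)
  base <- rand_dna(200)
  reads <- seq_records(sprintf("r%02d", 1:30),
                       vapply(runif(30, 0, 0.15), function(d)
                         mutate_haplotype(base, d), character(1)))
  prev <- Inf
  for (th in c(0.99, 0.97, 0.93, 0.88)) {
    cl <- greedy_cluster(reads, th)
    expect_equal(sum(vapply(cl, `[[`, integer(1), "size")), 30L)
    expect_setequal(unlist(lapply(cl, function(c) c$members$id)), reads$id)
    expect_lte(length(cl), prev)
    prev <- length(cl)
  }
})

test_that("star alignment handles singletons, identity and indels", {
  one <- greedy_cluster(seq_records("a", "ACGTACGT"))
  expect_equal(align_cluster(one[[1]]), "ACGTACGT", ignore_attr = TRUE)

  same <- greedy_cluster(seq_records(c("a", "b", "c"), rep("ACGTACGTAC", 3)))
  aln <- align_cluster(same[[1]])
  expect_true(all(aln == "ACGTACGTAC"))

  # one member with a single deletion: exactly one gap, in that row only
  rep_seq <- "ACGTACGTACGT"
  del <- paste0(substr(rep_seq, 1, 5), substr(rep_seq, 7, 12))
  cl <- list(representative = seq_records("a", rep_seq),
             members = seq_records(c("a", "b"), c(rep_seq, del)),
             size = 2L)
  aln2 <- align_cluster(cl)
  expect_equal(nchar(aln2[1]), nchar(aln2[2]))
  expect_equal(lengths(regmatches(aln2, gregexpr("-", aln2))), c(0L, 1L))
  # the member row must agree with the pairwise alignment oracle
  o <- oracle_nw(rep_seq, del)
  expect_equal(sum(strsplit(aln2[1], "")[[1]] ==
                     strsplit(aln2[2], "")[[1]]), o$matches)
})

test_that("majority consensus follows the majority and breaks ties to the representative", {
  expect_equal(majority_consensus(c("ACGT", "ACGT", "ACGT")), "ACGT")
  expect_equal(majority_consensus(c("ACGT", "ACGT", "AGGT")), "ACGT")
  # two rows, one differing column: tie resolved toward the reference row
  expect_equal(majority_consensus(c("ACGT", "AGGT"), ref = 1L), "ACGT")
  expect_equal(majority_consensus(c("ACGT", "AGGT"), ref = 2L), "AGGT")
  # gap-majority columns are deleted
  expect_equal(majority_consensus(c("AC-T", "AC-T", "ACGT"), ref = 3L), "ACT")
  expect_error(majority_consensus(character(0)), "empty")
})

test_that("the major variant is the most-read consensus, ties to lowest index", {
  cons <- data.frame(id = c("S-C1", "S-C2", "S-C3"),
                     seq = c("AA", "CC", "GG"),
                     n_reads = c(341L, 2L, 1L), stringsAsFactors = FALSE)
  expect_equal(select_major(cons)$id, "S-C1")
  cons2 <- cons; cons2$n_reads <- c(5L, 5L, 1L)
  expect_equal(select_major(cons2)$id, "S-C1")
  expect_equal(select_major(cons[2, ])$id, "S-C2")
  expect_error(select_major(cons[0, ]), "no consensus")
})

test_that("haplotype structure is recovered across seeded replicates", {
  # divergences >= 2x the clustering radius, CCS-like 0.3% error
  ok <- vapply(1:40, function(rep_seed) {
    set.seed(1000 + rep_seed)
    major <- rand_dna(400)
    strain <- list(strain_id = "S1",
                   haplotypes = c(major,
                                  mutate_haplotype(major, 0.06),
                                  mutate_haplotype(major, 0.09)))
    bc <- list(fwd_barcode = rand_dna(16), rev_barcode = rand_dna(16))
    sim <- simulate_strain_reads(strain, n_dominant = 30,
                                 minor_counts = c(5, 3),
                                 error_rate = 0.003, barcodes = bc)
    cc <- cluster_consensus(seq_records(sim$truth$read_id, sim$truth$insert),
                            sample = "S1")
    length(cc$clusters) == 3L &&
      setequal(cc$consensus$n_reads, c(30L, 5L, 3L)) &&
      setequal(cc$consensus$seq, strain$haplotypes)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("consensus ids number clusters by decreasing size", {
  set.seed(65)
  major <- rand_dna(300)
  minor <- mutate_haplotype(major, 0.08)
  reads <- seq_records(sprintf("r%02d", 1:9), c(rep(minor, 2), rep(major, 7)))
  cc <- cluster_consensus(reads, sample = "MY01", region = "ITS")
  expect_equal(cc$consensus$id, c("MY01-C1", "MY01-C2"))
  expect_equal(cc$consensus$n_reads, c(7L, 2L))
  expect_equal(cc$consensus$seq[1], major)
})
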