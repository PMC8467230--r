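test_that("mutate_haplotype hits the substitution count exactly", {
  set.seed(42)
  base <- rand_dna(1000)
  expect_identical(mutate_haplotype(base, 0), base)
  mut <- mutate_haplotype(base, 0.05, seed = 1)
  expect_equal(sum(utf8ToInt(mut) != utf8ToInt(base)), 50L)
  # re-measured through the alignment route; the aligner may shave a
  # few mismatched columns into gaps, never the other way round
  p <- pairwise_p_distance(base, mut)
  expect_lte(p, 0.05)
  expect_gt(p, 0.045)
})

test_that("protected spans are never mutated", {
  set.seed(7)
  base <- rand_dna(400)
  span <- c(100L, 150L)  # 0-based half-open
  for (d in c(0.05, 0.15)) {
    mut <- mutate_haplotype(base, d, protected_spans = list(span))
    expect_identical(substr(mut, 101, 150), substr(base, 101, 150))
  }
  expect_error(mutate_haplotype("ACGTACGT", 0.2,
                                protected_spans = list(c(0L, 8L))),
               "incompatible")
})

test_that("species panels keep one invariant priming site per cassette", {
  site <- reverse_complement("TCCTCCGCTTATTGATATGC")
  p1 <- build_species_panel(1, seed = 3)
  expect_length(p1, 1)
  expect_equal(length(gregexpr(site, p1[[1]]$cassette, fixed = TRUE)[[1]]), 1L)
  p0 <- build_species_panel(2, seed = 3, interspecific_divergence = 0)
  expect_identical(p0[[1]]$cassette, p0[[2]]$cassette)
})

test_that("pairwise species divergence is about twice the ancestor distance", {
  panel <- build_species_panel(9, seed = 11, interspecific_divergence = 0.10)
  cas <- vapply(panel, `[[`, character(1), "cassette")
  for (i in 1:8) for (j in (i + 1):9) {
    # substitution distance of the equal-length cassettes: the process
    # puts ~2d(1-d) + d^2*2/3 differing sites between two species
    h <- mean(utf8ToInt(cas[i]) != utf8ToInt(cas[j]))
    expect_gt(h, 0.15)
    expect_lt(h, 0.25)
    # the alignment-based estimate can sit slightly below the site
    # count at this divergence (gap/mismatch trading), never above it
    p <- pairwise_p_distance(cas[i], cas[j])
    expect_lte(p, h)
    expect_gt(p, 0.12)
  }
})

test_that("error-free reads are the tagged haplotype up to orientation", {
  set.seed(5)
  strain <- list(strain_id = "S1", haplotypes = rand_dna(500))
  bc <- list(fwd_barcode = rand_dna(16), rev_barcode = rand_dna(16))
  sim <- simulate_strain_reads(strain, n_dominant = 10, error_rate = 0,
                               barcodes = bc, seed = 9)
  expected <- paste0(bc$fwd_barcode, strain$haplotypes,
                     reverse_complement(bc$rev_barcode))
  fwd <- sim$reads$seq == expected
  rev <- sim$reads$seq == reverse_complement(expected)
  expect_true(all(fwd | rev))
  expect_equal(sim$truth$orientation, ifelse(fwd, "fwd", "rev"))
})

test_that("read counts, subread depths and read quality follow the model", {
  set.seed(6)
  major <- rand_dna(500)
  strain <- list(strain_id = "S1",
                 haplotypes = c(major,
                                mutate_haplotype(major, 0.05),
                                mutate_haplotype(major, 0.08)))
  bc <- list(fwd_barcode = rand_dna(16), rev_barcode = rand_dna(16))
  sim <- simulate_strain_reads(strain, n_dominant = 200,
                               minor_counts = c(2, 1),
                               error_rate = 0.002, mean_subreads = 33,
                               barcodes = bc, seed = 10)
  expect_equal(nrow(sim$truth), 203L)
  expect_equal(as.vector(table(sim$truth$haplotype)), c(200L, 2L, 1L))
  expect_true(all(sim$reads$np >= 5L))
  expect_gt(mean(sim$reads$np), 30)
  expect_lt(mean(sim$reads$np), 36)
  expect_equal(sim$reads$rq, 1 - sim$truth$n_errors / 500)
  # mean realised error, re-measured through the alignment route
  p <- vapply(seq_len(200), function(i)
    pairwise_p_distance(sim$truth$insert[i], major), numeric(1))
  expect_gt(mean(p), 0.001)
  expect_lt(mean(p), 0.003)
  expect_error(simulate_strain_reads(strain, n_dominant = 0,
                                     minor_counts = c(0, 0), barcodes = bc),
               "zero reads")
})

test_that("generated barcode pools respect the minimum pairwise distance", {
  bm <- make_barcodes(paste0("s", 1:6), length = 16, min_dist = 8, seed = 2)
  pool <- c(bm$fwd_barcode, bm$rev_barcode)
  for (i in seq_along(pool)[-1]) for (j in seq_len(i - 1)) {
    expect_gte(sum(utf8ToInt(pool[i]) != utf8ToInt(pool[j])), 8)
  }
})

test_that("dataset truth accounts for every read exactly once", {
  sim <- simulate_dataset(n_species = 2, strains_per_species = 2, seed = 13,
                          its_len = 150, lsu_len = 200,
                          dominant_range = c(10L, 15L),
                          minor_range = c(1L, 3L), max_minors = 2L)
  expect_setequal(sim$reads$id, sim$truth$read_id)
  expect_false(anyDuplicated(sim$truth$read_id) > 0)
  counts <- table(sim$truth$strain, sim$truth$haplotype)
  for (sid in unique(sim$haplotypes$strain)) {
    ht <- sim$haplotypes[sim$haplotypes$strain == sid, ]
    expect_equal(as.vector(counts[sid, as.character(ht$haplotype)]),
                 as.integer(ht$n_reads))
  }
})

test_that("written simulations reload consistently", {
  sim <- simulate_dataset(n_species = 2, strains_per_species = 1, seed = 3,
                          its_len = 150, lsu_len = 200,
                          dominant_range = c(5L, 8L), max_minors = 1L)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  reads <- read_fastx(file.path(dir, "reads.fastq"))
  expect_equal(reads$seq, sim$reads$seq)
  expect_equal(reads$np, sim$reads$np)
  refs <- read_references(file.path(dir, "references.fasta"))
  expect_equal(nrow(refs), nrow(sim$references))
  expect_equal(sort(unique(refs$region)), c("ITS", "LSU"))
})
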