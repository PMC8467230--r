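make_ref_panel <- function(seed = 91, n_species = 3, len = 150,
                           divergence = 0.1) {
  set.seed(seed)
  anc_its <- rand_dna(len); anc_lsu <- rand_dna(len)
  refs <- do.call(rbind, lapply(seq_len(n_species), function(i) {
    data.frame(id = paste0("REF", i, c("_ITS", "_LSU")),
               species = paste0("sp", i), region = c("ITS", "LSU"),
               strain = paste0("ST", i),
               seq = c(mutate_haplotype(anc_its, divergence),
                       mutate_haplotype(anc_lsu, divergence)),
               stringsAsFactors = FALSE)
  }))
  rownames(refs) <- NULL
  refs
}

test_that("a query identical to a reference is assigned there, concordant", {
  refs <- make_ref_panel()
  res <- classify(refs$seq[refs$region == "ITS"][2], refs, region = "ITS",
                  origin = "sp2")
  expect_equal(res$assigned, "sp2")
  expect_equal(res$distance, 0)
  expect_equal(res$flag, "concordant")
  expect_gt(res$margin, 0)
  expect_error(classify("ACGT", refs[0, ], "ITS"), "no references")
})

test_that("a variant closer to another species is flagged as outlier", {
  refs <- make_ref_panel(seed = 92)
  sp2 <- refs$seq[refs$species == "sp2" & refs$region == "ITS"]
  query <- mutate_haplotype(sp2, 0.02, seed = 5)  # 0.02 from sp2, ~0.2 elsewhere
  res <- classify(query, refs, region = "ITS", origin = "sp1")
  expect_equal(res$assigned, "sp2")
  expect_equal(res$flag, "outlier")
})

test_that("classification does not depend on reference order", {
  refs <- make_ref_panel(seed = 93)
  query <- mutate_haplotype(refs$seq[1], 0.03, seed = 6)
  a <- classify(query, refs, "ITS")
  b <- classify(query, refs[rev(seq_len(nrow(refs))), ], "ITS")
  expect_equal(a$assigned, b$assigned)
  expect_equal(a$distance, b$distance)
})

test_that("combined classification weights regions by their length", {
  set.seed(94)
  its_a <- rand_dna(100); lsu_a <- rand_dna(300)
  its_b <- mutate_haplotype(its_a, 0.2); lsu_b <- mutate_haplotype(lsu_a, 0.2)
  refs <- data.frame(
    id = c("A_I", "A_L", "B_I", "B_L"),
    species = c("spA", "spA", "spB", "spB"),
    region = c("ITS", "LSU", "ITS", "LSU"),
    strain = c("A", "A", "B", "B"),
    seq = c(its_a, lsu_a, its_b, lsu_b), stringsAsFactors = FALSE)
  # ITS favours A (distance 0), the 3x longer LSU favours B
  res <- classify_combined(its_a, lsu_b, refs, origin = "spA")
  expect_equal(res$assigned, "spB")
  d_its <- pairwise_p_distance(its_a, its_b)
  d_lsu <- pairwise_p_distance(lsu_a, lsu_b)
  dA <- (100 * 0 + 300 * d_lsu) / 400
  dB <- (100 * d_its + 300 * 0) / 400
  expect_equal(res$distance, dB)
  expect_equal(res$margin, dA - dB)
  expect_equal(res$flag, "outlier")

  both_a <- classify_combined(its_a, lsu_a, refs, origin = "spA")
  expect_equal(both_a$assigned, "spA")
  expect_equal(both_a$flag, "concordant")

  expect_warning(one <- classify_combined(its_a, NA, refs, origin = "spA"),
                 "falling back")
  expect_equal(one$assigned, "spA")
})

test_that("combined classification is at least as accurate as one region", {
  set.seed(95)
  refs <- make_ref_panel(seed = 95, len = 60)
  tally <- c(its = 0, lsu = 0, comb = 0)
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    sp <- sample(1:3, 1)
    its_ref <- refs$seq[refs$species == paste0("sp", sp) & refs$region == "ITS"]
    lsu_ref <- refs$seq[refs$species == paste0("sp", sp) & refs$region == "LSU"]
    q_its <- mutate_haplotype(its_ref, 0.1)
    q_lsu <- mutate_haplotype(lsu_ref, 0.1)
    origin <- paste0("sp", sp)
    tally["its"] <- tally["its"] +
      (classify(q_its, refs, "ITS", origin = origin)$flag == "concordant")
    tally["lsu"] <- tally["lsu"] +
      (classify(q_lsu, refs, "LSU", origin = origin)$flag == "concordant")
    tally["comb"] <- tally["comb"] +
      (classify_combined(q_its, q_lsu, refs, origin = origin)$flag == "concordant")
  }
  expect_gte(tally[["comb"]], tally[["its"]])
  expect_gte(tally[["comb"]], tally[["lsu"]])
})

test_that("neighbor joining recovers known topologies", {
  # additive distances from the unrooted tree ((A,B),(C,D))
  D <- matrix(c(0, 3, 3, 3,
                3, 0, 4, 4,
                3, 4, 0, 2,
                3, 4, 2, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  nwk <- nj_tree(D)
  tr <- ape::read.tree(text = nwk)
  ref <- ape::read.tree(text = "((A:1,B:2):1,C:1,D:1);")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref))[1], 0)

  three <- matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0), 3, 3,
                  dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  expect_match(nj_tree(three), "^\\(.*\\);$")
  expect_error(nj_tree(three[1:2, 1:2]), "at least 3")
})
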