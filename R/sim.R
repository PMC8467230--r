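# Synthetic tagged-amplicon generator.
#
# Emulates multi-copy rDNA amplicon sequencing at the CCS level: each
# species carries one base cassette (ITS region, an invariant ITS4
# priming site, then the D1-D2 LSU region); each strain holds a major
# haplotype plus minor variants at known p-distances; reads are the
# haplotype with i.i.d. substitution errors, flanked by dual barcodes,
# in random orientation, with subread-count and read-quality metadata.
# A truth table records every read's origin so downstream stages can be
# validated exactly.

ITS4_PRIMER <- "TCCTCCGCTTATTGATATGC"

.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

.substitute_bases <- function(chars, pos) {
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  for (p in pos) chars[p] <- sample(alt[[chars[p]]], 1L)
  chars
}

#' Mutate a haplotype to a target p-distance
#'
#' Substitution-only mutation: `round(target * L_free)` positions outside
#' the protected spans are substituted (uniformly to one of the three
#' alternative bases), where `L_free` is the number of unprotected
#' positions. The realised p-distance to `base` is that count divided by
#' the sequence length.
#'
#' @param base DNA string.
#' @param target_p_distance fraction in `[0, 0.2]`.
#' @param seed optional integer seed.
#' @param protected_spans list of 0-based half-open `c(start, end)`
#'   intervals that must not be touched (e.g. the primer site).
#' @return mutated DNA string.
#' @export
mutate_haplotype <- function(base, target_p_distance, seed = NULL,
                             protected_spans = list()) {
  stopifnot(target_p_distance >= 0, target_p_distance <= 0.2)
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(base, "")[[1]]
  free <- rep(TRUE, length(chars))
  for (sp in protected_spans) {
    if (sp[2L] > sp[1L]) free[(sp[1L] + 1L):sp[2L]] <- FALSE
  }
  if (target_p_distance > 0 && !any(free))
    stop("target divergence incompatible with protected spans")
  n_sub <- round(target_p_distance * sum(free))
  if (n_sub == 0L) return(base)
  pos <- sample(which(free), n_sub)
  paste(.substitute_bases(chars, pos), collapse = "")
}

#' Build a panel of species cassette models
#'
#' One random ancestral cassette (`ITS | ITS4 site | LSU`) is drawn and
#' each species receives an independently mutated copy at
#' `interspecific_divergence` from the ancestor, keeping the ITS4
#' priming site invariant; pairwise species p-distances are therefore
#' close to twice that value.
#'
#' @param n_species number of species (>= 1).
#' @param seed integer seed.
#' @param interspecific_divergence per-species p-distance from the
#'   shared ancestor.
#' @param its_len,lsu_len region lengths in bp.
#' @return list of species models: `name`, `cassette`, 0-based half-open
#'   `its_span`, `site_span`, `lsu_span`, `divergence`.
#' @export
build_species_panel <- function(n_species, seed = 1L,
                                interspecific_divergence = 0.10,
                                its_len = 620L, lsu_len = 880L) {
  stopifnot(n_species >= 1L)
  set.seed(seed)
  site <- reverse_complement(ITS4_PRIMER)
  repeat {
    ancestor <- paste0(.random_dna(its_len), site, .random_dna(lsu_len))
    if (length(gregexpr(site, ancestor, fixed = TRUE)[[1]]) == 1L) break
  }
  site_span <- c(its_len, its_len + nchar(site))
  lapply(seq_len(n_species), function(i) {
    repeat {
      cassette <- mutate_haplotype(ancestor, interspecific_divergence,
                                   protected_spans = list(site_span))
      # the priming site must stay unique so cleaving is unambiguous
      if (length(gregexpr(site, cassette, fixed = TRUE)[[1]]) == 1L) break
    }
    list(name = sprintf("Species%02d", i), cassette = cassette,
         its_span = c(0L, its_len), site_span = site_span,
         lsu_span = c(site_span[2L], nchar(cassette)),
         divergence = interspecific_divergence)
  })
}

# region substrings of a cassette-coordinate haplotype
.region_seq <- function(seq, span) substr(seq, span[1L] + 1L, span[2L])

#' Generate barcode pairs
#'
#' Random barcodes with a guaranteed minimum pairwise Hamming distance
#' across the whole pool, so that demultiplexing with a small mismatch
#' budget is unambiguous.
#'
#' @param samples character vector of sample names.
#' @param length barcode length in bp.
#' @param min_dist minimum pairwise Hamming distance within the pool.
#' @param seed optional integer seed.
#' @return barcode map data.frame (`sample`, `fwd_barcode`,
#'   `rev_barcode`).
#' @export
make_barcodes <- function(samples, length = 16L, min_dist = 8L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- character(0)
  while (base::length(pool) < 2L * base::length(samples)) {
    cand <- .random_dna(length)
    ok <- all(vapply(pool, function(b)
      sum(utf8ToInt(b) != utf8ToInt(cand)) >= min_dist, logical(1)))
    if (ok) pool <- c(pool, cand)
  }
  data.frame(sample = samples,
             fwd_barcode = pool[seq_along(samples)],
             rev_barcode = pool[base::length(samples) + seq_along(samples)],
             stringsAsFactors = FALSE)
}

#' Simulate CCS reads for one strain
#'
#' Each read is `fwd_barcode + haplotype-with-errors +
#' reverse_complement(rev_barcode)`, reverse-complemented with
#' probability 0.5. Sequencing errors are i.i.d. substitutions at
#' `error_rate` per base of the insert (uniform over the three
#' alternative bases). Subread counts are `min_subreads` plus a Poisson
#' excess reaching `mean_subreads` on average; read quality is one minus
#' the realised per-base error rate.
#'
#' @param strain strain model: list with `strain_id`, `haplotypes`
#'   (character, major variant first) and optionally `species`.
#' @param n_dominant read count of the major haplotype.
#' @param minor_counts integer vector of read counts, one per minor
#'   haplotype (may be empty).
#' @param error_rate per-base substitution error rate (CCS residual
#'   errors; <= 0.01 for >= 99% accurate reads).
#' @param mean_subreads mean subread depth (minimum enforced at
#'   `min_subreads`).
#' @param barcodes list/row with `fwd_barcode` and `rev_barcode`.
#' @param seed optional integer seed.
#' @param min_subreads lower bound of the subread-count distribution.
#' @return list with `reads` (sequence record frame) and `truth`
#'   (frame: `read_id`, `strain`, `haplotype` index, `n_errors`,
#'   `orientation`, `insert` — the error-bearing insert in forward
#'   orientation).
#' @export
simulate_strain_reads <- function(strain, n_dominant, minor_counts = integer(0),
                                  error_rate = 0.002, mean_subreads = 33,
                                  barcodes, seed = NULL, min_subreads = 5L) {
  if (!is.null(seed)) set.seed(seed)
  counts <- c(n_dominant, minor_counts)
  if (length(counts) != length(strain$haplotypes))
    stop("need one read count per haplotype (major first)")
  total <- sum(counts)
  if (total <= 0L) stop("zero reads requested for strain ", strain$strain_id)
  hap_of <- rep(seq_along(counts), counts)
  L <- nchar(strain$haplotypes[1L])
  ids <- sprintf("%s_r%04d", strain$strain_id, seq_len(total))
  inserts <- character(total)
  n_err <- integer(total)
  for (r in seq_len(total)) {
    chars <- strsplit(strain$haplotypes[hap_of[r]], "")[[1]]
    k <- rbinom(1L, L, error_rate)
    if (k > 0L) chars <- .substitute_bases(chars, sample.int(L, k))
    inserts[r] <- paste(chars, collapse = "")
    n_err[r] <- k
  }
  flip <- runif(total) < 0.5
  tagged <- paste0(barcodes$fwd_barcode, inserts,
                   reverse_complement(barcodes$rev_barcode))
  tagged[flip] <- reverse_complement(tagged[flip])
  np <- min_subreads + rpois(total, max(mean_subreads - min_subreads, 0))
  reads <- seq_records(ids, tagged, np = np, rq = 1 - n_err / L)
  truth <- data.frame(read_id = ids, strain = strain$strain_id,
                      haplotype = hap_of, n_errors = n_err,
                      orientation = ifelse(flip, "rev", "fwd"),
                      insert = inserts, stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Simulate a complete multi-species amplicon dataset
#'
#' Builds a species panel, derives strains (one major haplotype at
#' `strain_divergence` from the species cassette, plus 0 to
#' `max_minors` minor haplotypes at divergences sampled from
#' `minor_grid`), simulates tagged CCS reads per strain, and emits a
#' truth table, barcode map and a per-strain Sanger-like reference
#' panel (the true major haplotype of each region).
#'
#' The defaults emulate the observed study conditions: dominant
#' clusters of 99--427 reads, minor clusters of 1--14 reads, mean
#' subread depth 33 (minimum 5), read accuracy >= 99%, intragenomic
#' divergences spanning roughly 0.01--0.09 and intraspecific (between
#' strain) divergence of a few parts per thousand. The minor-divergence
#' grid spans that range while staying clear of the 3% clustering
#' radius, where a variant's cluster membership is not defined.
#'
#' @param n_species,strains_per_species panel dimensions.
#' @param seed integer seed (drives the whole dataset).
#' @param interspecific_divergence see [build_species_panel()].
#' @param strain_divergence p-distance of each strain's major haplotype
#'   from its species cassette.
#' @param minor_grid divergence levels minors are drawn from.
#' @param max_minors maximum number of minor haplotypes per strain.
#' @param dominant_range,minor_range inclusive read-count ranges.
#' @param error_rate,mean_subreads see [simulate_strain_reads()].
#' @param its_len,lsu_len region lengths in bp.
#' @param n_cross_minors number of strains receiving an additional
#'   cross-species minor variant (derived from another species'
#'   cassette; models shared variants escaping concerted evolution that
#'   classify outside their species of origin).
#' @return object of class `amplicon_sim`: list with `reads` (shuffled
#'   record frame), `truth` (read-level), `haplotypes` (strain-level:
#'   sequences, regions, divergences, read counts, type), `barcode_map`
#'   (with a `species` column), `references`, `species` (panel) and
#'   `spans`.
#' @export
simulate_dataset <- function(n_species = 9L, strains_per_species = 2L,
                             seed = 1L, interspecific_divergence = 0.10,
                             strain_divergence = 0.002,
                             minor_grid = c(0.01, 0.045, 0.06, 0.075, 0.09),
                             max_minors = 3L,
                             dominant_range = c(99L, 427L),
                             minor_range = c(1L, 14L),
                             error_rate = 0.002, mean_subreads = 33,
                             its_len = 620L, lsu_len = 880L,
                             n_cross_minors = 0L) {
  set.seed(seed)
  panel <- build_species_panel(n_species, seed = sample.int(1e6, 1L),
                               interspecific_divergence = interspecific_divergence,
                               its_len = its_len, lsu_len = lsu_len)
  site_span <- panel[[1L]]$site_span
  its_span <- panel[[1L]]$its_span
  lsu_span <- panel[[1L]]$lsu_span

  strain_ids <- character(0)
  strain_species <- character(0)
  hap_tab <- list()
  strains <- list()
  for (si in seq_along(panel)) {
    for (ki in seq_len(strains_per_species)) {
      sid <- sprintf("MY%02d%02d", si, ki)
      major <- mutate_haplotype(panel[[si]]$cassette, strain_divergence,
                                protected_spans = list(site_span))
      k_min <- sample(0:max_minors, 1L)
      divs <- if (k_min) sample(minor_grid, k_min, replace = TRUE) else numeric(0)
      minors <- vapply(divs, function(d)
        mutate_haplotype(major, d, protected_spans = list(site_span)),
        character(1))
      haps <- c(major, minors)
      n_dom <- sample(dominant_range[1L]:dominant_range[2L], 1L)
      n_min <- if (k_min) sample(minor_range[1L]:minor_range[2L], k_min,
                                 replace = TRUE) else integer(0)
      strains[[sid]] <- list(
        strain_id = sid, species = panel[[si]]$name,
        haplotypes = haps, divergences = c(0, divs),
        counts = c(n_dom, n_min), type = rep("own", length(haps)))
      strain_ids <- c(strain_ids, sid)
      strain_species <- c(strain_species, panel[[si]]$name)
    }
  }
  # optional cross-species minor variants (identification stress case)
  if (n_cross_minors > 0L && n_species >= 2L) {
    pick <- strain_ids[seq_len(min(n_cross_minors, length(strain_ids)))]
    for (sid in pick) {
      own <- match(strains[[sid]]$species,
                   vapply(panel, `[[`, character(1), "name"))
      donor <- panel[[if (own == length(panel)) 1L else own + 1L]]
      variant <- mutate_haplotype(donor$cassette, 0.02,
                                  protected_spans = list(site_span))
      strains[[sid]]$haplotypes <- c(strains[[sid]]$haplotypes, variant)
      strains[[sid]]$divergences <- c(strains[[sid]]$divergences, NA_real_)
      strains[[sid]]$counts <- c(strains[[sid]]$counts,
                                 sample(max(2L, minor_range[1L]):minor_range[2L], 1L))
      strains[[sid]]$type <- c(strains[[sid]]$type, "cross")
    }
  }

  bm <- make_barcodes(strain_ids)
  bm$species <- strain_species

  reads <- list(); truth <- list()
  for (sid in strain_ids) {
    st <- strains[[sid]]
    sim <- simulate_strain_reads(
      st, n_dominant = st$counts[1L], minor_counts = st$counts[-1L],
      error_rate = error_rate, mean_subreads = mean_subreads,
      barcodes = bm[bm$sample == sid, ])
    reads[[sid]] <- sim$reads
    truth[[sid]] <- sim$truth
    hap_tab[[sid]] <- data.frame(
      strain = sid, species = st$species,
      haplotype = seq_along(st$haplotypes),
      divergence = st$divergences, n_reads = st$counts, type = st$type,
      seq = st$haplotypes,
      its_seq = vapply(st$haplotypes, .region_seq, character(1), its_span),
      lsu_seq = vapply(st$haplotypes, .region_seq, character(1), lsu_span),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  reads <- do.call(rbind, reads)
  truth <- do.call(rbind, truth)
  shuffle <- sample.int(nrow(reads))
  reads <- reads[shuffle, , drop = FALSE]
  rownames(reads) <- rownames(truth) <- NULL
  hap_tab <- do.call(rbind, hap_tab)
  rownames(hap_tab) <- NULL

  majors <- hap_tab[hap_tab$haplotype == 1L, ]
  references <- rbind(
    data.frame(id = paste0("SAN_", majors$strain, "_ITS"),
               species = majors$species, region = "ITS",
               strain = majors$strain, seq = majors$its_seq,
               stringsAsFactors = FALSE),
    data.frame(id = paste0("SAN_", majors$strain, "_LSU"),
               species = majors$species, region = "LSU",
               strain = majors$strain, seq = majors$lsu_seq,
               stringsAsFactors = FALSE))
  rownames(references) <- NULL

  structure(list(reads = reads, truth = truth, haplotypes = hap_tab,
                 barcode_map = bm, references = references,
                 species = panel,
                 spans = list(its = its_span, site = site_span, lsu = lsu_span),
                 params = list(seed = seed, error_rate = error_rate,
                               mean_subreads = mean_subreads,
                               interspecific_divergence = interspecific_divergence,
                               strain_divergence = strain_divergence)),
            class = "amplicon_sim")
}

#' @export
print.amplicon_sim <- function(x, ...) {
  cat("Synthetic amplicon dataset:", nrow(x$reads), "reads,",
      length(unique(x$truth$strain)), "strains,",
      length(x$species), "species\n")
  cat("  haplotypes per strain:",
      paste(range(table(x$haplotypes$strain)), collapse = "-"), "\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits `reads.fastq`, `truth.tsv`, `barcode_map.tsv` and
#' `references.fasta` under `dir`.
#'
#' @param sim an `amplicon_sim` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastx(sim$reads, file.path(dir, "reads.fastq"), format = "fastq")
  write_tsv(sim$truth[, c("read_id", "strain", "haplotype", "n_errors",
                          "orientation")],
            file.path(dir, "truth.tsv"))
  write_tsv(sim$barcode_map, file.path(dir, "barcode_map.tsv"))
  write_references(sim$references, file.path(dir, "references.fasta"))
  invisible(dir)
}

#' Truth-derived expected cluster structure for a region
#'
#' Predicts, from the simulator's ground truth alone, what identity
#' clustering at `threshold` must produce per strain: haplotypes closer
#' than the clustering radius `1 - threshold` are merged
#' (single-linkage, Hamming p-distance on the true region sequences)
#' because reads of a variant inside the radius of a cluster
#' representative necessarily join that cluster. Expected read counts
#' are summed over merged haplotypes, and the expected consensus of
#' each group is the per-column majority over the group's realised
#' (error-bearing) reads, ties resolved toward the dominant haplotype's
#' base. This prediction is independent of the alignment and clustering
#' code under test.
#'
#' @param sim an `amplicon_sim` object.
#' @param region `"ITS"` or `"LSU"`.
#' @param threshold clustering identity threshold.
#' @return data.frame with one row per expected cluster: `strain`,
#'   `group`, `n_reads`, `haplotypes` (merged indices, comma-separated),
#'   `dominant` (logical), `consensus`.
#' @export
expected_clusters <- function(sim, region = c("ITS", "LSU"),
                              threshold = 0.97) {
  region <- match.arg(region)
  span <- if (region == "ITS") sim$spans$its else sim$spans$lsu
  radius <- 1 - threshold
  out <- list()
  for (sid in unique(sim$haplotypes$strain)) {
    ht <- sim$haplotypes[sim$haplotypes$strain == sid, ]
    hseq <- vapply(ht$seq, .region_seq, character(1), span)
    n <- length(hseq)
    # single-linkage merge at p <= radius (equal lengths: Hamming)
    comp <- seq_len(n)
    if (n > 1L) {
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        p <- sum(utf8ToInt(hseq[i]) != utf8ToInt(hseq[j])) / nchar(hseq[i])
        if (p <= radius && comp[i] != comp[j])
          comp[comp == comp[j]] <- comp[i]
      }
    }
    tr <- sim$truth[sim$truth$strain == sid, ]
    gi <- 0L
    for (g in unique(comp)) {
      gi <- gi + 1L
      members <- which(comp == g)
      grp_reads <- tr[tr$haplotype %in% ht$haplotype[members], ]
      ins <- substr(grp_reads$insert, span[1L] + 1L, span[2L])
      # majority per column; ties toward the group's dominant haplotype
      dom <- members[which.max(ht$n_reads[members])]
      dom_chars <- strsplit(hseq[dom], "")[[1]]
      M <- do.call(rbind, strsplit(ins, ""))
      cons <- vapply(seq_len(ncol(M)), function(j) {
        tab <- table(M[, j])
        top <- names(tab)[tab == max(tab)]
        if (dom_chars[j] %in% top) dom_chars[j] else top[1L]
      }, character(1))
      out[[length(out) + 1L]] <- data.frame(
        strain = sid, group = gi, n_reads = nrow(grp_reads),
        haplotypes = paste(ht$haplotype[members], collapse = ","),
        dominant = 1L %in% ht$haplotype[members],
        consensus = paste(cons, collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
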