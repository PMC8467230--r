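# End-to-end pipeline: CCS filter -> demultiplex -> length filter ->
# region cleave -> cluster + consensus -> divergence report ->
# haplotype networks -> classification. Every input read ends up in
# exactly one sample/region bin or one discard category, and the run
# log accounts for all of them. All outputs are TSV (tab separated,
# header row) or FASTA; re-running with identical inputs and seed gives
# byte-identical files.

.ensure_reads <- function(x) if (is.data.frame(x)) x else read_fastx(x)
.ensure_map <- function(x) if (is.data.frame(x)) .check_barcode_map(x) else read_barcode_map(x)
.ensure_refs <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) .check_refs(x) else read_references(x)
}

#' Run the full amplicon pipeline
#'
#' @param reads sequence record frame or FASTA/FASTQ path of tagged
#'   CCS-level reads.
#' @param barcode_map data.frame or TSV path (`sample`, `fwd_barcode`,
#'   `rev_barcode`, optional `species`).
#' @param outdir output directory, created if needed.
#' @param references optional reference frame or FASTA path (see
#'   [read_references()]); enables the Sanger-based divergence columns
#'   and the classification table.
#' @param config a [pipeline_config()].
#' @return object of class `rdna_pipeline`: list with `consensus`
#'   (all consensus records), `divergence` (per-region
#'   [divergence_report()]s), `networks`, `classification`, `log`
#'   (stage/category counts) and `outdir`. Reports are also written
#'   under `outdir`.
#' @export
run_pipeline <- function(reads, barcode_map, outdir, references = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  reads <- .ensure_reads(reads)
  bm <- .ensure_map(barcode_map)
  refs <- .ensure_refs(references)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$rng_seed)

  logrows <- list()
  note <- function(stage, category, count)
    logrows[[length(logrows) + 1L]] <<- data.frame(
      stage = stage, category = category, count = count,
      stringsAsFactors = FALSE)
  note("input", "reads", nrow(reads))

  cf <- ccs_filter(reads, config$min_subreads, config$min_read_quality)
  note("ccs_filter", "kept", nrow(cf$kept))
  note("ccs_filter", "low_quality", nrow(cf$discarded))

  dm <- demultiplex(cf$kept, bm, config$max_barcode_mismatches)
  note("demultiplex", "assigned", nrow(dm$assigned))
  note("demultiplex", "unassigned", nrow(dm$discards$unassigned))
  note("demultiplex", "ambiguous", nrow(dm$discards$ambiguous))

  # length bounds apply to the demultiplexed (barcode-trimmed) amplicon
  lf <- length_filter(dm$assigned, config$min_len, config$max_len)
  note("length_filter", "kept", nrow(lf$kept))
  note("length_filter", "length", nrow(lf$discarded))

  samples <- bm$sample
  cons_all <- list(); assign_all <- list(); sizes_all <- list()
  n_primer_miss <- 0L; n_empty_part <- 0L
  for (smp in samples) {
    sr <- lf$kept[lf$kept$sample == smp, , drop = FALSE]
    if (nrow(sr) == 0L) next
    parts <- lapply(sr$seq, split_amplicon, primer = config$primer_its4,
                    max_mm = config$max_primer_mismatches)
    found <- !vapply(parts, is.null, logical(1))
    n_primer_miss <- n_primer_miss + sum(!found)
    for (region in c("ITS", "LSU")) {
      part <- vapply(parts[found], `[[`, character(1),
                     if (region == "ITS") "its_part" else "lsu_part")
      keep <- nzchar(part)
      n_empty_part <- n_empty_part + sum(!keep)
      if (!any(keep)) next
      rr <- sr[found, , drop = FALSE][keep, , drop = FALSE]
      rr$seq <- part[keep]
      cc <- cluster_consensus(rr, sample = smp, region = region,
                              threshold = config$cluster_identity,
                              denominator = config$identity_denominator)
      key <- paste(smp, region, sep = ".")
      cons_all[[key]] <- cc$consensus
      assign_all[[key]] <- cc$assignments
      sizes_all[[key]] <- data.frame(sample = smp, region = region,
                                     consensus_id = cc$consensus$id,
                                     n_reads = cc$consensus$n_reads,
                                     stringsAsFactors = FALSE)
      sdir <- file.path(outdir, smp, region)
      dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
      mem <- merge(rr[, c("id", "seq")], cc$assignments,
                   by.x = "id", by.y = "read_id", sort = TRUE)
      write_fastx(data.frame(id = paste0(mem$id, " cluster=", mem$consensus_id),
                             seq = mem$seq, stringsAsFactors = FALSE),
                  file.path(sdir, "clusters.fasta"))
      hdr <- sprintf("%s region=%s n_reads=%d", cc$consensus$id,
                     region, cc$consensus$n_reads)
      write_fastx(data.frame(id = hdr, seq = cc$consensus$seq,
                             stringsAsFactors = FALSE),
                  file.path(sdir, "consensus.fasta"))
      write_tsv(sizes_all[[key]], file.path(sdir, "cluster_sizes.tsv"))
    }
  }
  note("region_split", "primer_not_found", n_primer_miss)
  note("region_split", "empty_part", n_empty_part)
  consensus <- if (length(cons_all)) do.call(rbind, c(cons_all, make.row.names = FALSE))
               else data.frame(id = character(0), seq = character(0),
                               n_reads = integer(0), region = character(0),
                               sample = character(0), stringsAsFactors = FALSE)
  if (nrow(consensus) == 0L)
    warning("no reads survived the filters; outputs are empty")

  # species map: barcode-map column, else from the references
  species_map <- NULL
  if (!is.null(bm$species)) {
    species_map <- bm$species; names(species_map) <- bm$sample
  } else if (!is.null(refs) && !is.null(refs$strain) && !all(is.na(refs$strain))) {
    species_map <- refs$species; names(species_map) <- refs$strain
    species_map <- species_map[!duplicated(names(species_map))]
  }

  divergence <- list(); networks <- list()
  for (region in c("ITS", "LSU")) {
    cr <- consensus[consensus$region == region, , drop = FALSE]
    if (nrow(cr) == 0L || is.null(species_map)) next
    cons_by_strain <- split(cr$seq, cr$sample)
    sanger <- NULL
    if (!is.null(refs) && !is.null(refs$strain)) {
      rr <- refs[refs$region == region & !is.na(refs$strain), ]
      rr <- rr[rr$strain %in% names(cons_by_strain), ]
      if (nrow(rr)) {
        sanger <- rr$seq[!duplicated(rr$strain)]
        names(sanger) <- rr$strain[!duplicated(rr$strain)]
        sanger <- sanger[names(cons_by_strain)]
        names(sanger) <- names(cons_by_strain)
      }
    }
    rep <- divergence_report(cons_by_strain, sanger,
                             species_map[names(cons_by_strain)])
    divergence[[region]] <- rep
    write_tsv(as.data.frame(rep),
              file.path(outdir, paste0("divergence_", region, ".tsv")))

    # haplotype networks per species (consensus + Sanger combined)
    ndir <- file.path(outdir, "haplonet")
    dir.create(ndir, showWarnings = FALSE, recursive = TRUE)
    for (spc in unique(species_map[names(cons_by_strain)])) {
      strains <- names(cons_by_strain)[species_map[names(cons_by_strain)] == spc]
      ci <- cr[cr$sample %in% strains, , drop = FALSE]
      ids <- ci$id; seqs <- ci$seq
      src <- rep("PacBio", nrow(ci)); nrd <- ci$n_reads
      if (!is.null(sanger)) {
        have <- strains[strains %in% names(sanger) & !is.na(sanger[strains])]
        ids <- c(have, ids); seqs <- c(unname(sanger[have]), seqs)
        src <- c(rep("SAN", length(have)), src)
        nrd <- c(rep(NA_integer_, length(have)), nrd)
      }
      if (length(seqs) < 2L) next
      hs <- collapse_haplotypes(ids, seqs, src, nrd)
      net <- build_msn(hs, epsilon = config$epsilon)
      networks[[paste(spc, region, sep = ".")]] <- net
      repn <- network_report(net)
      base <- file.path(ndir, paste0(gsub("[^A-Za-z0-9_.-]", "_", spc), "_", region))
      write_tsv(repn$haplotypes, paste0(base, "_haplotypes.tsv"))
      write_tsv(repn$edges, paste0(base, "_edges.tsv"))
    }
  }

  classification <- NULL
  if (!is.null(refs) && nrow(consensus)) {
    cls <- list()
    for (i in seq_len(nrow(consensus))) {
      rec <- consensus[i, ]
      if (!any(refs$region == rec$region)) next
      origin <- if (!is.null(species_map)) unname(species_map[rec$sample])
                else NA_character_
      cl <- classify(rec$seq, refs, region = rec$region,
                     query_id = rec$id, origin = origin)
      cl$sample <- rec$sample; cl$region <- rec$region
      cl$n_reads <- rec$n_reads
      cl$major <- rec$id == select_major(
        consensus[consensus$sample == rec$sample &
                  consensus$region == rec$region, ])$id
      cls[[length(cls) + 1L]] <- cl
    }
    if (length(cls)) {
      classification <- do.call(rbind, cls)
      write_tsv(classification, file.path(outdir, "classification.tsv"))
    }
  }

  log <- do.call(rbind, logrows)
  write_tsv(log, file.path(outdir, "log.tsv"))
  structure(list(consensus = consensus, divergence = divergence,
                 networks = networks, classification = classification,
                 log = log, config = config, outdir = outdir),
            class = "rdna_pipeline")
}

#' @export
print.rdna_pipeline <- function(x, ...) {
  cat("rDNA amplicon pipeline run\n")
  n_in <- x$log$count[x$log$stage == "input"]
  cat("  input reads      :", n_in, "\n")
  for (st in c("ccs_filter", "demultiplex", "length_filter")) {
    rows <- x$log[x$log$stage == st, ]
    cat(sprintf("  %-17s: %s\n", st,
                paste(sprintf("%s=%d", rows$category, rows$count), collapse = ", ")))
  }
  cat("  consensus records:", nrow(x$consensus), "across",
      length(unique(x$consensus$sample)), "samples\n")
  if (!is.null(x$classification)) {
    maj <- x$classification[x$classification$major, ]
    cat(sprintf("  major-variant classification: %d/%d concordant\n",
                sum(maj$flag == "concordant"), nrow(maj)))
  }
  cat("  outputs under", x$outdir, "\n")
  invisible(x)
}
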