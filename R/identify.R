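# Distance-based species identification against a Sanger reference
# panel. A query is assigned to the species of its nearest reference by
# p-distance; ties break by the smaller mean distance to all of that
# species' references, then lexicographically. A query whose assigned
# species differs from its strain's putative species of origin is
# flagged as an outlier — the behaviour expected of divergent minor
# rDNA variants that escaped concerted evolution.

.check_refs <- function(refs) {
  need <- c("id", "species", "region", "seq")
  if (!is.data.frame(refs) || !all(need %in% names(refs)))
    stop("references need columns: ", paste(need, collapse = ", "))
  refs
}

#' Read a reference panel from FASTA
#'
#' Headers follow `>ACCESSION species=<name> region=<ITS|LSU>
#' [strain=<id>]`.
#'
#' @param path FASTA file.
#' @return reference frame with columns `id`, `species`, `region`,
#'   `strain`, `seq`.
#' @export
read_references <- function(path) {
  x <- Biostrings::readBStringSet(path)
  headers <- names(x)
  refs <- data.frame(
    id = sub("[[:space:]].*$", "", headers),
    species = gsub("_", " ", .parse_header_token(headers, "species")),
    region = .parse_header_token(headers, "region"),
    strain = .parse_header_token(headers, "strain"),
    seq = toupper(as.character(x)),
    stringsAsFactors = FALSE)
  if (any(is.na(refs$species)) || any(is.na(refs$region)))
    stop("reference headers must carry species= and region= tokens")
  refs
}

#' Write a reference panel to FASTA
#'
#' @param refs reference frame (`id`, `species`, `region`, optional
#'   `strain`, `seq`).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_references <- function(refs, path) {
  .check_refs(refs)
  h <- paste0(refs$id, " species=", gsub(" ", "_", refs$species),
              " region=", refs$region)
  if (!is.null(refs$strain)) h <- paste0(h, " strain=", refs$strain)
  x <- Biostrings::BStringSet(refs$seq)
  names(x) <- h
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

.pick_species <- function(d, ref_species) {
  best <- min(d)
  cand <- sort(unique(ref_species[d <= best + 1e-12]))
  if (length(cand) > 1L) {
    means <- vapply(cand, function(s) mean(d[ref_species == s]), numeric(1))
    cand <- cand[order(means, cand, method = "radix")]
  }
  assigned <- cand[1L]
  others <- d[ref_species != assigned]
  margin <- if (length(others)) min(others) - best else NA_real_
  list(assigned = assigned, distance = best, margin = margin)
}

#' Classify a consensus sequence against references
#'
#' @param query_seq query DNA string.
#' @param refs reference frame (see [read_references()]).
#' @param region region of the query (`"ITS"` or `"LSU"`); only
#'   references of this region are used.
#' @param query_id identifier reported in the result.
#' @param origin the query strain's putative species (or `NA`); the
#'   outlier flag compares the assignment against it.
#' @return one-row data.frame: `query`, `origin`, `assigned`,
#'   `distance`, `margin`, `flag` (`"concordant"`/`"outlier"`, `NA`
#'   when no origin given).
#' @export
classify <- function(query_seq, refs, region = "ITS", query_id = "query",
                     origin = NA_character_) {
  refs <- .check_refs(refs)
  refs <- refs[refs$region == region, , drop = FALSE]
  if (nrow(refs) == 0L) stop("no references for region ", region)
  d <- vapply(refs$seq, function(r) pairwise_p_distance(query_seq, r),
              numeric(1), USE.NAMES = FALSE)
  ans <- .pick_species(d, refs$species)
  data.frame(query = query_id, origin = origin, assigned = ans$assigned,
             distance = ans$distance, margin = ans$margin,
             flag = if (is.na(origin)) NA_character_ else
               if (ans$assigned == origin) "concordant" else "outlier",
             stringsAsFactors = FALSE)
}

#' Classify using both regions jointly
#'
#' Distances to each reference strain are the length-weighted mean of
#' the per-region p-distances (weights = reference region lengths), the
#' concatenation-equivalent combination. References are paired across
#' regions by their `strain` column. If one query region is missing the
#' call falls back to single-region classification with a warning.
#'
#' @param its_seq,lsu_seq query sequences (either may be `NA`).
#' @param refs reference frame with a `strain` column.
#' @param query_id,origin see [classify()].
#' @return one-row data.frame as in [classify()].
#' @export
classify_combined <- function(its_seq, lsu_seq, refs, query_id = "query",
                              origin = NA_character_) {
  refs <- .check_refs(refs)
  if (is.null(refs$strain) || any(is.na(refs$strain)))
    stop("combined classification needs a strain column in the references")
  if (is.na(its_seq) || is.na(lsu_seq)) {
    warning("one region missing; falling back to single-region classification")
    if (!is.na(its_seq))
      return(classify(its_seq, refs, "ITS", query_id, origin))
    return(classify(lsu_seq, refs, "LSU", query_id, origin))
  }
  strains <- intersect(refs$strain[refs$region == "ITS"],
                       refs$strain[refs$region == "LSU"])
  if (!length(strains)) stop("no reference strain carries both regions")
  comb <- vapply(strains, function(st) {
    ri <- refs[refs$strain == st & refs$region == "ITS", ][1L, ]
    rl <- refs[refs$strain == st & refs$region == "LSU", ][1L, ]
    wi <- nchar(ri$seq); wl <- nchar(rl$seq)
    di <- pairwise_p_distance(its_seq, ri$seq)
    dl <- pairwise_p_distance(lsu_seq, rl$seq)
    c((wi * di + wl * dl) / (wi + wl),
      match(ri$species, unique(refs$species)))
  }, numeric(2))
  species_of <- unique(refs$species)[comb[2L, ]]
  ans <- .pick_species(comb[1L, ], species_of)
  data.frame(query = query_id, origin = origin, assigned = ans$assigned,
             distance = ans$distance, margin = ans$margin,
             flag = if (is.na(origin)) NA_character_ else
               if (ans$assigned == origin) "concordant" else "outlier",
             stringsAsFactors = FALSE)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Convenience wrapper around [ape::nj()] producing a Newick string, for
#' visual QC of consensus/reference sets.
#'
#' @param D symmetric distance matrix with at least 3 labelled rows.
#' @return Newick string.
#' @export
nj_tree <- function(D) {
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(D))
  ape::write.tree(tr)
}
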