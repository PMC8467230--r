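# Divergence summaries: uncorrected p-distance means over the four pair
# sets used to characterise rDNA variation:
#   intragenomic          consensus pairs within one strain
#   Sanger-PacBio         every consensus vs the strain's Sanger sequence
#   intraspecific Sanger  Sanger pairs between strains of one species
#   intraspecific PacBio  consensus pairs between strains of one species
# A mean over an empty pair set is reported as NA (rendered "-").

#' Mean p-distance over a pair set
#'
#' With one sequence set, averages over unordered distinct pairs; with
#' two sets, averages over the full cross product.
#'
#' @param seqs_a character vector of DNA strings.
#' @param seqs_b optional second set.
#' @return mean p-distance, or `NA` when the pair set is empty.
#' @export
mean_pairset_distance <- function(seqs_a, seqs_b = NULL) {
  seqs_a <- as.character(seqs_a)
  if (is.null(seqs_b)) {
    if (length(seqs_a) < 2L) return(NA_real_)
    pairs <- combn(length(seqs_a), 2L)
    return(mean(apply(pairs, 2L, function(ij)
      pairwise_p_distance(seqs_a[ij[1L]], seqs_a[ij[2L]]))))
  }
  seqs_b <- as.character(seqs_b)
  if (!length(seqs_a) || !length(seqs_b)) return(NA_real_)
  mean(outer(seq_along(seqs_a), seq_along(seqs_b),
             Vectorize(function(i, j) pairwise_p_distance(seqs_a[i], seqs_b[j]))))
}

#' Divergence report per strain and species
#'
#' Computes the four summary statistics per strain/species. The
#' intraspecific PacBio statistic uses *all* consensus sequences of the
#' species' strains (between-strain pairs only), not just major
#' variants, so that divergent minor variants contribute — within-strain
#' pairs are counted by the intragenomic statistic instead.
#'
#' @param consensus named list: strain id -> character vector of that
#'   strain's consensus sequences.
#' @param sanger optional named character vector: strain id -> Sanger
#'   reference sequence.
#' @param species named character vector: strain id -> species label.
#' @return `divergence_report` data.frame with one row per strain and
#'   columns `species`, `strain`, `intragenomic`, `sanger_pacbio`,
#'   `intraspecific_sanger`, `intraspecific_pacbio` (species-level
#'   values repeated on each of the species' rows; `NA` = empty pair
#'   set).
#' @export
divergence_report <- function(consensus, sanger = NULL, species) {
  strains <- names(consensus)
  if (is.null(strains) || !all(strains %in% names(species)))
    stop("every strain in `consensus` needs a species assignment")
  sp <- species[strains]

  intragenomic <- vapply(strains, function(s)
    mean_pairset_distance(consensus[[s]]), numeric(1))
  sanger_pacbio <- vapply(strains, function(s) {
    if (is.null(sanger) || is.na(sanger[s])) return(NA_real_)
    mean_pairset_distance(consensus[[s]], sanger[[s]])
  }, numeric(1))

  intraspecific_sanger <- intraspecific_pacbio <- rep(NA_real_, length(strains))
  for (spc in unique(sp)) {
    members <- strains[sp == spc]
    idx <- which(sp == spc)
    if (length(members) >= 2L) {
      if (!is.null(sanger)) {
        san <- sanger[members]
        san <- san[!is.na(san)]
        if (length(san) >= 2L)
          intraspecific_sanger[idx] <- mean_pairset_distance(san)
      }
      pairs <- combn(length(members), 2L)
      d <- unlist(apply(pairs, 2L, function(ij) {
        a <- consensus[[members[ij[1L]]]]
        b <- consensus[[members[ij[2L]]]]
        if (!length(a) || !length(b)) return(NULL)
        as.vector(outer(seq_along(a), seq_along(b), Vectorize(function(i, j)
          pairwise_p_distance(a[i], b[j]))))
      }))
      if (length(d)) intraspecific_pacbio[idx] <- mean(d)
    }
  }
  structure(data.frame(species = unname(sp), strain = strains,
                       intragenomic = intragenomic,
                       sanger_pacbio = sanger_pacbio,
                       intraspecific_sanger = intraspecific_sanger,
                       intraspecific_pacbio = intraspecific_pacbio,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("divergence_report", "data.frame"))
}

#' @export
print.divergence_report <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v)
    ifelse(is.na(v), "-", formatC(v, digits = digits, format = "fg")))
  cat("Average p-distance within strains (intragenomic) and species (intraspecific)\n")
  print(y, row.names = FALSE)
  invisible(x)
}
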