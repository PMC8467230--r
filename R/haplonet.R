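# Haplotype collapsing and minimum spanning networks.
#
# The network is the union of all minimum spanning trees of the complete
# mutational-distance graph (the epsilon = 0 minimum spanning network):
# distance classes are processed in ascending order and an edge is
# admitted iff its endpoints lie in different components *as frozen at
# the start of its class*; components merge after each class. For
# epsilon > 0 the admission threshold of a pair is relaxed by epsilon
# distance units beyond the class at which its components first connect.

#' Collapse aligned sequences into haplotypes
#'
#' Sequences are star-aligned against the most frequent input sequence
#' (ties: first seen) and identical aligned rows merge into one
#' haplotype. Haplotypes are named `"Hap 1"`, `"Hap 2"`, ... by
#' decreasing frequency, ties by first appearance.
#'
#' @param ids sequence identifiers (e.g. `"MY4953-C1"` or a Sanger
#'   accession).
#' @param seqs DNA strings.
#' @param source per-sequence source tag, `"SAN"` or `"PacBio"`.
#' @param n_reads per-sequence read count (`NA` for Sanger entries).
#' @return object of class `haplotype_set`: list with `table` (frame:
#'   `haplotype`, `frequency`), `members` (frame: `id`, `source`,
#'   `n_reads`, `haplotype`) and `aligned` (named character vector, one
#'   representative aligned row per haplotype).
#' @export
collapse_haplotypes <- function(ids, seqs, source,
                                n_reads = rep(NA_integer_, length(seqs))) {
  stopifnot(length(ids) == length(seqs), length(source) == length(seqs))
  if (!length(seqs)) stop("no sequences to collapse")
  counts <- table(factor(seqs, levels = unique(seqs)))
  ref <- match(names(counts)[which.max(counts)], seqs)
  aligned <- star_align(seqs, ref = ref)
  key <- match(aligned, unique(aligned))
  freq <- tabulate(key)
  ord <- order(-freq, seq_along(freq), method = "radix")
  hap_of_key <- match(seq_along(freq), ord)  # key -> rank
  hap <- hap_of_key[key]
  members <- data.frame(id = ids, source = source, n_reads = n_reads,
                        haplotype = paste("Hap", hap),
                        stringsAsFactors = FALSE)
  rep_rows <- unique(aligned)[ord]
  names(rep_rows) <- paste("Hap", seq_along(ord))
  structure(list(
    table = data.frame(haplotype = names(rep_rows),
                       frequency = freq[ord],
                       stringsAsFactors = FALSE),
    members = members,
    aligned = rep_rows
  ), class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(nrow(x$table), "haplotypes from", nrow(x$members), "sequences\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Mutational distance between aligned haplotype rows
#'
#' Number of scored columns at which the rows differ; columns where
#' either row carries a gap are unscored.
#'
#' @param h1,h2 equal-length gapped rows.
#' @return non-negative integer.
#' @export
mutational_distance <- function(h1, h2) {
  stopifnot(nchar(h1) == nchar(h2))
  a <- strsplit(h1, "")[[1]]
  b <- strsplit(h2, "")[[1]]
  scored <- a != "-" & b != "-"
  sum(a[scored] != b[scored])
}

#' Build a minimum spanning haplotype network
#'
#' At `epsilon = 0` (the contract-tested default) the edge set equals
#' the union of all minimum spanning trees of the complete pairwise
#' mutational-distance graph. Larger `epsilon` admits edges up to
#' `epsilon` distance units beyond the class at which their endpoints'
#' components first connect, monotonically enriching the network.
#'
#' @param haps a `haplotype_set`, or a named character vector of
#'   equal-length aligned rows.
#' @param epsilon non-negative integer tolerance.
#' @return object of class `haplotype_network`: list with `nodes`
#'   (haplotype table, when available), `aligned`, `edges` (frame:
#'   `from`, `to`, `steps`) and `distances` (integer matrix).
#' @export
build_msn <- function(haps, epsilon = 0L) {
  hset <- NULL
  if (inherits(haps, "haplotype_set")) {
    hset <- haps
    rows <- haps$aligned
  } else rows <- haps
  stopifnot(length(rows) >= 1L, epsilon >= 0L)
  n <- length(rows)
  labs <- names(rows)
  if (is.null(labs)) labs <- paste("Hap", seq_len(n))
  D <- matrix(0L, n, n, dimnames = list(labs, labs))
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- mutational_distance(rows[[i]], rows[[j]])

  edges <- data.frame(from = character(0), to = character(0),
                      steps = integer(0), stringsAsFactors = FALSE)
  if (n > 1L) {
    # class-wise Kruskal: record the class at which each pair of nodes
    # first becomes connected
    comp <- seq_len(n)
    tconn <- matrix(NA_integer_, n, n)
    for (w in sort(unique(D[upper.tri(D)]))) {
      frozen <- comp
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (D[i, j] == w && frozen[i] != frozen[j]) {
          ci <- comp[i]; cj <- comp[j]
          comp[comp == cj] <- ci
        }
      }
      newly <- outer(comp, comp, "==") & is.na(tconn)
      tconn[newly] <- w
      if (all(comp == comp[1L])) break
    }
    keep <- which(upper.tri(D) & D <= tconn + epsilon, arr.ind = TRUE)
    keep <- keep[order(D[keep], keep[, 1L], keep[, 2L]), , drop = FALSE]
    edges <- data.frame(from = labs[keep[, 1L]], to = labs[keep[, 2L]],
                        steps = D[keep], stringsAsFactors = FALSE)
  }
  structure(list(nodes = if (!is.null(hset)) hset$table else
                   data.frame(haplotype = labs, frequency = NA_integer_,
                              stringsAsFactors = FALSE),
                 members = if (!is.null(hset)) hset$members else NULL,
                 aligned = rows, edges = edges, distances = D,
                 epsilon = as.integer(epsilon)),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("Minimum spanning haplotype network:", nrow(x$nodes), "haplotypes,",
      nrow(x$edges), "edges (epsilon =", x$epsilon, ")\n")
  invisible(x)
}

#' Haplotype table and edge list of a network
#'
#' Formats the haplotype table with member lists (`"MY3233 (SAN)"` for
#' Sanger entries, `"MY4953-C1 (341)"` for consensus sequences with
#' their read counts) and a colour class per node: `"both"` when a
#' haplotype contains Sanger and PacBio members, `"sanger_only"` or
#' `"pacbio_only"` otherwise.
#'
#' @param network a `haplotype_network` built from a `haplotype_set`.
#' @return list with `haplotypes` and `edges` data.frames.
#' @export
network_report <- function(network) {
  stopifnot(inherits(network, "haplotype_network"))
  tab <- network$nodes
  mem <- network$members
  if (!is.null(mem)) {
    fmt <- ifelse(mem$source == "SAN", paste0(mem$id, " (SAN)"),
                  paste0(mem$id, " (", mem$n_reads, ")"))
    tab$sequences <- vapply(tab$haplotype, function(h)
      paste(fmt[mem$haplotype == h], collapse = "; "), character(1))
    tab$class <- vapply(tab$haplotype, function(h) {
      src <- unique(mem$source[mem$haplotype == h])
      if (all(c("SAN", "PacBio") %in% src)) "both"
      else if ("SAN" %in% src) "sanger_only" else "pacbio_only"
    }, character(1))
  }
  list(haplotypes = tab, edges = network$edges)
}
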