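# Independent oracles used across tests. These re-derive expected
# values by direct means (plain matrix dynamic programming in R,
# exhaustive enumeration) and share no code with the implementation.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Global unit-cost alignment by straightforward DP over full matrices:
# minimise cost, then maximise matches among cost-optimal alignments.
oracle_nw <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  C <- matrix(0L, n + 1L, m + 1L); M <- matrix(0L, n + 1L, m + 1L)
  C[1L, ] <- 0:m; C[, 1L] <- 0:n
  for (i in seq_len(n)) for (j in seq_len(m)) {
    eq <- A[i] == B[j]
    cc <- c(C[i, j] + !eq, C[i, j + 1L] + 1L, C[i + 1L, j] + 1L)
    mm <- c(M[i, j] + eq, M[i, j + 1L], M[i + 1L, j])
    best <- min(cc)
    C[i + 1L, j + 1L] <- best
    M[i + 1L, j + 1L] <- max(mm[cc == best])
  }
  list(cost = C[n + 1L, m + 1L], matches = M[n + 1L, m + 1L])
}

oracle_identity <- function(a, b) {
  o <- oracle_nw(a, b)
  o$matches / min(nchar(a), nchar(b))
}

oracle_p_distance <- function(a, b) {
  o <- oracle_nw(a, b)
  mism <- nchar(a) + nchar(b) - 2L * o$matches - o$cost
  mism / (o$matches + mism)
}

# Union of all minimum spanning trees of a complete weighted graph, by
# exhaustive enumeration of the (n-1)-edge subsets.
oracle_mst_union <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(cbind(from = integer(0), to = integer(0)))
  E <- t(combn(n, 2L))
  w <- D[E]
  if (n == 2L) return(cbind(from = 1L, to = 2L))
  subsets <- combn(nrow(E), n - 1L)
  best <- Inf
  in_union <- logical(nrow(E))
  for (s in seq_len(ncol(subsets))) {
    idx <- subsets[, s]
    comp <- seq_len(n)
    for (e in idx) {
      a <- E[e, 1L]; b <- E[e, 2L]
      if (comp[a] != comp[b]) comp[comp == comp[b]] <- comp[a]
    }
    if (any(comp != comp[1L])) next  # not spanning
    tw <- sum(w[idx])
    if (tw < best) { best <- tw; in_union[] <- FALSE }
    if (tw == best) in_union[idx] <- TRUE
  }
  E[in_union, , drop = FALSE]
}

# canonical "i-j" strings for edge-set comparison
edge_key <- function(from, to) {
  paste(pmin(from, to), pmax(from, to), sep = "-")
}
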