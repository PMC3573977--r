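# Independent oracles, deliberately kept apart from the implementation:
# a plain-R affine-gap Smith-Waterman scorer (Gotoh recurrences) and direct
# per-pair alignment statistics computed straight from Biostrings objects.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# exhaustive dynamic-programming local alignment score; gap of length L
# costs gap_open + L * gap_extend
sw_score_oracle <- function(a, b, mat = blosum62, gap_open = 11,
                            gap_extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (consuming b)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (consuming a)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      diag <- H[i - 1, j - 1] + mat[av[i - 1], bv[j - 1]]
      H[i, j] <- max(0, diag, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# per-pair identity/coverage computed directly on the Biostrings alignment
# object (counting logic independent of the package's align_stats)
pair_stats_oracle <- function(res_a, res_b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(res_a), Biostrings::AAString(res_b),
    type = "local", substitutionMatrix = blosum62,
    gapOpening = 11, gapExtension = 1)
  if (Biostrings::score(aln) <= 0) {
    return(list(identity = 0, cov_a = 0, cov_b = 0))
  }
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  pc <- strsplit(pat, "")[[1]]
  sc <- strsplit(sub, "")[[1]]
  list(
    identity = 100 * sum(pc == sc & pc != "-") / length(pc),
    cov_a = 100 * sum(pc != "-") / nchar(res_a),
    cov_b = 100 * sum(sc != "-") / nchar(res_b)
  )
}

# independent greedy clustering following the stated rule: longest first,
# join the first representative matched at >= min_identity with coverage of
# the shorter sequence >= min_coverage
greedy_cluster_oracle <- function(seqs, min_identity = 97,
                                  min_coverage = 90) {
  ord <- order(-nchar(seqs$residues), seq_len(nrow(seqs)))
  seqs <- seqs[ord, , drop = FALSE]
  reps <- character(0)
  out <- character(0)
  for (i in seq_len(nrow(seqs))) {
    assigned <- NA_character_
    for (r in reps) {
      rres <- seqs$residues[seqs$protein_id == r]
      st <- pair_stats_oracle(seqs$residues[i], rres)
      cov <- if (nchar(seqs$residues[i]) <= nchar(rres)) st$cov_a else
        st$cov_b
      if (st$identity >= min_identity && cov >= min_coverage) {
        assigned <- r
        break
      }
    }
    if (is.na(assigned)) {
      reps <- c(reps, seqs$protein_id[i])
      assigned <- seqs$protein_id[i]
    }
    out[seqs$protein_id[i]] <- assigned
  }
  out
}

# raw alignment score reachable from the reported bit score:
# bit = (lambda * S - ln K) / ln 2  =>  S = (bit * ln 2 + ln K) / lambda
raw_from_bits <- function(bit_score, lambda = 0.318, K = 0.13) {
  (bit_score * log(2) + log(K)) / lambda
}
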