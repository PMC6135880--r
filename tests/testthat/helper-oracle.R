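# Independent brute-force oracles and fixture builders shared across tests.

# Quadratic-space affine-gap Smith-Waterman score, written directly from the
# recurrences with full matrices (independent of the package's C++ path).
oracle_sw_score <- function(q, s, submat, gap_open, gap_extend) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  m <- length(qc); n <- length(sc)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m) + 1) {
    for (j in seq_len(n) + 1) {
      E[i, j] <- max(E[i, j - 1] - gap_extend,
                     H[i, j - 1] - gap_open - gap_extend)
      F[i, j] <- max(F[i - 1, j] - gap_extend,
                     H[i - 1, j] - gap_open - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + submat[qc[i - 1], sc[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Score of a reported alignment (aligned strings with '-' gaps) under the
# same affine model; used to verify that reported spans/identities describe
# a genuinely optimal local alignment.
rescore_alignment <- function(qaln, saln, submat, gap_open, gap_extend) {
  qc <- strsplit(qaln, "", fixed = TRUE)[[1]]
  sc <- strsplit(saln, "", fixed = TRUE)[[1]]
  stopifnot(length(qc) == length(sc))
  score <- 0
  in_gap <- FALSE
  for (k in seq_along(qc)) {
    if (qc[k] == "-" || sc[k] == "-") {
      score <- score - gap_extend - if (in_gap) 0 else gap_open
      in_gap <- TRUE
    } else {
      score <- score + submat[qc[k], sc[k]]
      in_gap <- FALSE
    }
  }
  score
}

AA20_TEST <- c("A","R","N","D","C","Q","E","G","H","I",
               "L","K","M","F","P","S","T","W","Y","V")

random_aa <- function(len) {
  paste(sample(AA20_TEST, len, replace = TRUE), collapse = "")
}

# Labeled reference + genome fixture shared by the pipeline tests.
pipeline_fixture <- function(seed = 1, n_scaffolds = 5, orfs_per_scaffold = 10,
                             n_transfers = 6, divergence = 0.1) {
  panels <- generate_reference_panels(3, 10, c(200, 40), seed = seed)
  genome <- generate_host_genome(n_scaffolds, orfs_per_scaffold,
                                 seed = seed + 1000L)
  genome <- implant_transfers(genome, panels, n_transfers, divergence,
                              seed = seed + 2000L)
  list(panels = panels, genome = genome)
}
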