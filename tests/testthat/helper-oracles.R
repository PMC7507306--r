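# Independent oracles used across tests. These never call the package's
# alignment code paths.

blosum62_test <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Gotoh affine-gap dynamic program, written independently of the package,
# returning the optimal LOCAL alignment score (gap of length L costs
# open + L * ext). Only suitable for short strings.
oracle_local_score <- function(a, b, mat = blosum62_test(),
                               open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1) # best ending in a match/mismatch (or fresh start)
  X <- matrix(NEG, n + 1, m + 1) # gap in b (consume a)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(
        0,
        M[i, j] + s, X[i, j] + s, Y[i, j] + s
      )
      X[i + 1, j + 1] <- max(
        M[i, j + 1] - open - ext, X[i, j + 1] - ext,
        Y[i, j + 1] - open - ext
      )
      Y[i + 1, j + 1] <- max(
        M[i + 1, j] - open - ext, Y[i + 1, j] - ext,
        X[i + 1, j] - open - ext
      )
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# random protein string helper
random_protein <- function(n, alphabet = c(
                             "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
                           )) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# raw (position-wise) identity for equal-length ungapped sequences
hamming_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  mean(av == bv)
}

# partition comparison: TRUE iff two cluster labelings induce the same
# partition of ids
same_partition <- function(ids, labels_a, labels_b) {
  split_a <- lapply(split(ids, labels_a), sort)
  split_b <- lapply(split(ids, labels_b), sort)
  setequal(split_a, split_b)
}
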