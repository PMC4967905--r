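# Independent oracles, written deliberately as naive full-matrix R code so
# they share no code path with the package's aligner.

# Optimal local affine-gap score; a gap of length k costs go + k*ge.
r_sw_score <- function(a, b, mat, go = 11, ge = 1) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - go - ge, E[i, j - 1] - ge)
    F[i, j] <- max(H[i - 1, j] - go - ge, F[i - 1, j] - ge)
    H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                   E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

random_protein <- function(n) {
  paste(sample(orthofixr:::AA20, n, replace = TRUE), collapse = "")
}
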