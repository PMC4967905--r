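# Amino-acid alphabet, scoring matrix plumbing, hydropathy, genetic code.
#
# Internal conventions: sequences are uppercase character scalars; encoded
# sequences are 0-based integer vectors indexing the rows of the active
# substitution matrix. One extra "mask" letter (#) with a large negative score
# against everything supports iterative hit masking.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# Robinson-Robinson style background composition over the 20 standard residues
AA_BACKGROUND <- c(
  A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019, Q = 0.043,
  E = 0.063, G = 0.074, H = 0.022, I = 0.051, L = 0.091, K = 0.057,
  M = 0.022, F = 0.039, P = 0.052, S = 0.071, T = 0.058, W = 0.013,
  Y = 0.032, V = 0.064)

# Kyte-Doolittle hydropathy
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

STRONG_HYDROPHOBIC <- c("L", "I", "V", "F")
LINKER_RESIDUES <- c("G", "S", "T", "N", "Q", "P", "E", "D", "K", "R")
MASK_CHAR <- "#"

#' BLOSUM62 substitution matrix with a masking letter
#'
#' The BLOSUM62 matrix shipped with Biostrings, extended by one row/column for
#' the internal masking letter `#`, which scores -100 against everything so
#' that masked regions can never take part in an alignment.
#'
#' @return An integer matrix with dimnames over the extended alphabet.
#' @export
blosum62_matrix <- function() {
  if (is.null(the$blosum62)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    m <- env$BLOSUM62
    ab <- c(rownames(m), MASK_CHAR)
    ext <- matrix(-100L, nrow(m) + 1L, ncol(m) + 1L, dimnames = list(ab, ab))
    ext[seq_len(nrow(m)), seq_len(ncol(m))] <- as.integer(m)
    storage.mode(ext) <- "integer"
    the$blosum62 <- ext
  }
  the$blosum62
}

# Encode a sequence as 0-based indices into the rows of `mat`.
# Unknown letters map to X when present, else error.
aa_encode <- function(x, mat = blosum62_matrix()) {
  ab <- rownames(mat)
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  idx <- match(ch, ab)
  if (anyNA(idx)) {
    xi <- match("X", ab)
    if (is.na(xi)) abort("sequence contains letters absent from the matrix")
    idx[is.na(idx)] <- xi
  }
  idx - 1L
}

aa_encode_list <- function(xs, mat = blosum62_matrix()) {
  lapply(xs, aa_encode, mat = mat)
}

# Windowed mean hydropathy; returns a numeric vector of window means, one per
# window start (length = n - window + 1), or numeric(0) for short sequences.
window_hydropathy <- function(seq, window = 19L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  kd <- unname(KD_HYDROPATHY[ch])
  kd[is.na(kd)] <- 0
  n <- length(kd)
  if (n < window) return(numeric(0))
  cs <- cumsum(c(0, kd))
  (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
}

# ---- genetic code -----------------------------------------------------------

codon_table <- function() {
  if (is.null(the$codons)) {
    gc <- Biostrings::GENETIC_CODE
    the$codons <- split(names(gc), unname(gc))
  }
  the$codons
}

# Encode a protein (no stop letter) as a CDS, appending a stop codon.
# Codon choice is uniform over synonymous codons under the current RNG state.
encode_cds <- function(protein) {
  tab <- codon_table()
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(ch, function(a) {
    opts <- tab[[a]]
    if (is.null(opts)) abort(paste0("cannot encode residue '", a, "'"))
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  stop_codon <- tab[["*"]][sample.int(3L, 1L)]
  paste0(paste(codons, collapse = ""), stop_codon)
}

translate_dna <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(dna, 1L, n)),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
}

revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

# BLOSUM62-conditional substitution kernel: P(b | a, b != a) proportional to
# background(b) * 2^(score(a,b)/2), i.e. the matrix's implied target
# frequencies restricted to off-diagonal moves.
substitution_kernel <- function() {
  if (is.null(the$subkernel)) {
    m <- blosum62_matrix()[AA20, AA20]
    k <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
    for (a in AA20) {
      w <- AA_BACKGROUND * 2 ^ (m[a, ] / 2)
      w[a] <- 0
      k[a, ] <- w / sum(w)
    }
    the$subkernel <- k
  }
  the$subkernel
}

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Uniform integer draw from [lo, hi], safe for degenerate ranges (base R's
# sample(x, ...) misbehaves when x has length one).
sample_range <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

random_aa <- function(n, residues = AA20, prob = AA_BACKGROUND[residues]) {
  paste(sample(residues, n, replace = TRUE, prob = prob), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Rewrite a sequence so that no 19-residue window exceeds a mean Kyte-Doolittle
# hydropathy of `cap`; keeps synthetic globular consensi from mimicking the
# transmembrane motif used elsewhere in the generator.
cap_hydropathy <- function(seq, cap = 2.0, window = 19L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (iter in seq_len(200L)) {
    kd <- unname(KD_HYDROPATHY[ch]); kd[is.na(kd)] <- 0
    n <- length(kd)
    if (n < window) break
    cs <- cumsum(c(0, kd))
    wm <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
    bad <- which(wm >= cap)
    if (!length(bad)) break
    w <- bad[1]
    span <- w:(w + window - 1L)
    hot <- span[which.max(kd[span])]
    ch[hot] <- sample(LINKER_RESIDUES, 1L)
  }
  paste(ch, collapse = "")
}
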