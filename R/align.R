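# Local protein alignment and six-frame translated DNA search.
#
# This is the computational substrate for best hits, partial-ortholog mapping,
# EST placement and missing-gene recovery. Scores follow the BLAST convention:
# a gap of length k costs gap_open + k * gap_extend.

#' Alignment parameters
#'
#' @param matrix Integer substitution matrix with dimnames; defaults to
#'   BLOSUM62 extended with a masking letter (see [blosum62_matrix()]).
#' @param gap_open Gap existence penalty (non-negative).
#' @param gap_extend Per-residue gap extension penalty (non-negative,
#'   `gap_open >= gap_extend`).
#' @param min_score Minimum local score for a hit to be reported by search
#'   operations.
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(matrix = blosum62_matrix(), gap_open = 11L,
                             gap_extend = 1L, min_score = 30L) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (!isTRUE(all(matrix == t(matrix))))
    abort("substitution matrix must be symmetric")
  if (gap_open < gap_extend || gap_extend < 0)
    abort("require gap_open >= gap_extend >= 0")
  structure(list(matrix = matrix, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_score = as.integer(min_score)),
            class = "alignment_params")
}

mask_index <- function(params) {
  match(MASK_CHAR, rownames(params$matrix)) - 1L
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gaps and a fixed, reproducible trace
#' (ties prefer diagonal, then up, then left). Identity is computed over all
#' aligned columns, gap columns included in the denominator.
#'
#' @param a,b Amino-acid strings (non-empty).
#' @param params An [alignment_params()] object.
#' @param query_id,target_id Optional sequence labels carried into the result.
#' @return A `local_alignment`: list with `score`, `identity`, `matches`,
#'   `aligned_columns`, 0-based half-open `query_start/end`, `target_start/end`
#'   and the per-column residue indices `query_cols`/`target_cols` (-1 = gap).
#' @export
local_align <- function(a, b, params = alignment_params(),
                        query_id = NA_character_, target_id = NA_character_) {
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  a <- toupper(a); b <- toupper(b)
  ea <- aa_encode(a, params$matrix)
  eb <- aa_encode(b, params$matrix)
  raw <- .sw_align_c(ea, eb, params$matrix, params$gap_open, params$gap_extend)
  ach <- strsplit(a, "", fixed = TRUE)[[1]]
  bch <- strsplit(b, "", fixed = TRUE)[[1]]
  cols <- length(raw$a_col)
  matches <- count_matches(raw, ach, bch)
  structure(list(
    query_id = query_id, target_id = target_id,
    score = raw$score,
    matches = as.integer(matches), aligned_columns = cols,
    identity = if (cols) matches / cols else NA_real_,
    query_start = raw$a_start, query_end = raw$a_end,
    target_start = raw$b_start, target_end = raw$b_end,
    query_cols = raw$a_col, target_cols = raw$b_col),
    class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("<local_alignment> score %d, identity %.3f over %d columns\n",
              x$score, x$identity, x$aligned_columns))
  cat(sprintf("  query  [%d, %d)  target [%d, %d)\n",
              x$query_start, x$query_end, x$target_start, x$target_end))
  invisible(x)
}

#' Percent identity of a local alignment
#'
#' Matches divided by aligned columns; gap columns count in the denominator.
#'
#' @param aln A `local_alignment`.
#' @return A fraction in `[0, 1]`.
#' @export
percent_identity <- function(aln) {
  if (is.null(aln$aligned_columns) || aln$aligned_columns == 0L)
    abort("identity undefined: alignment has zero aligned columns")
  aln$matches / aln$aligned_columns
}

# Matching columns of a traceback (gap columns never match).
count_matches <- function(raw, ach, bch) {
  ng <- raw$a_col >= 0L & raw$b_col >= 0L
  if (!any(ng)) return(0L)
  sum(ach[raw$a_col[ng] + 1L] == bch[raw$b_col[ng] + 1L])
}

# Score-only local alignment of one encoded query against encoded targets.
sw_scores <- function(query_enc, target_encs, params) {
  vapply(target_encs, function(t)
    .sw_score_c(query_enc, t, params$matrix, params$gap_open,
                params$gap_extend), integer(1))
}

# Full all-vs-all score matrix between two encoded sequence lists.
sw_score_matrix <- function(a_encs, b_encs, params) {
  .sw_score_matrix_c(a_encs, b_encs, params$matrix, params$gap_open,
                     params$gap_extend)
}

# The six translation frames of a scaffold. Returns a tibble with strand,
# frame offset (0..2 on the reported strand) and the translated aa string.
# Recently translated scaffolds are cached (translation dominates repeated
# genome scans with different queries).
six_frames <- function(scaffold) {
  cache <- the$frames_cache
  if (is.null(cache)) cache <- the$frames_cache <- list()
  for (entry in cache)
    if (identical(entry$seq, scaffold)) return(entry$frames)
  rc <- revcomp(scaffold)
  frames <- tibble(
    strand = rep(c("+", "-"), each = 3L),
    frame = rep(0:2, 2L),
    aa = c(vapply(0:2, function(f) translate_dna(substring(scaffold, f + 1L)),
                  character(1)),
           vapply(0:2, function(f) translate_dna(substring(rc, f + 1L)),
                  character(1))))
  cache[[length(cache) + 1L]] <- list(seq = scaffold, frames = frames)
  if (length(cache) > 32L) cache <- cache[-1L]
  the$frames_cache <- cache
  frames
}

# Diagonal self-alignment score of a sequence.
self_score <- function(seq, params) {
  idx <- aa_encode(seq, params$matrix) + 1L
  sum(params$matrix[cbind(idx, idx)])
}

#' Translated six-frame search of a protein against DNA
#'
#' Scans all six reading frames of `scaffold` with Smith-Waterman, iteratively
#' masking accepted hits so multiple loci per frame are reported. DNA
#' coordinates are reported on the forward strand, 0-based half-open.
#'
#' @param protein Amino-acid query string.
#' @param scaffold DNA string (length >= 3).
#' @param params An [alignment_params()]; hits with score below
#'   `params$min_score` are dropped.
#' @param max_hits_per_frame Cap on hits extracted per frame.
#' @return A tibble sorted by decreasing score with columns `strand`, `frame`,
#'   `score`, `identity`, `matches`, `aligned_columns`, `query_start`,
#'   `query_end`, `dna_start`, `dna_end`.
#' @export
translated_search <- function(protein, scaffold, params = alignment_params(),
                              max_hits_per_frame = 10L) {
  if (nchar(scaffold) < 3L) abort("scaffold shorter than one codon")
  frames <- six_frames(scaffold)
  qenc <- aa_encode(protein, params$matrix)
  L <- nchar(scaffold)
  mask <- mask_index(params)
  out <- purrr::pmap(frames, function(strand, frame, aa) {
    if (!nzchar(aa)) return(NULL)
    tenc <- aa_encode(aa, params$matrix)
    ach <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
    tch <- strsplit(aa, "", fixed = TRUE)[[1]]
    hits <- list()
    for (k in seq_len(max_hits_per_frame)) {
      # cheap score-only screen before each traceback pass
      if (.sw_score_c(qenc, tenc, params$matrix, params$gap_open,
                      params$gap_extend) < params$min_score) break
      raw <- .sw_align_c(qenc, tenc, params$matrix, params$gap_open,
                         params$gap_extend)
      cols <- length(raw$a_col)
      matches <- count_matches(raw, ach, tch)
      if (strand == "+") {
        dna_start <- frame + 3L * raw$b_start
        dna_end <- frame + 3L * raw$b_end
      } else {
        dna_start <- L - (frame + 3L * raw$b_end)
        dna_end <- L - (frame + 3L * raw$b_start)
      }
      hits[[k]] <- tibble(
        strand = strand, frame = frame, score = raw$score,
        identity = matches / cols, matches = as.integer(matches),
        aligned_columns = cols,
        query_aligned = sum(raw$a_col >= 0L & raw$b_col >= 0L),
        query_start = raw$a_start, query_end = raw$a_end,
        dna_start = dna_start, dna_end = dna_end)
      tenc[(raw$b_start + 1L):raw$b_end] <- mask
    }
    bind_rows(hits)
  })
  res <- bind_rows(out)
  if (!nrow(res)) {
    return(tibble(strand = character(), frame = integer(), score = integer(),
                  identity = double(), matches = integer(),
                  aligned_columns = integer(), query_aligned = integer(),
                  query_start = integer(), query_end = integer(),
                  dna_start = integer(), dna_end = integer()))
  }
  arrange(res, desc(.data$score), .data$dna_start)
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the standard whitespace-delimited matrix layout used by BLAST
#' (`#` comment lines, a header row of letters, one labelled row per letter)
#' and appends the package's masking letter.
#'
#' @param path Path to the matrix file.
#' @return An integer matrix suitable for [alignment_params()].
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  labs <- vapply(rows, `[`, character(1), 1L)
  vals <- t(vapply(rows, function(r) as.integer(r[-1]),
                   integer(length(header))))
  dimnames(vals) <- list(labs, header)
  vals <- vals[header, header, drop = FALSE]  # canonical order
  ab <- c(header, MASK_CHAR)
  ext <- matrix(-100L, length(ab), length(ab), dimnames = list(ab, ab))
  ext[header, header] <- vals
  storage.mode(ext) <- "integer"
  ext
}
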