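# Reciprocal best-hit orthology and iterated partial-ortholog mapping.

# Resolve the best target index for one row of a score matrix.
# Ties: higher identity of the full alignment, then lexicographic target id.
best_index <- function(scores, query_seq, target_seqs, target_ids, params) {
  top <- max(scores)
  cand <- which(scores == top)
  if (length(cand) > 1L) {
    ids <- vapply(cand, function(j)
      local_align(query_seq, target_seqs[[j]], params)$identity, numeric(1))
    cand <- cand[ids == max(ids)]
    if (length(cand) > 1L)
      cand <- cand[order(target_ids[cand])][1L]
  }
  cand[1L]
}

#' Best local-alignment hit of a query in a proteome
#'
#' @param query Amino-acid string.
#' @param targets An [annotated_proteome()] or a named character vector of
#'   protein sequences.
#' @param params An [alignment_params()]; `NULL` is returned when no target
#'   reaches `params$min_score`.
#' @param query_id Label carried into the result.
#' @return A `local_alignment` against the winning target, or `NULL`.
#' @export
best_hit <- function(query, targets, params = alignment_params(),
                     query_id = NA_character_) {
  seqs <- if (inherits(targets, "annotated_proteome"))
    proteome_seqs(targets) else targets
  if (!length(seqs)) abort("no targets")
  qenc <- aa_encode(query, params$matrix)
  tencs <- aa_encode_list(seqs, params$matrix)
  scores <- sw_scores(qenc, tencs, params)
  if (max(scores) < params$min_score) return(NULL)
  j <- best_index(scores, query, as.list(seqs), names(seqs), params)
  local_align(query, seqs[[j]], params, query_id = query_id,
              target_id = names(seqs)[j])
}

# Internal RBH engine over a precomputed score matrix.
rbh_from_matrix <- function(scores, a_seqs, b_seqs, min_identity, params) {
  a_ids <- names(a_seqs); b_ids <- names(b_seqs)
  best_b <- vapply(seq_along(a_seqs), function(i)
    best_index(scores[i, ], a_seqs[[i]], b_seqs, b_ids, params), integer(1))
  best_a <- vapply(seq_along(b_seqs), function(j)
    best_index(scores[, j], b_seqs[[j]], a_seqs, a_ids, params), integer(1))
  rows <- list()
  for (i in seq_along(a_seqs)) {
    j <- best_b[i]
    if (best_a[j] != i) next
    if (scores[i, j] < params$min_score) next
    aln <- local_align(a_seqs[[i]], b_seqs[[j]], params,
                       query_id = a_ids[i], target_id = b_ids[j])
    if (aln$identity < min_identity) next
    rows[[length(rows) + 1L]] <- tibble(
      a_id = a_ids[i], b_id = b_ids[j], score = aln$score,
      identity = aln$identity,
      a_start = aln$query_start, a_end = aln$query_end,
      b_start = aln$target_start, b_end = aln$target_end,
      reciprocal = TRUE)
  }
  out <- bind_rows(rows)
  if (!nrow(out))
    out <- tibble(a_id = character(), b_id = character(), score = integer(),
                  identity = double(), a_start = integer(),
                  a_end = integer(), b_start = integer(), b_end = integer(),
                  reciprocal = logical())
  out
}

#' Reciprocal best-hit ortholog pairs
#'
#' A pair (a, b) is emitted iff b is a's best hit, a is b's best hit, and the
#' pairwise identity (over aligned columns) reaches `min_identity`. Each
#' protein appears in at most one pair.
#'
#' @param A,B [annotated_proteome()]s (or named sequence vectors).
#' @param min_identity Identity cutoff in `[0, 1]` (default 0.60).
#' @param params An [alignment_params()].
#' @return Tibble `a_id`, `b_id`, `score`, `identity`, matched intervals
#'   (0-based half-open) and `reciprocal`.
#' @export
reciprocal_best_hits <- function(A, B, min_identity = 0.60,
                                 params = alignment_params()) {
  if (min_identity < 0 || min_identity > 1)
    abort("min_identity must lie in [0, 1]")
  a_seqs <- if (inherits(A, "annotated_proteome")) proteome_seqs(A) else A
  b_seqs <- if (inherits(B, "annotated_proteome")) proteome_seqs(B) else B
  a_encs <- aa_encode_list(a_seqs, params$matrix)
  b_encs <- aa_encode_list(b_seqs, params$matrix)
  scores <- sw_score_matrix(a_encs, b_encs, params)
  rbh_from_matrix(scores, as.list(a_seqs), as.list(b_seqs), min_identity,
                  params)
}

# Fraction of the shorter of two intervals shared with the other.
interval_overlap_fraction <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2)
  if (ov <= 0) return(0)
  ov / min(e1 - s1, e2 - s2)
}

#' Map partial orthologs onto split-gene topologies
#'
#' Finds intact proteins in one proteome that are hit by two or more
#' partner-species proteins on near-disjoint intervals (mutual overlap below
#' `max_overlap` of the shorter interval) -- the signature of a gene split
#' into fragments in the partner proteome. Fragments whose own sequence is
#' mostly unexplained by the intact protein are flagged as chimeric
#' candidates.
#'
#' @param single_proteome Proteome holding the intact ("single") proteins.
#' @param fragment_proteome Partner proteome whose proteins may be fragments.
#' @param params An [alignment_params()].
#' @param max_overlap Mutual-overlap tolerance (default 0.2).
#' @param scores Optional precomputed score matrix
#'   (fragments x singles) to avoid re-alignment.
#' @return Tibble with `single_id`, `fragment_ids` (list), of the fragments
#'   ordered by position on the single protein, `fragment_intervals` (list of
#'   matrices, rows = `start`,`end` on the single protein),
#'   `chimeric_candidates` (list of logicals), `adjacency` (`NA`, fill via
#'   [classify_adjacency()]).
#' @export
map_partial_orthologs <- function(single_proteome, fragment_proteome,
                                  params = alignment_params(),
                                  max_overlap = 0.2, scores = NULL) {
  s_seqs <- if (inherits(single_proteome, "annotated_proteome"))
    proteome_seqs(single_proteome) else single_proteome
  f_seqs <- if (inherits(fragment_proteome, "annotated_proteome"))
    proteome_seqs(fragment_proteome) else fragment_proteome
  if (is.null(scores)) {
    scores <- sw_score_matrix(aa_encode_list(f_seqs, params$matrix),
                              aa_encode_list(s_seqs, params$matrix), params)
  }
  f_ids <- names(f_seqs); s_ids <- names(s_seqs)
  best_s <- vapply(seq_along(f_seqs), function(i)
    best_index(scores[i, ], f_seqs[[i]], as.list(s_seqs), s_ids, params),
    integer(1))
  ok <- vapply(seq_along(f_seqs), function(i)
    scores[i, best_s[i]] >= params$min_score, logical(1))
  rows <- list()
  for (j in seq_along(s_seqs)) {
    frs <- which(best_s == j & ok)
    if (length(frs) < 2L) next
    alns <- lapply(frs, function(i)
      local_align(f_seqs[[i]], s_seqs[[j]], params, query_id = f_ids[i],
                  target_id = s_ids[j]))
    iv <- t(vapply(alns, function(a) c(a$target_start, a$target_end),
                   numeric(2)))
    # require pairwise near-disjoint intervals on the single protein
    disjoint <- TRUE
    for (x in seq_len(nrow(iv) - 1L)) for (y in (x + 1L):nrow(iv)) {
      if (interval_overlap_fraction(iv[x, 1], iv[x, 2],
                                    iv[y, 1], iv[y, 2]) >= max_overlap)
        disjoint <- FALSE
    }
    if (!disjoint) next
    ord <- order(iv[, 1])
    chim <- vapply(alns, function(a) {
      covered <- (a$query_end - a$query_start) / nchar(f_seqs[[a$query_id]])
      covered < 0.7
    }, logical(1))
    colnames(iv) <- c("start", "end")
    rows[[length(rows) + 1L]] <- tibble(
      single_id = s_ids[j],
      fragment_ids = list(f_ids[frs][ord]),
      fragment_intervals = list(iv[ord, , drop = FALSE]),
      chimeric_candidates = list(chim[ord]),
      adjacency = NA_character_)
  }
  out <- bind_rows(rows)
  if (!nrow(out))
    out <- tibble(single_id = character(), fragment_ids = list(),
                  fragment_intervals = list(), chimeric_candidates = list(),
                  adjacency = character())
  out
}

#' Classify the genomic adjacency of split-gene fragments
#'
#' @param mapping One row of the tibble from [map_partial_orthologs()].
#' @param annotation Proteins tibble (or [annotated_proteome()]) of the
#'   fragment species, providing `scaffold_id`, `strand`, `cds_start`.
#' @return `"same_scaffold_adjacent"` if the fragments occupy consecutive
#'   gene loci on one scaffold in the order of their intervals,
#'   `"same_scaffold_distant"` otherwise on one scaffold, or
#'   `"cross_scaffold"`.
#' @export
classify_adjacency <- function(mapping, annotation) {
  ann <- if (inherits(annotation, "annotated_proteome"))
    annotation$proteins else annotation
  ids <- mapping$fragment_ids[[1]]
  if (length(ids) < 2L)
    abort("adjacency undefined for single-fragment mappings")
  rows <- ann[match(ids, ann$protein_id), ]
  if (anyNA(rows$protein_id))
    abort("fragment ids missing from the annotation")
  if (length(unique(rows$scaffold_id)) > 1L) return("cross_scaffold")
  # loci on this scaffold in genomic order
  sc <- ann %>% filter(.data$scaffold_id == rows$scaffold_id[1]) %>%
    arrange(.data$cds_start)
  pos <- match(ids, sc$protein_id)
  # the fragments are ordered by protein-interval; on the plus strand that
  # must correspond to ascending loci, on the minus strand descending
  step <- if (all(rows$strand == "-")) -1L else 1L
  consecutive <- all(diff(pos) == step)
  if (consecutive) "same_scaffold_adjacent" else "same_scaffold_distant"
}
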