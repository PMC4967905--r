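# Domain calling against the family catalog and comparison of architectures
# as linear family-name sequences.

consensus_self_scores <- function(catalog, params) {
  m <- params$matrix
  vapply(catalog$consensus, function(cs) {
    idx <- aa_encode(cs, m) + 1L
    sum(m[cbind(idx, idx)])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Call domains on a protein
#'
#' Each family's consensus is locally aligned against the protein, accepted
#' hits are masked and the family re-scanned so tandem repeats are recovered.
#' A hit is accepted when its score reaches `min_fraction_of_max_score` times
#' the consensus self-score. Overlapping hits across families are resolved by
#' keeping the higher score (ties: longer hit, then earlier start).
#'
#' @param protein Amino-acid string.
#' @param catalog Tibble from [build_domain_catalog()].
#' @param min_fraction_of_max_score Acceptance threshold as a fraction of the
#'   consensus self-score; the default 0.45 keeps drastically truncated
#'   domains (about half the family mean) detectable.
#' @param params An [alignment_params()].
#' @param protein_id Label carried into the result.
#' @param max_hits_per_family Cap on tandem copies per family.
#' @return Tibble `protein_id`, `family`, `start`, `end` (0-based half-open),
#'   `score`, `length_fraction`, sorted by `start`.
#' @export
call_domains <- function(protein, catalog,
                         min_fraction_of_max_score = 0.45,
                         params = alignment_params(),
                         protein_id = NA_character_,
                         max_hits_per_family = 12L) {
  if (!nrow(catalog)) abort("empty domain catalog")
  m <- params$matrix
  selfs <- consensus_self_scores(catalog, params)
  penc <- aa_encode(protein, m)
  mask <- mask_index(params)
  hits <- list()
  for (f in seq_len(nrow(catalog))) {
    cenc <- aa_encode(catalog$consensus[f], m)
    thr <- min_fraction_of_max_score * selfs[f]
    tenc <- penc
    for (k in seq_len(max_hits_per_family)) {
      raw <- .sw_align_c(cenc, tenc, m, params$gap_open, params$gap_extend)
      if (raw$score < thr) break
      hits[[length(hits) + 1L]] <- tibble(
        family = catalog$family[f],
        start = raw$b_start, end = raw$b_end, score = raw$score,
        length_fraction = (raw$b_end - raw$b_start) /
          catalog$mean_length[f])
      tenc[(raw$b_start + 1L):raw$b_end] <- mask
    }
  }
  hits <- bind_rows(hits)
  if (!nrow(hits)) {
    return(tibble(protein_id = character(), family = character(),
                  start = integer(), end = integer(), score = integer(),
                  length_fraction = double()))
  }
  hits <- resolve_overlaps(hits)
  hits %>%
    mutate(protein_id = protein_id, .before = 1L) %>%
    arrange(.data$start)
}

# Greedy overlap resolution: rank by score, then length, then start, then
# family name; a hit survives if it overlaps every accepted hit by less than
# 20% of the shorter of the two.
resolve_overlaps <- function(hits, max_overlap = 0.2) {
  ord <- order(-hits$score, -(hits$end - hits$start), hits$start,
               hits$family)
  hits <- hits[ord, ]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    for (j in which(keep)) {
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
      shorter <- min(hits$end[i] - hits$start[i],
                     hits$end[j] - hits$start[j])
      if (ov > max_overlap * shorter) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  hits[keep, ]
}

#' Call domains across a whole proteome
#'
#' @param proteome An [annotated_proteome()].
#' @inheritParams call_domains
#' @return One tibble of hits for all proteins.
#' @export
call_domains_proteome <- function(proteome, catalog,
                                  min_fraction_of_max_score = 0.45,
                                  params = alignment_params()) {
  rows <- purrr::map2(proteome$proteins$seq, proteome$proteins$protein_id,
                      function(s, id)
                        call_domains(s, catalog, min_fraction_of_max_score,
                                     params, protein_id = id))
  bind_rows(rows)
}

arch_families <- function(x) {
  if (is.character(x)) return(x)
  if (is.data.frame(x)) {
    x <- arrange(x, .data$start)
    return(x$family)
  }
  abort("expected a family-name vector or a domain-hit tibble")
}

#' Compare two domain architectures
#'
#' Architectures are ordered family-name sequences; repeat counts are
#' significant (set `collapse_repeats = TRUE` to score repeat-run length
#' differences as identical). Non-identical pairs are classified into a
#' minimal edit category.
#'
#' @param a,b Family-name character vectors or domain-hit tibbles.
#' @param collapse_repeats Collapse tandem runs before comparison.
#' @return An `arch_comparison`: list with `identical`, `edit` (one of
#'   `none`, `n_terminal_extension`, `c_terminal_extension`,
#'   `internal_insertion`, `internal_deletion`, `repeat_count_change`,
#'   `other`), `details`, `surplus_side` (`"a"`, `"b"` or `NA`), and the
#'   shared `prefix`/`suffix` lengths.
#' @export
compare_architectures <- function(a, b, collapse_repeats = FALSE) {
  ax <- arch_families(a)
  bx <- arch_families(b)
  if (collapse_repeats) {
    ax <- rle(ax)$values
    bx <- rle(bx)$values
  }
  res <- function(edit, details, side = NA_character_, p = 0L, s = 0L)
    structure(list(identical = edit == "none", edit = edit,
                   details = details, surplus_side = side,
                   prefix = p, suffix = s, a = ax, b = bx),
              class = "arch_comparison")
  if (identical(ax, bx)) return(res("none", "identical architectures"))
  # same succession of families, only repeat-run lengths differ
  if (identical(rle(ax)$values, rle(bx)$values))
    return(res("repeat_count_change",
               "same family succession, different repeat-run lengths"))
  na <- length(ax); nb <- length(bx)
  p <- 0L
  while (p < min(na, nb) && ax[p + 1L] == bx[p + 1L]) p <- p + 1L
  s <- 0L
  while (s < min(na, nb) - p && ax[na - s] == bx[nb - s]) s <- s + 1L
  ra <- if (na - s >= p + 1L) ax[(p + 1L):(na - s)] else character(0)
  rb <- if (nb - s >= p + 1L) bx[(p + 1L):(nb - s)] else character(0)
  if (!length(ra) || !length(rb)) {
    side <- if (length(rb)) "b" else "a"
    surplus <- if (length(rb)) rb else ra
    lab <- paste0(side, " carries surplus [",
                  paste(surplus, collapse = ","), "]")
    edit <- if (s == 0L && p > 0L) "c_terminal_extension"
    else if (p == 0L && s > 0L) "n_terminal_extension"
    else if (p > 0L && s > 0L)
      if (side == "b") "internal_insertion" else "internal_deletion"
    else "other"  # no shared flank at all
    return(res(edit, lab, side, p, s))
  }
  res("other", sprintf("shared prefix %d, suffix %d; divergent cores", p, s),
      NA_character_, p, s)
}

#' @export
print.arch_comparison <- function(x, ...) {
  cat(sprintf("<arch_comparison> %s (%s)\n  a: %s\n  b: %s\n",
              if (x$identical) "identical" else "different", x$edit,
              paste(x$a, collapse = ","), paste(x$b, collapse = ",")))
  invisible(x)
}

#' Reconstruct the architecture of a split gene from its fragments
#'
#' Concatenates fragment architectures in single-protein coordinate order,
#' de-duplicating boundary hits of the same family that overlap once
#' projected onto the intact partner's coordinates.
#'
#' @param fragments List of domain-hit tibbles, one per fragment, ordered as
#'   in `mapping`.
#' @param mapping A split mapping row (see [map_partial_orthologs()]) whose
#'   `fragment_intervals` give each fragment's interval on the intact
#'   protein.
#' @return A single domain-hit tibble in projected coordinates.
#' @export
architecture_of_union <- function(fragments, mapping) {
  iv <- mapping$fragment_intervals[[1]]
  if (length(fragments) != nrow(iv))
    abort("fragments must match the mapping, in order")
  if (is.unsorted(iv[, 1])) abort("fragments must be ordered by interval")
  if (!is.null(mapping$fragment_ids)) {
    want <- mapping$fragment_ids[[1]]
    got <- vapply(fragments, function(fr)
      if (nrow(fr) && "protein_id" %in% names(fr)) fr$protein_id[1]
      else NA_character_, character(1))
    if (!anyNA(got) && !identical(got, want))
      abort("fragments must be supplied in mapping order")
  }
  proj <- purrr::imap(fragments, function(fr, k) {
    if (!nrow(fr)) return(fr)
    fr %>% arrange(.data$start) %>%
      mutate(start = .data$start + iv[k, 1], end = .data$end + iv[k, 1])
  })
  out <- bind_rows(proj) %>% arrange(.data$start)
  if (nrow(out) < 2L) return(out)
  keep <- rep(TRUE, nrow(out))
  for (i in 2:nrow(out)) {
    j <- max(which(keep[seq_len(i - 1L)]))
    ov <- min(out$end[i], out$end[j]) - max(out$start[i], out$start[j])
    shorter <- min(out$end[i] - out$start[i], out$end[j] - out$start[j])
    if (out$family[i] == out$family[j] && ov > 0.5 * shorter) {
      # same boundary domain seen from both fragments: keep the higher score
      if (!is.null(out$score) && out$score[i] > out$score[j]) keep[j] <- FALSE
      else keep[i] <- FALSE
    }
  }
  out[keep, ]
}
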