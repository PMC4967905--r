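# Misprediction rules ("dogmas"), EST junction tests, tiered correction and
# translated recovery of missing genes.
#
# Two rules are implemented: (1) extracellular and intracellular domains
# co-occurring without an intervening transmembrane segment; (2) drastic
# truncation of a globular domain relative to its family mean length.
# Corrections follow a fixed evidence-tier precedence: transcript (EST)
# evidence first, then translated genome search, then ortholog projection.

#' Detect transmembrane segments by windowed hydropathy
#'
#' Mean Kyte-Doolittle hydropathy over a sliding window; windows at or above
#' the threshold are unioned and merged into segments.
#'
#' @param protein Amino-acid string.
#' @param window Window width in residues (default 19).
#' @param threshold Mean-hydropathy threshold (default 2.5).
#' @return Tibble `start`, `end` (0-based half-open), possibly empty.
#' @export
detect_tm_segments <- function(protein, window = 19L, threshold = 2.5) {
  wm <- window_hydropathy(protein, window)
  hot <- which(wm >= threshold)
  if (!length(hot))
    return(tibble(start = integer(), end = integer()))
  starts <- hot - 1L            # 0-based window starts
  ends <- hot - 1L + window
  keep_s <- c(starts[1], starts[which(diff(hot) > window) + 1L])
  keep_e <- c(ends[which(diff(hot) > window)], ends[length(ends)])
  tibble(start = as.integer(keep_s), end = as.integer(keep_e))
}

# Signal-peptide stand-in: initial methionine followed by a strongly
# hydrophobic stretch.
has_signal_motif <- function(protein, threshold = 2.5) {
  if (substr(protein, 1L, 1L) != "M" || nchar(protein) < 13L) return(FALSE)
  ch <- strsplit(substr(protein, 2L, 13L), "", fixed = TRUE)[[1]]
  kd <- unname(KD_HYDROPATHY[ch]); kd[is.na(kd)] <- 0
  mean(kd) >= threshold
}

#' Flag extracellular/intracellular domain co-occurrence
#'
#' A protein violates the localization rule when an extracellular-class and
#' an intracellular-class domain co-occur with no transmembrane segment
#' between them in sequence order. Families of class `"either"` never
#' trigger.
#'
#' @param arch Domain-hit tibble for one protein.
#' @param catalog Domain catalog providing localization classes.
#' @param tm Tibble of TM segments (e.g. from [detect_tm_segments()]).
#' @return A `dogma_flag` list, or `NULL`.
#' @export
check_localization_conflict <- function(arch, catalog, tm) {
  if (!nrow(arch)) return(NULL)
  loc <- catalog$localization[match(arch$family, catalog$family)]
  if (anyNA(loc)) abort("architecture contains families absent from catalog")
  ex <- which(loc == "extracellular")
  ic <- which(loc == "intracellular")
  if (!length(ex) || !length(ic)) return(NULL)
  for (i in ex) for (j in ic) {
    first <- if (arch$start[i] <= arch$start[j]) i else j
    second <- if (first == i) j else i
    gap_s <- arch$end[first]; gap_e <- arch$start[second]
    separated <- FALSE
    if (nrow(tm)) {
      inter <- pmin(tm$end, gap_e) - pmax(tm$start, gap_s)
      separated <- any(inter >= 10L)
    }
    if (!separated) {
      return(structure(list(
        protein_id = arch$protein_id[1], rule = "localization_conflict",
        evidence = sprintf(
          "%s (extracellular) and %s (intracellular) co-occur with no TM between",
          arch$family[i], arch$family[j]),
        involved_hits = arch[c(first, second), ]), class = "dogma_flag"))
    }
  }
  NULL
}

#' Flag drastic truncation of a globular domain
#'
#' @param hit One domain-hit row with `length_fraction`.
#' @param catalog Domain catalog (for the evidence message).
#' @param threshold Flag iff `length_fraction < threshold` (strict; default
#'   0.6).
#' @return A `dogma_flag` list, or `NULL`.
#' @export
check_truncation <- function(hit, catalog, threshold = 0.6) {
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  if (hit$length_fraction >= threshold) return(NULL)
  ml <- catalog$mean_length[match(hit$family, catalog$family)]
  structure(list(
    protein_id = if ("protein_id" %in% names(hit)) hit$protein_id[1]
    else NA_character_,
    rule = "domain_truncation",
    evidence = sprintf(
      "%s hit covers %d of %d family-mean residues (fraction %.3f)",
      hit$family, hit$end - hit$start, ml, hit$length_fraction),
    involved_hits = hit), class = "dogma_flag")
}

#' @export
print.dogma_flag <- function(x, ...) {
  cat(sprintf("<dogma_flag> %s on %s: %s\n", x$rule, x$protein_id,
              x$evidence))
  invisible(x)
}

# Map an EST onto a protein by translated alignment; returns the protein-space
# interval of the best placement or NULL below min_score.
map_est_to_protein <- function(protein, est_seq, params) {
  hits <- translated_search(protein, est_seq, params,
                            max_hits_per_frame = 2L)
  if (!nrow(hits)) return(NULL)
  hits[1, ]
}

#' Test a putative fusion junction against EST evidence
#'
#' ESTs are placed on the protein by translated alignment. A spanning EST
#' covers at least `window` residues on both sides of the junction and
#' supports it; a refuting EST either ends with a stop codon at or before the
#' junction (within the window) or starts (5' end / signal peptide) at or
#' after it. The verdict is `supported` when any EST spans, `refuted` when
#' boundary-defining ESTs exist and none spans, otherwise `no_evidence`.
#'
#' @param protein Amino-acid string of the suspect protein.
#' @param junction Protein coordinate (0-based) of the putative junction.
#' @param ests EST tibble (see [generate_ests()]).
#' @param window Residues required on both sides for spanning, and the
#'   tolerance for boundary evidence (default 30).
#' @param params An [alignment_params()].
#' @param protein_id Label carried into the result.
#' @return A `junction_verdict` list.
#' @export
test_fusion_junction <- function(protein, junction, ests, window = 30L,
                                 params = alignment_params(),
                                 protein_id = NA_character_) {
  if (junction < 0 || junction > nchar(protein))
    abort("junction outside the protein")
  supporting <- character(0); refuting <- character(0)
  for (k in seq_len(nrow(ests))) {
    hit <- map_est_to_protein(protein, ests$seq[k], params)
    if (is.null(hit)) next
    qs <- hit$query_start; qe <- hit$query_end
    if (qs <= junction - window && qe >= junction + window) {
      supporting <- c(supporting, ests$est_id[k])
      next
    }
    stop_refutes <- isTRUE(ests$includes_stop[k]) &&
      abs(qe - junction) <= window
    start_refutes <- isTRUE(ests$includes_start[k]) &&
      abs(qs - junction) <= window
    if (stop_refutes || start_refutes)
      refuting <- c(refuting, ests$est_id[k])
  }
  verdict <- if (length(supporting)) "supported"
  else if (length(refuting)) "refuted"
  else "no_evidence"
  structure(list(protein_id = protein_id, junction = junction,
                 verdict = verdict, supporting_est_ids = supporting,
                 refuting_est_ids = refuting),
            class = "junction_verdict")
}

#' @export
print.junction_verdict <- function(x, ...) {
  cat(sprintf("<junction_verdict> %s at %d on %s (%d supporting, %d refuting)\n",
              x$verdict, x$junction, x$protein_id,
              length(x$supporting_est_ids), length(x$refuting_est_ids)))
  invisible(x)
}

#' Compare an ortholog pair against a trusted reference proteome
#'
#' The reference ortholog is found by best hit (score threshold only, no
#' identity cutoff); both members' architectures are compared with the
#' reference architecture.
#'
#' @param a_arch,b_arch Domain-hit tibbles of the two members.
#' @param a_seq Sequence used to locate the reference ortholog.
#' @param reference An [annotated_proteome()] whose `domains` table holds the
#'   trusted architectures.
#' @param params An [alignment_params()].
#' @return A list with `agreement` (one of `both`, `a_only`, `b_only`,
#'   `neither`, `no_reference`) and `reference_id`.
#' @export
classify_against_reference <- function(a_arch, b_arch, a_seq, reference,
                                       params = alignment_params()) {
  hit <- best_hit(a_seq, reference, params)
  if (is.null(hit))
    return(list(agreement = "no_reference", reference_id = NA_character_))
  ref_arch <- reference$domains %>%
    filter(.data$protein_id == hit$target_id) %>% arrange(.data$start)
  a_same <- compare_architectures(a_arch, ref_arch)$identical
  b_same <- compare_architectures(b_arch, ref_arch)$identical
  agreement <- if (a_same && b_same) "both" else if (a_same) "a_only"
  else if (b_same) "b_only" else "neither"
  list(agreement = agreement, reference_id = hit$target_id)
}

# ESTs plausibly originating from a predicted gene's locus: exact-substring
# screen of each EST (or its reverse complement) against the annotated
# region. Works because transcripts are error-free copies of their gene.
ests_at_locus <- function(ests, proteome, protein_row, margin = 1000L) {
  if (!nrow(ests)) return(ests)
  sc <- scaffold_seq(proteome, protein_row$scaffold_id)
  region <- substr(sc, max(0L, protein_row$cds_start - margin) + 1L,
                   min(nchar(sc), protein_row$cds_end + margin))
  keep <- vapply(ests$seq, function(s)
    grepl(s, region, fixed = TRUE) || grepl(revcomp(s), region, fixed = TRUE),
    logical(1), USE.NAMES = FALSE)
  ests[keep, ]
}

correction_result <- function(original_ids, action, tier,
                              corrected_architecture = NULL,
                              corrected_seq = NA_character_,
                              details = "", supporting_est_ids = character(0),
                              gene_model = NULL) {
  structure(list(
    original_ids = original_ids, action = action, evidence_tier = tier,
    corrected_architecture = corrected_architecture %||%
      tibble(protein_id = character(), family = character(),
             start = integer(), end = integer(), score = integer(),
             length_fraction = double()),
    corrected_seq = corrected_seq, details = details,
    supporting_est_ids = supporting_est_ids, gene_model = gene_model),
    class = "correction_result")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("<correction_result> action %s (tier %s) on %s\n", x$action,
              x$evidence_tier, paste(x$original_ids, collapse = ",")))
  invisible(x)
}

#' Recover a missing gene by translated genome search
#'
#' Scans every scaffold in all six frames with the query protein; if a chain
#' of hits on one scaffold and strand covers at least `min_coverage` of the
#' query, a gene model is built from the chained region, translated, and its
#' domains called. ESTs matching the locus are recorded as confirmation.
#'
#' @param query Amino-acid string (a protein with no reciprocal best hit).
#' @param scaffolds An [annotated_proteome()] (its scaffolds are searched) or
#'   a tibble with `scaffold_id`, `seq`.
#' @param ests EST tibble of the searched species (may be empty).
#' @param catalog Domain catalog for re-calling domains on the rebuilt model.
#' @param params An [alignment_params()].
#' @param min_coverage Minimum fraction of the query covered by the hit chain.
#' @param min_fraction_of_max_score Domain-call threshold for the rebuilt
#'   model.
#' @param min_score_fraction Genome-scan score threshold as a fraction of the
#'   query self-score (keeps the scan focused on near-full-length loci).
#' @return A `correction_result` with action `recover_gene`, or `NULL`.
#' @export
find_missing_gene <- function(query, scaffolds, ests = NULL, catalog = NULL,
                              params = alignment_params(),
                              min_coverage = 0.8,
                              min_fraction_of_max_score = 0.45,
                              min_score_fraction = 0.25) {
  sc_tbl <- if (inherits(scaffolds, "annotated_proteome"))
    scaffolds$scaffolds else as_tibble(scaffolds)
  params <- scan_params(query, params, min_score_fraction)
  best <- NULL
  for (i in seq_len(nrow(sc_tbl))) {
    hits <- translated_search(query, sc_tbl$seq[i], params)
    cand <- best_gene_chain(hits, nchar(query), min_coverage)
    if (is.null(cand)) next
    cand$scaffold_id <- sc_tbl$scaffold_id[i]
    cand$scaffold_seq <- sc_tbl$seq[i]
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  if (is.null(best)) return(NULL)
  dna <- substr(best$scaffold_seq, best$dna_start + 1L, best$dna_end)
  if (best$strand == "-") dna <- revcomp(dna)
  model_protein <- translate_dna(dna)
  model_protein <- sub("\\*.*$", "", model_protein)
  arch <- if (!is.null(catalog))
    call_domains(model_protein, catalog, min_fraction_of_max_score, params,
                 protein_id = "recovered") else NULL
  est_ids <- character(0)
  if (!is.null(ests) && nrow(ests)) {
    region <- substr(best$scaffold_seq,
                     max(0L, best$dna_start - 1000L) + 1L,
                     min(nchar(best$scaffold_seq), best$dna_end + 1000L))
    keep <- vapply(ests$seq, function(s)
      grepl(s, region, fixed = TRUE) ||
        grepl(revcomp(s), region, fixed = TRUE), logical(1),
      USE.NAMES = FALSE)
    est_ids <- ests$est_id[keep]
  }
  correction_result(
    original_ids = character(0), action = "recover_gene",
    tier = "translated_genome_search", corrected_architecture = arch,
    corrected_seq = model_protein,
    details = sprintf("rebuilt on %s:%d-%d(%s), query coverage %.2f",
                      best$scaffold_id, best$dna_start, best$dna_end,
                      best$strand, best$coverage),
    supporting_est_ids = est_ids,
    gene_model = tibble(scaffold_id = best$scaffold_id,
                        strand = best$strand, cds_start = best$dna_start,
                        cds_end = best$dna_end))
}

# Pick the best gene-model chain from translated-search hits. Genes are
# intronless, so a single hit covering the query is preferred; failing that,
# a greedy collinear chain of near-disjoint hits (same strand, consistent
# query/DNA order, gaps below max_gap) is assembled. Returns NULL when no
# candidate covers at least min_coverage of the query.
best_gene_chain <- function(hits, qlen, min_coverage = 0.8,
                            max_gap = 1000L) {
  if (is.null(hits) || !nrow(hits)) return(NULL)
  cand <- NULL
  consider <- function(ds, de, strand, score, cov) {
    if (cov >= min_coverage && (is.null(cand) || score > cand$score))
      cand <<- list(strand = strand, dna_start = ds, dna_end = de,
                    score = score, coverage = cov)
  }
  for (k in seq_len(nrow(hits)))
    consider(hits$dna_start[k], hits$dna_end[k], hits$strand[k],
             hits$score[k], hits$query_aligned[k] / qlen)
  if (!is.null(cand)) return(cand)
  for (grp in split(hits, hits$strand)) {
    sel <- integer(0)
    for (k in order(-grp$score)) {
      ok <- TRUE
      for (j in sel) {
        qo <- interval_overlap_fraction(grp$query_start[k],
                                        grp$query_end[k],
                                        grp$query_start[j],
                                        grp$query_end[j])
        if (qo >= 0.2) { ok <- FALSE; break }
        dgap <- max(grp$dna_start[k], grp$dna_start[j]) -
          min(grp$dna_end[k], grp$dna_end[j])
        if (dgap > max_gap) { ok <- FALSE; break }
        qdir <- sign(grp$query_start[k] - grp$query_start[j])
        ddir <- sign(grp$dna_start[k] - grp$dna_start[j])
        want <- if (grp$strand[1] == "+") qdir else -qdir
        if (ddir != want) { ok <- FALSE; break }
      }
      if (ok) sel <- c(sel, k)
    }
    if (length(sel))
      consider(min(grp$dna_start[sel]), max(grp$dna_end[sel]),
               grp$strand[1], sum(grp$score[sel]),
               min(sum(grp$query_aligned[sel]) / qlen,
                   covered_fraction(grp$query_start[sel],
                                    grp$query_end[sel], qlen)))
  }
  cand
}

# Raise the hit threshold of a genome scan to a fraction of the query's
# self-score (never below the configured absolute minimum).
scan_params <- function(query, params, min_score_fraction) {
  params$min_score <- max(params$min_score,
                          as.integer(ceiling(min_score_fraction *
                                               self_score(query, params))))
  params
}

covered_fraction <- function(starts, ends, len) {
  if (!length(starts)) return(0)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0L; cur_s <- starts[1]; cur_e <- ends[1]
  for (k in seq_along(starts)[-1]) {
    if (starts[k] <= cur_e) cur_e <- max(cur_e, ends[k])
    else { tot <- tot + (cur_e - cur_s); cur_s <- starts[k]; cur_e <- ends[k] }
  }
  (tot + (cur_e - cur_s)) / len
}

#' Correct a discordant ortholog pair by tiered evidence
#'
#' Applies the correction protocol to a pair whose architectures differ:
#' tier 1 trims or splits a suspect protein at an EST-refuted fusion
#' junction; tier 2 merges split-gene fragments or rebuilds a damaged model
#' by translated search of the genomic locus; tier 3 merges fragments whose
#' combined architecture equals the intact partner's (ortholog projection,
#' lower confidence). The first succeeding tier wins.
#'
#' @param suspect_id,partner_id Protein ids: the member presumed erroneous
#'   and its (presumed correct) partner.
#' @param suspect_proteome,partner_proteome The two [annotated_proteome()]s.
#' @param suspect_arch,partner_arch Called domain-hit tibbles.
#' @param comparison The [compare_architectures()] result (suspect as `a`,
#'   partner as `b`).
#' @param ests EST tibble of the suspect's species.
#' @param catalog Domain catalog.
#' @param mapping Optional split mapping row (intact partner + suspect-side
#'   fragments) from [map_partial_orthologs()].
#' @param params An [alignment_params()].
#' @param junction_window Junction-test window (residues, default 30).
#' @param min_fraction_of_max_score Domain-call threshold for corrected
#'   models.
#' @return A `correction_result`; `action == "none"` when the pair is
#'   already concordant or no evidence tier succeeds.
#' @export
fix_prediction <- function(suspect_id, partner_id,
                           suspect_proteome, partner_proteome,
                           suspect_arch, partner_arch, comparison,
                           ests, catalog, mapping = NULL,
                           params = alignment_params(),
                           junction_window = 30L,
                           min_fraction_of_max_score = 0.45) {
  if (comparison$identical)
    return(correction_result(c(suspect_id, partner_id), "none", "est",
                             details = "architectures already concordant"))
  s_row <- suspect_proteome$proteins[
    match(suspect_id, suspect_proteome$proteins$protein_id), ]
  p_row <- partner_proteome$proteins[
    match(partner_id, partner_proteome$proteins$protein_id), ]
  s_seq <- s_row$seq; p_seq <- p_row$seq
  recall <- function(seq, ids) {
    arch <- call_domains(seq, catalog, min_fraction_of_max_score, params,
                         protein_id = ids[1])
    arch
  }

  # ---- tier 1: EST evidence against a surplus (fusion/extension) junction
  if (identical(comparison$surplus_side, "a") &&
      comparison$edit %in% c("c_terminal_extension", "n_terminal_extension",
                             "internal_insertion")) {
    jc <- junction_candidates(suspect_arch, partner_arch, comparison,
                              nchar(s_seq))
    cand_ests <- ests_at_locus(ests, suspect_proteome, s_row)
    for (junction in jc) {
      v <- test_fusion_junction(s_seq, junction, cand_ests,
                                window = junction_window, params = params,
                                protein_id = suspect_id)
      if (v$verdict != "refuted") next
      boundary <- est_defined_boundary(s_seq, junction, cand_ests, v, params,
                                       window = junction_window)
      if (comparison$edit == "n_terminal_extension") {
        corrected <- substr(s_seq, boundary + 1L, nchar(s_seq))
      } else {
        corrected <- substr(s_seq, 1L, boundary)
      }
      removed <- if (comparison$edit == "n_terminal_extension")
        substr(s_seq, 1L, boundary) else
          substr(s_seq, boundary + 1L, nchar(s_seq))
      action <- "trim_extension"
      if (nchar(removed) >= 30L) {
        other <- best_hit(removed, partner_proteome, params)
        if (!is.null(other) && other$target_id != partner_id)
          action <- "split"
      }
      return(correction_result(
        suspect_id, action, "est", recall(corrected, suspect_id),
        corrected_seq = corrected,
        details = sprintf("junction %d refuted; boundary at %d", junction,
                          boundary),
        supporting_est_ids = v$refuting_est_ids))
    }
  }

  # ---- fragment merge: tier 2 by genomic contiguity, tier 3 by projection
  if (!is.null(mapping) && nrow(mapping) == 1L &&
      length(mapping$fragment_ids[[1]]) >= 2L) {
    fids <- mapping$fragment_ids[[1]]
    frows <- suspect_proteome$proteins[
      match(fids, suspect_proteome$proteins$protein_id), ]
    merged <- paste(frows$seq, collapse = "")
    adjacency <- classify_adjacency(mapping, suspect_proteome)
    tier <- NA_character_
    if (adjacency != "cross_scaffold") {
      sc <- scaffold_seq(suspect_proteome, frows$scaffold_id[1])
      span <- c(min(frows$cds_start), max(frows$cds_end))
      region <- substr(sc, span[1] + 1L, span[2])
      hits <- translated_search(p_seq, region, params)
      if (nrow(hits) &&
          min(sum(hits$query_aligned) / nchar(p_seq),
              covered_fraction(hits$query_start, hits$query_end,
                               nchar(p_seq))) >= 0.8)
        tier <- "translated_genome_search"
    }
    if (is.na(tier)) {
      frag_archs <- lapply(fids, function(id)
        call_domains(frows$seq[match(id, frows$protein_id)], catalog,
                     min_fraction_of_max_score, params, protein_id = id))
      union_arch <- architecture_of_union(frag_archs, mapping)
      if (compare_architectures(union_arch, partner_arch)$identical)
        tier <- "ortholog_projection"
    }
    if (!is.na(tier)) {
      return(correction_result(
        fids, "merge", tier, recall(merged, fids[1]),
        corrected_seq = merged,
        details = sprintf("merged %d fragments (%s)", length(fids),
                          adjacency)))
    }
  }

  # ---- tier 2 fallback: rebuild the model from its genomic locus with the
  # partner as template (covers truncation, missed fixes of any kind, and
  # fusions without usable transcript evidence)
  rebuilt <- rebuild_from_locus(p_seq, suspect_proteome, s_row, params)
  if (!is.null(rebuilt)) {
    cand_ests <- ests_at_locus(ests, suspect_proteome, s_row)
    return(correction_result(
      suspect_id, "recover_gene", "translated_genome_search",
      recall(rebuilt, suspect_id), corrected_seq = rebuilt,
      details = "model rebuilt from genomic locus with partner as template",
      supporting_est_ids = cand_ests$est_id))
  }

  correction_result(c(suspect_id, partner_id), "none", "ortholog_projection",
                    details = "no evidence tier succeeded")
}

# Candidate junction coordinates on the suspect protein: midpoints of the
# linker gaps flanking the surplus domain block.
junction_candidates <- function(suspect_arch, partner_arch, comparison,
                                suspect_len) {
  sa <- arrange(suspect_arch, .data$start)
  n <- nrow(sa)
  p <- comparison$prefix; s <- comparison$suffix
  if (comparison$edit == "c_terminal_extension") {
    # surplus block starts after the shared prefix of p domains
    if (p >= 1L && p < n)
      return((sa$end[p] + sa$start[p + 1L]) %/% 2L)
    return(integer(0))
  }
  if (comparison$edit == "n_terminal_extension") {
    k <- n - s  # last surplus domain index
    if (k >= 1L && k < n)
      return((sa$end[k] + sa$start[k + 1L]) %/% 2L)
    return(integer(0))
  }
  if (comparison$edit == "internal_insertion" && p >= 1L && p < n) {
    left <- (sa$end[p] + sa$start[p + 1L]) %/% 2L
    k <- n - s
    right <- if (k >= 1L && k < n) (sa$end[k] + sa$start[k + 1L]) %/% 2L
    else integer(0)
    return(unique(c(left, right)))
  }
  integer(0)
}

# Sharpen a refuted junction to the EST-defined boundary: the stop-codon end
# (for downstream surplus) or transcript start (for upstream surplus) of the
# refuting ESTs closest to the junction; falls back to the candidate.
est_defined_boundary <- function(protein, junction, ests, verdict, params,
                                 window = 30L) {
  ref <- ests[ests$est_id %in% verdict$refuting_est_ids, , drop = FALSE]
  stops <- integer(0); starts <- integer(0)
  for (k in seq_len(nrow(ref))) {
    hit <- map_est_to_protein(protein, ref$seq[k], params)
    if (is.null(hit)) next
    if (isTRUE(ref$includes_stop[k]) && abs(hit$query_end - junction) <= window)
      stops <- c(stops, hit$query_end)
    if (isTRUE(ref$includes_start[k]) &&
        abs(hit$query_start - junction) <= window)
      starts <- c(starts, hit$query_start)
  }
  if (length(stops)) return(max(stops))
  if (length(starts)) return(min(starts))
  junction
}

# Rebuild a gene model at the suspect's locus using the partner protein as
# template: translated search of the locus +/- margin; accept when the hit
# chain covers >= 80% of the template.
rebuild_from_locus <- function(template, suspect_proteome, s_row, params,
                               margin = 3000L, min_coverage = 0.8,
                               min_score_fraction = 0.25) {
  sc <- scaffold_seq(suspect_proteome, s_row$scaffold_id)
  rs <- max(0L, s_row$cds_start - margin)
  re <- min(nchar(sc), s_row$cds_end + margin)
  region <- substr(sc, rs + 1L, re)
  params <- scan_params(template, params, min_score_fraction)
  hits <- translated_search(template, region, params)
  cand <- best_gene_chain(hits, nchar(template), min_coverage)
  if (is.null(cand)) return(NULL)
  dna <- substr(region, cand$dna_start + 1L, cand$dna_end)
  if (cand$strand == "-") dna <- revcomp(dna)
  prot <- sub("\\*.*$", "", translate_dna(dna))
  if (nchar(prot) >= 20L) prot else NULL
}
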