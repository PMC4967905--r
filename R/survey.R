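# End-to-end survey: sample multi-domain proteins, find orthologs, compare
# architectures, audit and correct discordant pairs, report concordance.

#' Survey configuration
#'
#' @param sample_size Number of proteins sampled from species A (default 100).
#' @param min_domains Minimum called domains for a protein to qualify
#'   (default 2).
#' @param min_identity Reciprocal-best-hit identity cutoff (default 0.60).
#' @param min_fraction_of_max_score Domain-call acceptance threshold.
#' @param truncation_threshold Strict length-fraction threshold of the
#'   truncation rule (default 0.6).
#' @param junction_window Junction-test window in residues (default 30).
#' @param seed Seed for the protein sample.
#' @return A `survey_config` list.
#' @export
survey_config <- function(sample_size = 100L, min_domains = 2L,
                          min_identity = 0.60,
                          min_fraction_of_max_score = 0.45,
                          truncation_threshold = 0.6,
                          junction_window = 30L, seed = 1L) {
  if (min_domains < 1L) abort("min_domains must be >= 1")
  structure(list(sample_size = as.integer(sample_size),
                 min_domains = as.integer(min_domains),
                 min_identity = min_identity,
                 min_fraction_of_max_score = min_fraction_of_max_score,
                 truncation_threshold = truncation_threshold,
                 junction_window = as.integer(junction_window),
                 seed = as.integer(seed)), class = "survey_config")
}

#' Sample proteins with at least a given number of domains
#'
#' @param proteome An [annotated_proteome()].
#' @param archs Domain-hit tibble for the proteome (from
#'   [call_domains_proteome()]).
#' @param n Sample size.
#' @param min_domains Minimum number of called domains.
#' @param seed Integer seed.
#' @return Character vector of `n` protein ids (uniform, without
#'   replacement).
#' @export
sample_multidomain_proteins <- function(proteome, archs, n, min_domains = 2L,
                                        seed = 1L) {
  counts <- archs %>% dplyr::count(.data$protein_id)
  qualifying <- counts$protein_id[counts$n >= min_domains]
  qualifying <- intersect(proteome$proteins$protein_id, qualifying)
  if (length(qualifying) < n)
    abort(sprintf("only %d proteins have >= %d domains; cannot sample %d",
                  length(qualifying), min_domains, n))
  with_seed(seed, sort(sample(qualifying, n)))
}

# dogma flags for one protein
audit_flags <- function(arch, seq, catalog, truncation_threshold) {
  flags <- list()
  tm <- detect_tm_segments(seq)
  lf <- check_localization_conflict(arch, catalog, tm)
  if (!is.null(lf)) flags[[length(flags) + 1L]] <- lf
  for (k in seq_len(nrow(arch))) {
    tf <- check_truncation(arch[k, ], catalog, truncation_threshold)
    if (!is.null(tf)) flags[[length(flags) + 1L]] <- tf
  }
  flags
}

#' Run the full ortholog-architecture survey
#'
#' Samples multi-domain proteins from species A, pairs them with species B by
#' reciprocal best hit, compares domain architectures, audits discordant
#' pairs with the misprediction rules and EST junction tests, applies the
#' tiered correction protocol, routes absent orthologs to translated
#' missing-gene recovery, and tallies a concordance report.
#'
#' @param A,B Predicted [annotated_proteome()]s (A is sampled).
#' @param reference Trusted [annotated_proteome()] whose `domains` hold
#'   curated architectures.
#' @param ests_a,ests_b EST tibbles per species.
#' @param catalog Domain catalog.
#' @param config A [survey_config()].
#' @param params An [alignment_params()].
#' @return A `survey_report`.
#' @export
run_survey <- function(A, B, reference, ests_a, ests_b, catalog,
                       config = survey_config(),
                       params = alignment_params()) {
  thr <- config$min_fraction_of_max_score
  arch_a_tbl <- call_domains_proteome(A, catalog, thr, params)
  arch_b_tbl <- call_domains_proteome(B, catalog, thr, params)
  empty_arch <- arch_a_tbl[0, ]
  arch_of <- function(tbl, id) {
    out <- tbl[tbl$protein_id == id, , drop = FALSE]
    if (nrow(out)) arrange(out, .data$start) else empty_arch
  }
  sampled <- sample_multidomain_proteins(A, arch_a_tbl, config$sample_size,
                                         config$min_domains, config$seed)

  a_seqs <- proteome_seqs(A); b_seqs <- proteome_seqs(B)
  a_encs <- aa_encode_list(a_seqs, params$matrix)
  b_encs <- aa_encode_list(b_seqs, params$matrix)
  scores <- sw_score_matrix(a_encs, b_encs, params)
  pairs <- rbh_from_matrix(scores, as.list(a_seqs), as.list(b_seqs),
                           config$min_identity, params)
  map_b <- map_partial_orthologs(A, B, params, scores = t(scores))
  map_a <- map_partial_orthologs(B, A, params, scores = scores)

  ref_seqs <- proteome_seqs(reference)
  ref_encs <- aa_encode_list(ref_seqs, params$matrix)

  pair_rows <- list(); absent_rows <- list()
  for (aid in sampled) {
    hitrow <- pairs[pairs$a_id == aid, , drop = FALSE]
    a_seq <- a_seqs[[aid]]
    a_arch <- arch_of(arch_a_tbl, aid)
    if (!nrow(hitrow)) {
      rec <- find_missing_gene(a_seq, B, ests_b, catalog, params,
                               min_fraction_of_max_score = thr)
      absent_rows[[length(absent_rows) + 1L]] <- tibble(
        a_id = aid, recovered = !is.null(rec),
        recovered_arch_identical = if (is.null(rec)) FALSE else
          compare_architectures(rec$corrected_architecture,
                                a_arch)$identical,
        supporting_ests = if (is.null(rec)) 0L else
          length(rec$supporting_est_ids))
      next
    }
    bid <- hitrow$b_id[1]
    b_arch <- arch_of(arch_b_tbl, bid)
    cmp <- compare_architectures(a_arch, b_arch)
    refcls <- classify_against_reference_scored(
      a_arch, b_arch, aid, a_encs, ref_seqs, ref_encs, reference, params)
    flags_a <- audit_flags(a_arch, a_seq, catalog,
                           config$truncation_threshold)
    flags_b <- audit_flags(b_arch, b_seqs[[bid]], catalog,
                           config$truncation_threshold)

    same_after <- cmp$identical
    action <- "none"; tier <- NA_character_; suspect <- NA_character_
    verdicts <- character(0); adjacency <- NA_character_
    if (!cmp$identical) {
      order_suspects <- switch(refcls$agreement,
                               a_only = c("b", "a"),
                               b_only = c("a", "b"),
                               c("b", "a"))
      for (side in order_suspects) {
        if (side == "b") {
          sid <- bid; pid <- aid
          sp <- B; pp <- A
          s_arch <- b_arch; p_arch <- a_arch
          oriented <- compare_architectures(b_arch, a_arch)
          ests <- ests_b
          mrow <- map_b[map_b$single_id == aid, , drop = FALSE]
          mrow <- filter_mapping(mrow, sid)
        } else {
          sid <- aid; pid <- bid
          sp <- A; pp <- B
          s_arch <- a_arch; p_arch <- b_arch
          oriented <- cmp
          ests <- ests_a
          mrow <- map_a[map_a$single_id == bid, , drop = FALSE]
          mrow <- filter_mapping(mrow, sid)
        }
        fix <- fix_prediction(sid, pid, sp, pp, s_arch, p_arch, oriented,
                              ests, catalog,
                              mapping = if (nrow(mrow)) mrow else NULL,
                              params = params,
                              junction_window = config$junction_window,
                              min_fraction_of_max_score = thr)
        if (fix$action == "none") next
        fixed_same <- compare_architectures(fix$corrected_architecture,
                                            p_arch)$identical
        if (fixed_same) {
          same_after <- TRUE
          action <- fix$action; tier <- fix$evidence_tier; suspect <- sid
          if (nrow(mrow)) adjacency <- classify_adjacency(mrow, sp)
          break
        }
        # remember a failed attempt but keep trying the other side
        if (action == "none") {
          action <- fix$action; tier <- fix$evidence_tier; suspect <- sid
        }
      }
    }
    pair_rows[[length(pair_rows) + 1L]] <- tibble(
      a_id = aid, b_id = bid, identity = hitrow$identity[1],
      same_architecture = cmp$identical, edit = cmp$edit,
      reference_agreement = refcls$agreement,
      n_flags_a = length(flags_a), n_flags_b = length(flags_b),
      flag_rules = list(c(vapply(flags_a, `[[`, character(1), "rule"),
                          vapply(flags_b, `[[`, character(1), "rule"))),
      suspect_id = suspect, correction_action = action,
      correction_tier = tier, adjacency = adjacency,
      same_after_correction = same_after)
  }

  pairs_tbl <- bind_rows(pair_rows)
  absent_tbl <- if (length(absent_rows)) bind_rows(absent_rows) else
    tibble(a_id = character(), recovered = logical(),
           recovered_arch_identical = logical(), supporting_ests = integer())
  ref_levels <- c("both", "a_only", "b_only", "neither", "no_reference")
  ref_hist <- setNames(integer(5), ref_levels)
  if (nrow(pairs_tbl)) {
    tt <- table(factor(pairs_tbl$reference_agreement, levels = ref_levels))
    ref_hist[] <- as.integer(tt)
  }
  counts <- list(
    sample_size = length(sampled),
    ortholog_present = nrow(pairs_tbl),
    ortholog_absent = nrow(absent_tbl),
    same_architecture = sum(pairs_tbl$same_architecture),
    different_architecture = sum(!pairs_tbl$same_architecture),
    same_after_correction = sum(pairs_tbl$same_after_correction),
    different_after_correction = sum(!pairs_tbl$same_after_correction),
    absent_recovered = sum(absent_tbl$recovered),
    reference_agreement = as.list(ref_hist))
  structure(list(counts = counts, pairs = pairs_tbl, absent = absent_tbl,
                 sampled_ids = sampled, config = config),
            class = "survey_report")
}

filter_mapping <- function(mrow, suspect_id) {
  if (!nrow(mrow)) return(mrow)
  keep <- vapply(seq_len(nrow(mrow)), function(i)
    suspect_id %in% mrow$fragment_ids[[i]], logical(1))
  mrow[keep, ][seq_len(min(1L, sum(keep))), , drop = FALSE]
}

# Reference classification against precomputed encodings.
classify_against_reference_scored <- function(a_arch, b_arch, aid, a_encs,
                                              ref_seqs, ref_encs, reference,
                                              params) {
  sc <- sw_scores(a_encs[[aid]], ref_encs, params)
  if (max(sc) < params$min_score)
    return(list(agreement = "no_reference", reference_id = NA_character_))
  j <- which.max(sc)
  rid <- names(ref_seqs)[j]
  ref_arch <- reference$domains %>% filter(.data$protein_id == rid) %>%
    arrange(.data$start)
  a_same <- compare_architectures(a_arch, ref_arch)$identical
  b_same <- compare_architectures(b_arch, ref_arch)$identical
  agreement <- if (a_same && b_same) "both" else if (a_same) "a_only"
  else if (b_same) "b_only" else "neither"
  list(agreement = agreement, reference_id = rid)
}

#' @export
print.survey_report <- function(x, ...) {
  ct <- x$counts
  cat("<survey_report>\n")
  cat(sprintf("  sampled %d | orthologs present %d, absent %d (recovered %d)\n",
              ct$sample_size, ct$ortholog_present, ct$ortholog_absent,
              ct$absent_recovered))
  cat(sprintf("  architectures: same %d, different %d\n",
              ct$same_architecture, ct$different_architecture))
  cat(sprintf("  after correction: same %d, different %d\n",
              ct$same_after_correction, ct$different_after_correction))
  ra <- ct$reference_agreement
  cat(sprintf("  reference agreement: both %d, a_only %d, b_only %d, neither %d, no_reference %d\n",
              ra$both, ra$a_only, ra$b_only, ra$neither, ra$no_reference))
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

#' Percentages of discordant ortholog pairs
#'
#' With a `survey_report`, returns the report's headline percentages; with
#' numeric counts, returns `round_half_up(100 * different / present)` --
#' integer percentages with halves rounded up.
#'
#' @param x A `survey_report`, or a numeric vector of discordant-pair counts.
#' @param present Number of ortholog pairs (required when `x` is numeric).
#' @return A tibble of labelled percentages, or an integer vector.
#' @export
report_percentages <- function(x, present = NULL) {
  if (is.numeric(x)) {
    if (is.null(present) || any(present <= 0))
      abort("need a positive ortholog-pair count")
    return(as.integer(round_half_up(100 * x / present)))
  }
  ct <- x$counts
  if (ct$ortholog_present == 0L)
    abort("no ortholog pairs: percentages undefined")
  tibble(
    metric = c("different_architecture", "different_after_correction"),
    count = c(ct$different_architecture, ct$different_after_correction),
    of = ct$ortholog_present,
    percent = as.integer(round_half_up(
      100 * c(ct$different_architecture, ct$different_after_correction) /
        ct$ortholog_present)))
}

#' Write a survey report as JSON
#'
#' Deterministic layout (fixed key order, no rounding) so identical runs give
#' bit-identical files.
#'
#' @param report A `survey_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey_report <- function(report, path) {
  payload <- list(
    schema_version = 1L,
    counts = report$counts,
    pairs = report$pairs %>%
      mutate(flag_rules = purrr::map_chr(.data$flag_rules, paste,
                                         collapse = ";")),
    absent = report$absent,
    sampled_ids = report$sampled_ids)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
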