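# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a survey report into per-pair records
#'
#' @param x A `survey_report`.
#' @param ... Unused.
#' @return The per-pair tibble (one row per sampled protein with an
#'   ortholog), with flags, verdicts and correction provenance.
#' @export
tidy.survey_report <- function(x, ...) {
  x$pairs
}

#' One-row summary of a survey report
#'
#' @param x A `survey_report`.
#' @param ... Unused.
#' @return A one-row tibble mirroring the concordance table: ortholog
#'   presence, architecture agreement before and after correction, and the
#'   reference-agreement histogram.
#' @export
glance.survey_report <- function(x, ...) {
  ct <- x$counts
  tibble(
    sample_size = ct$sample_size,
    ortholog_present = ct$ortholog_present,
    ortholog_absent = ct$ortholog_absent,
    same_architecture = ct$same_architecture,
    different_architecture = ct$different_architecture,
    same_after_correction = ct$same_after_correction,
    different_after_correction = ct$different_after_correction,
    absent_recovered = ct$absent_recovered,
    ref_both = ct$reference_agreement$both,
    ref_a_only = ct$reference_agreement$a_only,
    ref_b_only = ct$reference_agreement$b_only,
    ref_neither = ct$reference_agreement$neither,
    ref_no_reference = ct$reference_agreement$no_reference)
}

#' Tidy a local alignment
#'
#' @param x A `local_alignment`.
#' @param ... Unused.
#' @return A one-row tibble with ids, score, identity and intervals.
#' @export
tidy.local_alignment <- function(x, ...) {
  tibble(query_id = x$query_id, target_id = x$target_id, score = x$score,
         identity = x$identity, matches = x$matches,
         aligned_columns = x$aligned_columns,
         query_start = x$query_start, query_end = x$query_end,
         target_start = x$target_start, target_end = x$target_end)
}
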