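# The annotated-proteome container: proteins with scaffold coordinates, the
# truth domain architecture (for simulated truth sets), transmembrane
# segments, coding sequences and the scaffold DNA itself.
#
# All internal coordinates are 0-based half-open; GFF3/TSV writers convert to
# 1-based inclusive at the boundary.

#' Construct an annotated proteome
#'
#' @param proteins Tibble with columns `protein_id`, `scaffold_id`, `strand`,
#'   `cds_start`, `cds_end` (0-based half-open DNA coordinates on the forward
#'   strand), `seq` (amino acids), `cds` (coding DNA, 5'->3', including the
#'   stop codon where present) and `has_signal_peptide`.
#' @param scaffolds Tibble with `scaffold_id`, `seq` (DNA).
#' @param domains Tibble of truth domain hits (`protein_id`, `family`,
#'   `start`, `end`), or NULL for predicted proteomes.
#' @param tm Tibble of transmembrane segments (`protein_id`, `start`, `end`).
#' @param species Optional species label.
#' @return An object of class `annotated_proteome`.
#' @export
annotated_proteome <- function(proteins, scaffolds, domains = NULL, tm = NULL,
                               species = NA_character_) {
  proteins <- as_tibble(proteins)
  needed <- c("protein_id", "scaffold_id", "strand", "cds_start", "cds_end",
              "seq")
  missing <- setdiff(needed, names(proteins))
  if (length(missing))
    abort(paste("proteins tibble lacks columns:",
                paste(missing, collapse = ", ")))
  if (anyDuplicated(proteins$protein_id))
    abort("duplicate protein ids")
  structure(list(
    proteins = proteins,
    scaffolds = as_tibble(scaffolds),
    domains = if (is.null(domains))
      tibble(protein_id = character(), family = character(),
             start = integer(), end = integer()) else as_tibble(domains),
    tm = if (is.null(tm))
      tibble(protein_id = character(), start = integer(), end = integer())
      else as_tibble(tm),
    species = species), class = "annotated_proteome")
}

#' @export
print.annotated_proteome <- function(x, ...) {
  cat(sprintf("<annotated_proteome%s> %d proteins on %d scaffolds",
              if (is.na(x$species)) "" else paste0(" ", x$species),
              nrow(x$proteins), nrow(x$scaffolds)))
  if (nrow(x$domains))
    cat(sprintf(", %d truth domain hits", nrow(x$domains)))
  cat("\n")
  invisible(x)
}

proteome_seqs <- function(proteome) {
  setNames(proteome$proteins$seq, proteome$proteins$protein_id)
}

scaffold_seq <- function(proteome, scaffold_id) {
  i <- match(scaffold_id, proteome$scaffolds$scaffold_id)
  if (is.na(i)) abort(paste("unknown scaffold", scaffold_id))
  proteome$scaffolds$seq[i]
}
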