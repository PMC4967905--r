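# Readers and writers for the external formats the pipeline touches.
#
# Dialects: FASTA wrapped at 60 columns, sequences normalized to upper case;
# GFF3 and the domain TSV are 1-based inclusive on disk while all internal
# coordinates stay 0-based half-open; round trips are lossless after one
# normalization pass.

#' Read a FASTA file
#'
#' Tolerant of wrapped lines and CRLF endings; sequences are upper-cased; ids
#' split from descriptions at the first whitespace.
#'
#' @param path Readable FASTA path (protein, DNA or EST).
#' @return Tibble `id`, `desc`, `seq`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) {
    warn("empty FASTA file")
    return(tibble(id = character(), desc = character(), seq = character()))
  }
  full <- names(set)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full),
                 NA_character_)
  if (anyDuplicated(id)) abort("duplicate FASTA ids")
  tibble(id = id, desc = desc,
         seq = unname(toupper(as.character(set))))
}

#' Write a FASTA file
#'
#' @param records Tibble with `id`, `seq` and optional `desc`.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (anyDuplicated(records$id)) abort("duplicate FASTA ids")
  nm <- if ("desc" %in% names(records))
    ifelse(is.na(records$desc), records$id,
           paste(records$id, records$desc)) else records$id
  set <- Biostrings::BStringSet(setNames(toupper(records$seq), nm))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' CDS features with ID attributes; coordinates are converted from the
#' 1-based inclusive GFF3 convention to internal 0-based half-open.
#'
#' @param path GFF3 path.
#' @param scaffold_lengths Optional named vector for bounds checking.
#' @return Tibble `protein_id`, `scaffold_id`, `strand`, `cds_start`,
#'   `cds_end`.
#' @export
read_gff3 <- function(path, scaffold_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  out <- tibble(
    protein_id = as.character(gr$ID),
    scaffold_id = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    cds_start = GenomicRanges::start(gr) - 1L,
    cds_end = GenomicRanges::end(gr))
  if (!is.null(scaffold_lengths)) {
    lens <- scaffold_lengths[out$scaffold_id]
    if (anyNA(lens) || any(out$cds_end > lens) || any(out$cds_start < 0L))
      abort("feature outside scaffold bounds")
  }
  out
}

#' Write gene annotations as GFF3
#'
#' @param annotation Tibble with `protein_id`, `scaffold_id`, `strand`,
#'   `cds_start`, `cds_end` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$scaffold_id,
    ranges = IRanges::IRanges(start = annotation$cds_start + 1L,
                              end = annotation$cds_end),
    strand = annotation$strand)
  gr$type <- "CDS"
  gr$source <- "orthofixr"
  gr$phase <- 0L
  gr$ID <- annotation$protein_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a domain-hit table (pfam_scan-like TSV)
#'
#' Columns `seq_id`, `family`, `start`, `end`, `score`, 1-based inclusive on
#' disk; rows are sorted by (`seq_id`, `start`) on read.
#'
#' @param path TSV path.
#' @return Tibble `protein_id`, `family`, `start`, `end` (0-based half-open),
#'   `score`.
#' @export
read_domain_tsv <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    seq_id = readr::col_character(), family = readr::col_character(),
    start = readr::col_integer(), end = readr::col_integer(),
    score = readr::col_double()))
  if (any(tb$start > tb$end)) abort("domain rows with start > end")
  tb %>%
    transmute_domains() %>%
    arrange(.data$protein_id, .data$start)
}

transmute_domains <- function(tb) {
  tibble(protein_id = tb$seq_id, family = tb$family,
         start = tb$start - 1L, end = tb$end, score = tb$score)
}

#' Write a domain-hit table
#'
#' @param domains Tibble with `protein_id`, `family`, `start`, `end`
#'   (0-based half-open) and optional `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_tsv <- function(domains, path) {
  out <- tibble(seq_id = domains$protein_id, family = domains$family,
                start = domains$start + 1L, end = domains$end,
                score = if ("score" %in% names(domains)) domains$score
                else NA_real_) %>%
    arrange(.data$seq_id, .data$start)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write truth labels as JSON
#'
#' @param labels Label tibble from [inject_annotation_errors()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_labels <- function(labels, path) {
  jsonlite::write_json(list(schema_version = 1L, labels = labels), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read truth labels from JSON
#'
#' @param path Path written by [write_truth_labels()].
#' @return Label tibble.
#' @export
read_truth_labels <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- purrr::map(raw$labels, function(l) tibble(
    predicted_protein_id = l$predicted_protein_id %||% NA_character_,
    error_kind = l$error_kind,
    source_gene_ids = list(unlist(l$source_gene_ids) %||% character(0)),
    junction_positions = list(as.integer(unlist(l$junction_positions)))))
  bind_rows(rows)
}

#' Read a simulation/survey configuration from YAML or JSON
#'
#' @param path Configuration file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' Export a simulated scenario to disk
#'
#' Writes the standard file set for one species of a simulated pair:
#' proteins FASTA, scaffolds FASTA, annotation GFF3, and (for truth
#' proteomes) the domain TSV.
#'
#' @param proteome An [annotated_proteome()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the vector of files written.
#' @export
export_proteome <- function(proteome, dir, prefix = "proteome") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  f1 <- file.path(dir, paste0(prefix, "_proteins.fa"))
  write_fasta(tibble(id = proteome$proteins$protein_id,
                     seq = proteome$proteins$seq), f1)
  f2 <- file.path(dir, paste0(prefix, "_scaffolds.fa"))
  write_fasta(tibble(id = proteome$scaffolds$scaffold_id,
                     seq = proteome$scaffolds$seq), f2)
  f3 <- file.path(dir, paste0(prefix, ".gff3"))
  write_gff3(proteome$proteins, f3)
  files <- c(f1, f2, f3)
  if (nrow(proteome$domains)) {
    f4 <- file.path(dir, paste0(prefix, "_domains.tsv"))
    doms <- proteome$domains
    if (!"score" %in% names(doms)) doms$score <- NA_real_
    write_domain_tsv(doms, f4)
    files <- c(files, f4)
  }
  invisible(files)
}
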