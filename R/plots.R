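# ggplot2 graphics for survey reports and domain architectures.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a survey report as a concordance bar chart
#'
#' Ortholog-pair counts by architecture agreement, before and after the
#' correction stage.
#'
#' @param object A `survey_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.survey_report <- function(object, ...) {
  ct <- object$counts
  df <- tibble(
    stage = factor(rep(c("as predicted", "after correction"), each = 2L),
                   levels = c("as predicted", "after correction")),
    agreement = factor(rep(c("same", "different"), 2L),
                       levels = c("same", "different")),
    pairs = c(ct$same_architecture, ct$different_architecture,
              ct$same_after_correction, ct$different_after_correction))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$pairs,
                                   fill = .data$agreement)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c(same = "#4575b4",
                                          different = "#d73027")) +
    ggplot2::labs(x = NULL, y = "ortholog pairs",
                  title = "Domain-architecture concordance of orthologs",
                  fill = "architecture") +
    ggplot2::theme_minimal()
}

#' Plot one or more domain architectures
#'
#' Draws each protein as a line with its domain hits as labelled boxes, the
#' standard domain-cartoon view for comparing architectures by eye.
#'
#' @param domains Domain-hit tibble (`protein_id`, `family`, `start`,
#'   `end`); may cover several proteins.
#' @param protein_lengths Optional named vector of protein lengths for the
#'   backbone lines.
#' @return A ggplot.
#' @export
plot_architecture <- function(domains, protein_lengths = NULL) {
  if (!nrow(domains)) abort("no domain hits to plot")
  ids <- unique(domains$protein_id)
  backbone <- tibble(
    protein_id = ids,
    xend = if (is.null(protein_lengths))
      vapply(ids, function(i) max(domains$end[domains$protein_id == i]),
             numeric(1))
    else unname(protein_lengths[ids]))
  ggplot2::ggplot(domains) +
    ggplot2::geom_segment(data = backbone,
                          ggplot2::aes(x = 0, xend = .data$xend,
                                       y = .data$protein_id,
                                       yend = .data$protein_id),
                          linewidth = 0.4, colour = "grey50") +
    ggplot2::geom_tile(ggplot2::aes(
      x = (.data$start + .data$end) / 2, y = .data$protein_id,
      width = .data$end - .data$start, fill = .data$family),
      height = 0.6, colour = "grey20") +
    ggplot2::labs(x = "residue", y = NULL, fill = "family") +
    ggplot2::theme_minimal()
}
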