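# ggplot2 methods for the three result types.

#' Plot a mutation spectrum
#'
#' Bar chart of the mean number of mutations per isolate in each
#' pyrimidine-centered substitution class, in the conventional class colours.
#'
#' @param object A `mut_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mut_spectrum <- function(object, ...) {
  d <- spectrum_summary(object)
  if ("context" %in% names(d)) {
    d <- d %>%
      group_by(.data$class) %>%
      summarise(mean_per_isolate = sum(.data$mean_per_isolate), .groups = "drop")
  }
  cols <- c("C>A" = "#03BCEE", "C>G" = "#010101", "C>T" = "#E32926",
            "T>A" = "#CAC9C9", "T>C" = "#A1CE63", "T>G" = "#EBC6C4")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$mean_per_isolate,
                                  fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = cols) +
    ggplot2::labs(x = "substitution class (pyrimidine-centered)",
                  y = "mutations per isolate") +
    ggplot2::theme_minimal()
}

#' Plot motif enrichment across samples
#'
#' Per-sample fold-enrichment with significant samples (one-sided Fisher
#' p below `alpha` and enrichment above 1) highlighted; the dashed line marks
#' the null value 1.
#'
#' @param object A `mut_enrichment`.
#' @param alpha Significance threshold for highlighting.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mut_enrichment <- function(object, alpha = 0.05, ...) {
  d <- as_tibble(object)
  d <- d[is.finite(d$enrichment), , drop = FALSE]
  d$significant <- !is.na(d$p_value) & d$p_value < alpha & d$enrichment > 1
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = .data$enrichment,
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "#E32926")) +
    ggplot2::labs(x = NULL,
                  y = paste0("fold-enrichment (", attr(object, "motif"), ")"),
                  colour = paste0("p < ", alpha)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot an assay comparison
#'
#' Median mutation frequencies with their distribution-free confidence
#' intervals for the untreated and treated groups of each genotype.
#'
#' @param object An `assay_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assay_comparison <- function(object, ...) {
  d <- as_tibble(object)
  long <- bind_rows(
    tibble(genotype = d$genotype, treatment = attr(object, "untreated"),
           median = d$median_untreated, lower = d$untreated_lower,
           upper = d$untreated_upper),
    tibble(genotype = d$genotype, treatment = attr(object, "treated"),
           median = d$median_treated, lower = d$treated_lower,
           upper = d$treated_upper)
  )
  long$treatment <- factor(long$treatment,
                           levels = c(attr(object, "untreated"),
                                      attr(object, "treated")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$genotype, y = .data$median,
                                     fill = .data$treatment)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = "mutation frequency", fill = NULL) +
    ggplot2::theme_minimal()
}
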