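#' Plot a coverage profile
#'
#' Depth per target position, with the flagging threshold and the
#' low-coverage intervals (the regions a diagnostic run refers to Sanger)
#' highlighted.
#'
#' @param object A `pkd_coverage` from [coverage_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pkd_coverage <- function(object, ...) {
  s <- coverage_summary(object)
  low <- low_coverage_intervals(object)
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area(fill = "grey70") +
    ggplot2::geom_hline(yintercept = s$threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "target position (bp)", y = "depth",
                  title = sprintf(
                    "coverage: mean %.0fx, %.1f%% of target >= %dx",
                    s$mean_depth, 100 * s$frac_ge_threshold, s$threshold)) +
    ggplot2::theme_minimal()
  if (nrow(low) > 0) {
    p <- p + ggplot2::geom_rect(
      data = low, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      fill = "firebrick", alpha = 0.15)
  }
  p
}

#' Plot MLPA dosage quotients
#'
#' Per-exon dosage quotients with the deletion/duplication thresholds;
#' called events colour the affected exons.
#'
#' @param object A `pkd_dosage` from [call_rearrangements()].
#' @param low,high Thresholds to draw (defaults match the caller).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pkd_dosage <- function(object, low = 0.70, high = 1.30, ...) {
  df <- tibble::as_tibble(object)
  df$exon <- factor(df$exon, levels = df$exon)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$exon, y = .data$dq,
                                   fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(low, 1, high),
                        linetype = c("dashed", "solid", "dashed"),
                        colour = c("firebrick", "grey40", "firebrick")) +
    ggplot2::scale_fill_manual(values = c(normal = "grey70",
                                          deletion = "steelblue",
                                          duplication = "darkorange")) +
    ggplot2::labs(x = "exon", y = "dosage quotient") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot calls on the VAF axis
#'
#' Variant calls by position and VAF, coloured by genotype, with the
#' calling threshold, het band and hom threshold drawn — a visual of the
#' decision bands of [call_germline()].
#'
#' @param object A `pkd_calls` tibble.
#' @param call_threshold,het_band,hom_threshold Bands to draw (defaults
#'   match the caller).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pkd_calls <- function(object, call_threshold = 0.10,
                               het_band = c(0.20, 0.80),
                               hom_threshold = 0.90, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$pos, y = .data$vaf,
                               colour = .data$genotype)) +
    ggplot2::geom_hline(yintercept = c(call_threshold, het_band,
                                       hom_threshold),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "position (bp)", y = "variant allele fraction") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
plot.pkd_coverage <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.pkd_dosage <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.pkd_calls <- function(x, ...) print(autoplot(x, ...))
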