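## ggplot2 views of the result objects.

#' Plot a read classification as category bars
#'
#' @param object A `trf_classification`.
#' @param log10_percent Draw percentages on a log10 axis (the alien-only
#'   sliver is typically orders of magnitude below the host bar).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trf_classification <- function(object, log10_percent = FALSE, ...) {
  p <- ggplot2::ggplot(object$summary,
                       ggplot2::aes(x = .data$category, y = .data$percent,
                                    fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(
      x = NULL, y = "% of reads",
      title = sprintf("Read classification (max %d mismatch%s)",
                      object$max_mismatch,
                      if (object$max_mismatch == 1) "" else "es")
    ) +
    ggplot2::theme_minimal()
  if (log10_percent) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot the 5'/3' end distributions of an end profile
#'
#' @param object An `end_profile`.
#' @param ... Unused.
#' @return A ggplot with one line per end.
#' @export
autoplot.end_profile <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$pct,
                                     colour = .data$end)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "position on reference (0-based)", y = "% of profiled reads",
      colour = "read end",
      title = sprintf("End profile: %s (n = %d)",
                      attr(object, "trf_id"), attr(object, "n_reads"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a permutation scan
#'
#' Read-length distribution of the permuted oligos.
#'
#' @param object A `permutation_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.permutation_scan <- function(object, ...) {
  ggplot2::ggplot(object$length_distribution,
                  ggplot2::aes(x = .data$length, y = .data$n_reads)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "permuted read length (nt)", y = "reads",
                  title = "Circularly permuted reads by length") +
    ggplot2::theme_minimal()
}

#' Plot growth curves
#'
#' @param object A [growth_curve()] tibble (several labels may be bound
#'   together with `dplyr::bind_rows()`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.growth_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_h, y = .data$od,
                                       colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "OD650", colour = NULL) +
    ggplot2::theme_minimal()
}
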