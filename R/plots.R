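# ggplot2 displays for the result objects.

#' @export
autoplot.ccs_error_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$type, y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "share of errors",
                  title = "Error-type mixture",
                  subtitle = sprintf("%d errors over %d aligned positions (%.3g%%)",
                                     object$n_errors, object$n_positions,
                                     100 * object$error_rate)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ccs_variant_spectrum <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = factor(.data$occurrences),
                               y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "times a 1-nt variant was observed",
                  y = "share of variants",
                  title = "1-nt variant spectrum") +
    ggplot2::theme_minimal()
}

#' Error rate by curation stage
#'
#' @param report A `ccs_run_report` from [run_pipeline()].
#' @return A ggplot.
#' @export
plot_error_by_stage <- function(report) {
  df <- report$stages[!is.na(report$stages$error_rate), , drop = FALSE]
  df$stage <- factor(df$stage, levels = df$stage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$error_rate,
                                   group = 1)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.3g%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "observed error rate",
                  title = "Error rate across curation stages") +
    ggplot2::theme_minimal()
}
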