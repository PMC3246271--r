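# ggplot2 displays for result objects.

#' Plot an expected-versus-observed mutational spectrum
#'
#' Bar chart of the six substitution types: observed event proportions
#' next to the proportions expected if every synonymous opportunity
#' mutated at a uniform rate.
#'
#' @param object A `spectrum_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spectrum_report
#' @export
autoplot.spectrum_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$counts[, c("type", "observed_prop", "expected_prop")],
    cols = c("expected_prop", "observed_prop"),
    names_to = "which", values_to = "proportion"
  )
  df$which <- ifelse(df$which == "observed_prop", "observed", "expected")
  df$type <- factor(df$type, levels = mutation_types())
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$type, y = .data$proportion, fill = .data$which)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(), colour = "black") +
    ggplot2::scale_fill_manual(values = c(expected = "white",
                                          observed = "black")) +
    ggplot2::labs(
      x = "base-pair substitution type",
      y = "proportion of synonymous events",
      fill = NULL
    ) +
    ggplot2::theme_classic()
}

#' Plot a parameter-recovery report
#'
#' Histogram of per-replicate combined-rate estimates with the true rate
#' marked.
#'
#' @param object A `recovery_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recovery_report
#' @export
autoplot.recovery_report <- function(object, ...) {
  ggplot2::ggplot(object$replicates, ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey80", colour = "black") +
    ggplot2::geom_vline(xintercept = object$truth, linetype = 2,
                        colour = "red") +
    ggplot2::labs(
      x = "combined rate estimate (per bp per generation)",
      y = "replicates",
      title = sprintf("coverage %.2f at %g%% nominal",
                      object$summary$coverage, 100 * object$summary$level)
    ) +
    ggplot2::theme_classic()
}
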