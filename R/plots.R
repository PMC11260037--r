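#' Plot scenario results
#'
#' Bar chart of mean validation accuracy (+/- SE over replicate runs) per
#' mating design, marginal over the other grid axes — the headline
#' design-comparison figure.
#'
#' @param object A `scenario_results`.
#' @param metric Column of the replicate table to summarise.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scenario_results <- function(object, metric = "a_val", ...) {
  reps <- object$replicates
  if ("error" %in% names(reps)) reps <- reps[is.na(reps$error), ]
  dat <- dplyr::summarise(
    dplyr::group_by(reps, .data$design),
    mean = mean(.data[[metric]]),
    se = sd(.data[[metric]]) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$design, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.2) +
    ggplot2::labs(x = "mating design", y = paste("mean", metric, "(± SE)")) +
    ggplot2::theme_minimal()
}

#' Plot an LD decay table
#'
#' Mean r2 per distance bin, one line per generation.
#'
#' @param object An `ld_table` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ld_table <- function(object, ...) {
  dat <- dplyr::mutate(object, mid = (.data$lo + .data$hi) / 2)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mid, y = .data$mean_r2,
                                    colour = factor(.data$generation))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "SNP pair distance (cM, bin midpoint)",
                  y = expression(mean ~ r^2), colour = "generation") +
    ggplot2::theme_minimal()
}
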