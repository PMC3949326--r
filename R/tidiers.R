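#' Tidy a psychometric result
#'
#' One row per displacement with the observed and fitted percentage of
#' forward reports.
#'
#' @param x a `lip_psychometric` from [run_ssd_experiment()].
#' @param ... unused.
#' @return A tibble with columns `label`, `condition`, `displacement`,
#'   `pct_forward`, `fitted`, `n_trials`.
#' @method tidy lip_psychometric
#' @export
tidy.lip_psychometric <- function(x, ...) {
  dplyr::mutate(x$curve,
                label = x$label, condition = x$condition,
                fitted = 100 * pnorm((.data$displacement - x$mu) / x$sigma),
                .before = 1)
}

#' Glance at a psychometric result
#'
#' @param x a `lip_psychometric`.
#' @param ... unused.
#' @return A one-row tibble: `label`, `condition`, ablation flags, fitted
#'   `mu` and `sigma` (degrees), trials per displacement and total trials.
#' @method glance lip_psychometric
#' @export
glance.lip_psychometric <- function(x, ...) {
  tibble::tibble(label = x$label, condition = x$condition,
                 variant = x$ablation$variant,
                 remapping_feedback = x$ablation$remapping_feedback,
                 corollary_discharge = x$ablation$corollary_discharge,
                 mu = x$mu, sigma = x$sigma,
                 n_trials = x$n_trials,
                 total_trials = nrow(x$trials))
}

#' @method tidy lip_psychofit
#' @export
tidy.lip_psychofit <- function(x, ...) {
  tibble::tibble(term = c("mu", "sigma"),
                 estimate = c(x$mu, x$sigma))
}

#' @method glance lip_psychofit
#' @export
glance.lip_psychofit <- function(x, ...) {
  tibble::tibble(mu = x$mu, sigma = x$sigma, sse = x$sse,
                 n = length(x$displacements))
}

#' Plot a psychometric curve
#'
#' Simulated percentages of forward reports (points) with the fitted
#' cumulative Gaussian (line).
#'
#' @param object a `lip_psychometric`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot lip_psychometric
#' @export
autoplot.lip_psychometric <- function(object, ...) {
  grid <- tibble::tibble(
    displacement = seq(min(object$curve$displacement),
                       max(object$curve$displacement), length.out = 200))
  grid$fitted <- 100 * pnorm((grid$displacement - object$mu) / object$sigma)
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$displacement,
                               y = .data$pct_forward)) +
    ggplot2::geom_point(shape = 4, size = 2) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$fitted)) +
    ggplot2::labs(
      x = "target displacement (deg)", y = "% forward reports",
      title = object$label,
      subtitle = sprintf("mu = %.2f deg, sigma = %.2f deg",
                         object$mu, object$sigma)) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' Plot remapping time courses
#'
#' Mean response of the tracked LIP(CD) cell in the 50-350 ms window after
#' flash onset, against flash time relative to saccade onset, for the
#' present- and future-receptive-field probes.
#'
#' @param object a `lip_remap` from [run_remapping()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot lip_remap
#' @export
autoplot.lip_remap <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              -"flash_time",
                              names_to = "probe", values_to = "response")
  long$probe <- sub("_response$", "", long$probe)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$flash_time,
                                     y = .data$response,
                                     colour = .data$probe)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "flash time relative to saccade onset (ms)",
                  y = "mean rate, 50-350 ms after flash",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
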