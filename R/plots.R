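#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bland-Altman plot
#'
#' Scatter of per-pair differences against per-pair means, with the bias
#' (solid) and 95% limits of agreement (dashed) drawn as horizontal lines.
#'
#' @param object A `par24_blandaltman` object.
#' @param ... Unused.
#' @return A ggplot.
#' @examples
#' pairs <- tibble::tibble(value_a = rnorm(20, 100, 10), value_b = rnorm(20, 95, 10))
#' autoplot(bland_altman(pairs))
#' @method autoplot par24_blandaltman
#' @export
autoplot.par24_blandaltman <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(
      x = "Mean of the two measurements",
      y = "Difference (A - B)",
      title = sprintf("Bland-Altman: bias %.1f, LoA [%.1f, %.1f] (n = %d)",
                      object$bias, object$loa_lower, object$loa_upper, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Bland-Altman panels for a study report
#'
#' One Bland-Altman panel per compared quantity, faceted.
#'
#' @param object A `par24_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot par24_report
#' @export
autoplot.par24_report <- function(object, ...) {
  pts <- purrr::imap(object$pairs, function(pairs, quantity) {
    ba <- bland_altman(pairs)
    dplyr::mutate(ba$points, quantity = quantity, bias = ba$bias,
                  loa_lower = ba$loa_lower, loa_upper = ba$loa_upper)
  })
  pts <- dplyr::bind_rows(pts)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$bias), linewidth = 0.5) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$loa_lower),
                        linetype = "dashed") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$loa_upper),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::labs(x = "Mean of the two measurements", y = "Difference (A - B)",
                  title = sprintf("Bland-Altman agreement, %s study", object$study)) +
    ggplot2::theme_minimal()
}

#' Minute-level intensity profile plot
#'
#' Step plot of a 1440-minute MET profile with the intensity boundaries at
#' 1.5 and 3.0 MET.
#'
#' @param profile Numeric vector of 1440 MET values.
#' @return A ggplot.
#' @export
plot_met_profile <- function(profile) {
  stopifnot(length(profile) == 1440)
  df <- tibble(minute = 0:1439, met = profile)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$minute / 60, y = .data$met)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = c(1.5, 3), linetype = "dotted") +
    ggplot2::labs(x = "Hour of day", y = "MET") +
    ggplot2::theme_minimal()
}
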