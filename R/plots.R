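#' Plot footprint orientation fractions
#'
#' Bar chart of the mean N@duplex and C@duplex fractions with replicate
#' standard errors and the significance label.
#' @param object A `footprint_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.footprint_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$orientation, y = .data$estimate,
                                   fill = .data$orientation)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$estimate - .data$std.error,
                   ymax = .data$estimate + .data$std.error),
      width = 0.15) +
    ggplot2::annotate("text", x = 1.5, y = max(df$estimate) * 1.08,
                      label = object$stars) +
    ggplot2::labs(y = "fraction of cleavage", x = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot an unwinding fit
#'
#' Observed fraction unwound with the fitted single-exponential rise.
#' @param object An `unwinding_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.unwinding_fit <- function(object, ...) {
  df <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$F)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::labs(x = "time (min)", y = "fraction unwound") +
    ggplot2::theme_minimal()
}

#' Plot a Hill binding fit
#' @param object A `hill_fit`.
#' @param ... Unused.
#' @return A ggplot object (log-scaled concentration axis).
#' @export
autoplot.hill_fit <- function(object, ...) {
  df <- object$fitted
  grid <- tibble::tibble(conc_nM = exp(seq(log(max(min(df$conc_nM), 1e-3)),
                                           log(max(df$conc_nM)),
                                           length.out = 200)))
  grid$fitted <- predict(object, grid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conc_nM)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted),
                       colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[protein] (nM)", y = "anisotropy change") +
    ggplot2::theme_minimal()
}

#' Plot a multi-exponential trace fit
#' @param object A `multiexp_fit`.
#' @param log_time Log-scale the time axis (useful for split time bases)?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.multiexp_fit <- function(object, log_time = TRUE, ...) {
  df <- object$fitted
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed),
                        size = 0.4, alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "fluorescence (a.u.)") +
    ggplot2::theme_minimal()
  if (log_time) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot footprint lane profiles
#'
#' Per-base intensity of each lane with the orientation regions shaded.
#' @param lanes Lane tibble (`replicate`, `base_index`, `intensity`,
#'   `is_control`).
#' @param regions Optional [region_map()] to shade.
#' @return A ggplot object.
#' @export
plot_profiles <- function(lanes, regions = NULL) {
  p <- ggplot2::ggplot(lanes, ggplot2::aes(x = .data$base_index,
                                           y = .data$intensity,
                                           colour = .data$replicate)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "base (from labelled end)", y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(regions)) {
    shade <- tibble::tibble(
      xmin = c(regions$n_region[1], regions$c_region[1]) - 0.5,
      xmax = c(regions$n_region[2], regions$c_region[2]) + 0.5,
      orientation = c("N@duplex", "C@duplex")
    )
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf, fill = .data$orientation),
      alpha = 0.12, inherit.aes = FALSE)
  }
  p
}
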