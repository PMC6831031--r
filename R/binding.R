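#' Fit a cooperative (Hill) binding isotherm to an anisotropy titration
#'
#' Least-squares fit of `Y = Amax * x^n / (Kd^n + x^n)` to baseline-
#' subtracted anisotropy values (the model form forces `Y(0) = 0`, so the
#' free-DNA baseline is removed first via `baseline`). The Hill coefficient
#' is fitted freely within `[0.25, 8]` to keep shallow titrations from
#' diverging while allowing strong cooperativity. Titrations that never
#' leave the low- or high-saturation regime are rejected as unidentifiable.
#'
#' @param series Tibble (`conc_nM`, `anisotropy`) with strictly increasing
#'   concentrations, e.g. from [simulate_anisotropy_series()] or
#'   [read_titration()].
#' @param baseline Anisotropy of free DNA, subtracted before fitting.
#'   Default 0 (already-corrected data).
#' @return A `hill_fit` object: `Amax`, `Kd_nM`, `n`, standard errors,
#'   `rss`; see [tidy.hill_fit()].
#' @export
fit_hill <- function(series, baseline = 0) {
  stopifnot(all(c("conc_nM", "anisotropy") %in% names(series)))
  if (nrow(series) < 5) {
    stop("need at least 5 titration points to fit the Hill model", call. = FALSE)
  }
  if (any(series$conc_nM < 0) || any(diff(series$conc_nM) <= 0)) {
    stop("concentrations must be non-negative and strictly increasing",
         call. = FALSE)
  }
  df <- dplyr::mutate(series, y = .data$anisotropy - baseline)
  ymax <- max(df$y)
  if (ymax <= 0) stop("no positive anisotropy change to fit", call. = FALSE)
  kd0 <- df$conc_nM[which(df$y >= ymax / 2)[1]]
  if (is.na(kd0) || kd0 <= 0) kd0 <- stats::median(df$conc_nM[df$conc_nM > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ Amax * conc_nM^n / (Kd^n + conc_nM^n), data = df,
      start = list(Amax = ymax, Kd = kd0, n = 1),
      lower = c(Amax = 1e-12, Kd = 1e-9, n = 0.25),
      upper = c(Amax = Inf, Kd = Inf, n = 8),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop("Hill fit failed to converge: ", conditionMessage(e), call. = FALSE)
    }
  )
  est <- stats::coef(fit)
  sat <- df$conc_nM^est["n"] / (est["Kd"]^est["n"] + df$conc_nM^est["n"])
  if (all(sat < 0.2) || all(sat > 0.8)) {
    stop("titration is unidentifiable: all points lie ",
         if (all(sat < 0.2)) "below 20%" else "above 80%",
         " saturation of the fitted isotherm", call. = FALSE)
  }
  ses <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 3))
  structure(
    list(Amax = unname(est["Amax"]), Kd_nM = unname(est["Kd"]),
         n = unname(est["n"]),
         se_Amax = ses[1], se_Kd = ses[2], se_n = ses[3],
         rss = sum(stats::resid(fit)^2),
         fitted = dplyr::mutate(df, fitted = stats::fitted(fit))),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> Amax = %.4f +/- %.4f, Kd = %.1f +/- %.1f nM, n = %.2f +/- %.2f\n",
              x$Amax, x$se_Amax, x$Kd_nM, x$se_Kd, x$n, x$se_n))
  invisible(x)
}

#' Predict anisotropy from a Hill fit
#' @param object A `hill_fit`.
#' @param newdata Optional tibble with `conc_nM`.
#' @param ... Unused.
#' @return Numeric vector of predicted (baseline-subtracted) anisotropy.
#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$fitted$conc_nM else newdata$conc_nM
  object$Amax * x^object$n / (object$Kd_nM^object$n + x^object$n)
}
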