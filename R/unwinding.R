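#' Fraction unwound from band intensities
#'
#' Converts single-strand / duplex band intensities to the fraction
#' unwound, normalized between the zero-time lane and the boiled (fully
#' denatured) control: with `r(t) = Is(t) / (Is(t) + Id(t))`,
#' `F(t) = (r(t) - r(0)) / (r(b) - r(0))`. `F(0)` is 0 by construction and
#' `F` evaluates to 1 on the boiled row itself; noisy observations may fall
#' slightly outside `[0, 1]` and are reported un-clamped. Multiplying all
#' bands of a row by a positive constant (lane loading) leaves `F`
#' unchanged.
#'
#' @param tc A band time course tibble (`time_min`, `Is`, `Id`, `row_type`)
#'   with one `zero` and one `boiled` row, as from
#'   [simulate_unwinding_timecourse()] or [read_timecourse()].
#' @return Tibble (`time_min`, `F`) over the zero and observation rows.
#' @export
fraction_unwound <- function(tc) {
  zero <- dplyr::filter(tc, .data$row_type == "zero")
  boiled <- dplyr::filter(tc, .data$row_type == "boiled")
  if (nrow(zero) != 1 || nrow(boiled) != 1) {
    stop("time course must contain exactly one zero-time and one boiled row",
         call. = FALSE)
  }
  obs <- dplyr::filter(tc, .data$row_type %in% c("zero", "obs"))
  tot <- obs$Is + obs$Id
  if (any(tot <= 0) || (zero$Is + zero$Id) <= 0 || (boiled$Is + boiled$Id) <= 0) {
    stop("row with zero total band intensity; cannot form band ratio",
         call. = FALSE)
  }
  r <- obs$Is / tot
  r0 <- zero$Is / (zero$Is + zero$Id)
  rb <- boiled$Is / (boiled$Is + boiled$Id)
  denom <- rb - r0
  if (denom <= 0) {
    stop("normalization error: boiled-control single-strand ratio (",
         signif(rb, 3), ") does not exceed the zero-time ratio (",
         signif(r0, 3), ")", call. = FALSE)
  }
  out <- tibble::tibble(time_min = obs$time_min, F = (r - r0) / denom)
  # the zero-time and boiled anchors are single noisy lanes; record that this
  # series was anchor-normalized so the fit can propagate their uncertainty
  attr(out, "normalization") <- list(r0 = r0, rb = rb)
  out
}

#' Fit a single-exponential rise to a fraction-unwound series
#'
#' Least-squares fit of `F(t) = Af * (1 - exp(-k t))`, the rising
#' re-parameterization of the offset-exponential `C + A exp(-k t)` with
#' `Af = C = -A`, so the fitted amplitude is directly the productive
#' fraction. Bounds `0 <= Af <= 1`, `k > 0`; initial guesses are the series
#' maximum and the reciprocal time of half-maximal signal. A series with no
#' resolvable signal is flagged degenerate rather than fitted.
#'
#' For a series produced by [fraction_unwound()] the amplitude standard
#' error additionally propagates the uncertainty of the zero-time and
#' boiled normalization anchors: those are single noisy lanes shared by
#' every point, so their error moves the whole series coherently and is
#' invisible to point-wise fit residuals. Taking the anchors' band-ratio
#' noise as equal to the per-point residual scale `s`, the delta method
#' adds `s^2 * ((1 - Af)^2 + Af^2)` to the amplitude variance (a slightly
#' conservative bound, since part of an anchor shift is absorbed by the
#' free rate).
#'
#' @param series Tibble (`time_min`, `F`), e.g. from [fraction_unwound()].
#' @return An `unwinding_fit` object (see [tidy.unwinding_fit()]) with
#'   fields `amplitude`, `k_per_min`, standard errors, `rss`, `degenerate`.
#' @export
fit_single_exponential <- function(series) {
  stopifnot(all(c("time_min", "F") %in% names(series)))
  series <- dplyr::arrange(series, .data$time_min)
  if (nrow(series) < 4) {
    stop("need at least 4 time points to fit the exponential", call. = FALSE)
  }
  fmax <- max(series$F)
  if (fmax < 0.01) {
    return(structure(
      list(amplitude = 0, k_per_min = NA_real_, se_amplitude = NA_real_,
           se_k = NA_real_, rss = sum(series$F^2), degenerate = TRUE,
           fitted = dplyr::mutate(series, fitted = 0)),
      class = "unwinding_fit"
    ))
  }
  t_half <- series$time_min[which(series$F >= fmax / 2)[1]]
  k0 <- 1 / max(t_half, min(series$time_min[series$time_min > 0]))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      F ~ Af * (1 - exp(-k * time_min)), data = series,
      start = list(Af = min(max(fmax, 0.02), 1), k = k0),
      lower = c(Af = 0, k = 1e-8), upper = c(Af = 1, k = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop("single-exponential fit failed to converge (start Af=",
           signif(fmax, 3), ", k=", signif(k0, 3), "): ",
           conditionMessage(e), call. = FALSE)
    }
  )
  est <- stats::coef(fit)
  ses <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA, NA))
  rss <- sum(stats::resid(fit)^2)
  se_af <- unname(ses[1])
  if (!is.null(attr(series, "normalization")) && !is.na(se_af)) {
    af <- unname(est["Af"])
    s2 <- rss / max(nrow(series) - 2, 1)
    se_af <- sqrt(se_af^2 + s2 * ((1 - af)^2 + af^2))
  }
  structure(
    list(amplitude = unname(est["Af"]), k_per_min = unname(est["k"]),
         se_amplitude = se_af, se_k = unname(ses[2]),
         rss = rss, degenerate = FALSE,
         fitted = dplyr::mutate(series, fitted = stats::fitted(fit))),
    class = "unwinding_fit"
  )
}

#' @export
print.unwinding_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<unwinding_fit> degenerate: amplitude ~ 0, rate unidentifiable\n")
  } else {
    cat(sprintf("<unwinding_fit> Af = %.3f +/- %.3f, k = %.4f +/- %.4f min^-1 (rss %.3g)\n",
                x$amplitude, x$se_amplitude, x$k_per_min, x$se_k, x$rss))
  }
  invisible(x)
}

#' Productive unwinding fraction from a fit
#'
#' The single-turnover amplitude is the fraction of complexes bound in the
#' productive, processive configuration.
#'
#' @param fit An `unwinding_fit` from [fit_single_exponential()].
#' @return One-row tibble (`productive_fraction`, `se`).
#' @export
productive_fraction <- function(fit) {
  stopifnot(inherits(fit, "unwinding_fit"))
  if (fit$degenerate) {
    stop("fit is degenerate (no resolvable amplitude); productive fraction undefined",
         call. = FALSE)
  }
  tibble::tibble(productive_fraction = fit$amplitude, se = fit$se_amplitude)
}

#' Convert rates between per-minute and per-second
#' @param k Rate value(s).
#' @return Converted rate(s).
#' @export
per_min_to_per_sec <- function(k) k / 60

#' @rdname per_min_to_per_sec
#' @export
per_sec_to_per_min <- function(k) k * 60
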