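#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an unwinding fit
#' @param x An `unwinding_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.unwinding_fit <- function(x, ...) {
  tibble::tibble(
    term = c("amplitude", "k_per_min"),
    estimate = c(x$amplitude, x$k_per_min),
    std.error = c(x$se_amplitude, x$se_k)
  )
}

#' @rdname tidy.unwinding_fit
#' @export
glance.unwinding_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, degenerate = x$degenerate,
                 n = nrow(x$fitted))
}

#' Tidy a Hill fit
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(
    term = c("Amax", "Kd_nM", "n"),
    estimate = c(x$Amax, x$Kd_nM, x$n),
    std.error = c(x$se_Amax, x$se_Kd, x$se_n)
  )
}

#' @rdname tidy.hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = nrow(x$fitted))
}

#' Tidy a multi-exponential fit
#' @param x A `multiexp_fit`.
#' @param ... Unused.
#' @return One row per parameter (phase amplitudes/rates and the offset).
#' @export
tidy.multiexp_fit <- function(x, ...) {
  ph <- x$phases
  dplyr::bind_rows(
    tibble::tibble(term = paste0("a", ph$phase), estimate = ph$amplitude,
                   std.error = ph$se_amplitude),
    tibble::tibble(term = paste0("k", ph$phase), estimate = ph$rate_s,
                   std.error = ph$se_rate),
    tibble::tibble(term = "C", estimate = x$C, std.error = x$se_C)
  )
}

#' @rdname tidy.multiexp_fit
#' @export
glance.multiexp_fit <- function(x, ...) {
  tibble::tibble(n_exp = x$n_exp, rss = x$rss, aicc = x$aicc,
                 degenerate = x$degenerate, n = x$n_points)
}

#' Tidy a footprint result
#' @param x A `footprint_result`.
#' @param ... Unused.
#' @return One row per orientation with mean fraction and standard error.
#' @export
tidy.footprint_result <- function(x, ...) {
  tibble::tibble(
    orientation = c("N_at_duplex", "C_at_duplex"),
    estimate = c(x$mean_F_N, x$mean_F_C),
    std.error = c(x$se_F_N, x$se_F_C)
  )
}

#' @rdname tidy.footprint_result
#' @export
glance.footprint_result <- function(x, ...) {
  tibble::tibble(
    n_replicates = x$n_replicates, t_statistic = x$t_statistic,
    p_value = x$p_value, stars = x$stars,
    classification = classify_binding_orientation(x)
  )
}
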