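#' Consistency of a footprint fraction with an unwinding amplitude
#'
#' If hexamers bound with a given face toward the duplex are the ones that
#' unwind, the orientation fraction and the single-turnover amplitude
#' estimate the same population and should agree within error. The check is
#' a two-sided z-score on the difference:
#' `z = |F_or - F_unwound| / sqrt(SE1^2 + SE2^2)`, consistent when
#' `z < 1.96`.
#'
#' @param f_or,f_unwound Fractions to compare.
#' @param se_or,se_unwound Their standard errors (> 0).
#' @return List: `z`, `consistent`.
#' @export
consistency_test <- function(f_or, se_or, f_unwound, se_unwound) {
  if (is.na(se_or) || is.na(se_unwound) || se_or <= 0 || se_unwound <= 0) {
    stop("both standard errors must be present and positive", call. = FALSE)
  }
  z <- abs(f_or - f_unwound) / sqrt(se_or^2 + se_unwound^2)
  list(z = z, consistent = z < 1.96)
}

#' Slow-phase sign pattern across stopped-flow conditions
#'
#' Extracts, for each fitted condition, the direction of the slowest phase
#' (the translocation-reporting phase): increase when its amplitude is
#' below `-2 SE`, decrease above `+2 SE`, flat otherwise. Degenerate fits
#' are marked missing rather than guessed.
#'
#' @param fits Named list of `multiexp_fit` objects (names or embedded
#'   conditions identify the experiment).
#' @return Tibble: `condition`, `label_site`, `block`, `slow_direction`,
#'   `slow_rate_s`, `slow_amplitude`.
#' @export
fret_sign_pattern <- function(fits) {
  purrr::imap_dfr(fits, function(fit, nm) {
    cond <- fit$condition
    base <- tibble::tibble(
      condition = if (!is.null(cond)) format(cond) else nm,
      label_site = if (!is.null(cond)) cond$label_site else NA_character_,
      block = if (!is.null(cond)) cond$block else NA_character_
    )
    if (isTRUE(fit$degenerate)) {
      return(dplyr::mutate(base, slow_direction = NA_character_,
                           slow_rate_s = NA_real_, slow_amplitude = NA_real_))
    }
    slow <- fit$phases[which.min(fit$phases$rate_s), ]
    dir <- if (is.na(slow$se_amplitude) ||
               abs(slow$amplitude) <= 2 * slow$se_amplitude) "flat"
           else if (slow$amplitude < 0) "increase" else "decrease"
    dplyr::mutate(base, slow_direction = dir,
                  slow_rate_s = slow$rate_s, slow_amplitude = slow$amplitude)
  })
}

#' Bundle evidence streams for the direction verdict
#'
#' @param footprint Tibble with one row per substrate: `substrate`, `F_N`,
#'   `se_F_N`.
#' @param unwinding Tibble: `substrate`, `productive_fraction`, `se`.
#' @param fret Sign-pattern tibble from [fret_sign_pattern()], or `NULL`.
#' @return A `direction_evidence` object.
#' @export
direction_evidence <- function(footprint = NULL, unwinding = NULL, fret = NULL) {
  if (is.null(footprint) && is.null(unwinding) && is.null(fret)) {
    stop("at least one evidence stream must be present", call. = FALSE)
  }
  structure(list(footprint = footprint, unwinding = unwinding, fret = fret),
            class = "direction_evidence")
}

#' Classify the translocation direction from combined evidence
#'
#' Decision table over two independent evidence streams:
#' \itemize{
#'   \item Footprint-unwinding correspondence: on at least one substrate the
#'     N@duplex fraction must be consistent (z < 1.96) with the productive
#'     amplitude while the C@duplex complement is not (supports N-first;
#'     mirrored pattern supports C-first).
#'   \item Blocked-substrate slow-phase signs: a slow rise for the
#'     N-terminal label together with no rise for the C-terminal label
#'     supports N-first; the mirrored pattern supports C-first.
#' }
#' A direction is returned only when both streams concur; anything else is
#' `indeterminate`, with the failing evidence lines listed. Relabelling N
#' and C throughout the evidence flips the verdict.
#'
#' @param evidence A [direction_evidence()].
#' @return A `direction_verdict`: `direction`, per-substrate `consistency`
#'   tibble, `fret_support`, `lines` (evidence lines with pass/fail).
#' @export
classify_translocation_direction <- function(evidence) {
  stopifnot(inherits(evidence, "direction_evidence"))
  lines <- character()
  consistency <- NULL
  stream_fp <- "none"

  if (!is.null(evidence$footprint) && !is.null(evidence$unwinding)) {
    joined <- dplyr::inner_join(evidence$footprint, evidence$unwinding,
                                by = "substrate")
    consistency <- joined |>
      dplyr::rowwise() |>
      dplyr::mutate(
        z_N = consistency_test(.data$F_N, .data$se_F_N,
                               .data$productive_fraction, .data$se)$z,
        z_C = consistency_test(1 - .data$F_N, .data$se_F_N,
                               .data$productive_fraction, .data$se)$z,
        N_consistent = .data$z_N < 1.96,
        C_consistent = .data$z_C < 1.96
      ) |>
      dplyr::ungroup()
    n_support <- any(consistency$N_consistent & !consistency$C_consistent)
    c_support <- any(consistency$C_consistent & !consistency$N_consistent)
    stream_fp <- if (n_support && !c_support) "N_first"
    else if (c_support && !n_support) "C_first" else "none"
    lines <- c(lines, sprintf(
      "footprint~unwinding [%s]: F_N consistent & F_C not on >=1 substrate -> %s",
      paste(consistency$substrate, collapse = ","), stream_fp))
  }

  stream_fret <- "none"
  if (!is.null(evidence$fret)) {
    blocked <- dplyr::filter(evidence$fret, .data$block == "streptavidin_present")
    n_rise <- any(blocked$slow_direction == "increase" &
                    blocked$label_site == "N_terminus", na.rm = TRUE)
    c_rise <- any(blocked$slow_direction == "increase" &
                    blocked$label_site == "C682", na.rm = TRUE)
    stream_fret <- if (n_rise && !c_rise) "N_first"
    else if (c_rise && !n_rise) "C_first" else "none"
    lines <- c(lines, sprintf(
      "blocked-substrate slow phase: N-label rise %s, C-label rise %s -> %s",
      n_rise, c_rise, stream_fret))
  }

  direction <- if (stream_fp != "none" && identical(stream_fp, stream_fret)) {
    stream_fp
  } else {
    "indeterminate"
  }
  structure(
    list(direction = direction, consistency = consistency,
         fret_support = stream_fret, footprint_support = stream_fp,
         lines = lines),
    class = "direction_verdict"
  )
}

#' @export
print.direction_verdict <- function(x, ...) {
  cat("<direction_verdict> ", x$direction, "\n", sep = "")
  for (l in x$lines) cat("  - ", l, "\n", sep = "")
  invisible(x)
}
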