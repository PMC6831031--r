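#' Subtract a protein-free control lane from a footprint lane
#'
#' Per-base subtraction with clamping at zero: densitometry cannot be
#' negative and the downstream ratio presumes non-negative mass.
#'
#' @param lane,control Tibbles with columns `base_index`, `intensity`
#'   covering the same strand (e.g. one replicate and the control from
#'   [simulate_cleavage_profiles()] or [read_profiles()]).
#' @return The lane tibble with `intensity` replaced by
#'   `max(lane - control, 0)` and a `background_subtracted` attribute.
#' @export
background_subtract <- function(lane, control) {
  if (nrow(lane) != nrow(control) ||
      !identical(lane$base_index, control$base_index)) {
    stop("lane and control profiles must cover the same bases", call. = FALSE)
  }
  out <- dplyr::mutate(lane, intensity = pmax(.data$intensity - control$intensity, 0))
  attr(out, "background_subtracted") <- TRUE
  out
}

#' Orientation fractions of one background-subtracted lane
#'
#' Sums the corrected cleavage intensity over the two orientation regions
#' and forms the ratio `F_N = S_N / (S_N + S_C)` (and its complement `F_C`):
#' the fraction of cleavage attributable to hexamers bound N-face toward
#' the duplex. Per-lane scale cancels, so no further normalization is
#' applied.
#'
#' @param corrected A background-subtracted lane (see
#'   [background_subtract()]).
#' @param regions A [region_map()].
#' @return One-row tibble: `S_N`, `S_C`, `F_N`, `F_C`.
#' @export
orientation_fraction <- function(corrected, regions) {
  stopifnot(inherits(regions, "region_map"))
  if (!isTRUE(attr(corrected, "background_subtracted"))) {
    stop("profile must be background-subtracted first (see background_subtract())",
         call. = FALSE)
  }
  in_region <- function(r) {
    sum(corrected$intensity[corrected$base_index >= r[1] &
                              corrected$base_index <= r[2]])
  }
  s_n <- in_region(regions$n_region)
  s_c <- in_region(regions$c_region)
  tot <- s_n + s_c
  if (tot <= 0) {
    stop("degenerate lane: no corrected intensity in either orientation region",
         call. = FALSE)
  }
  tibble::tibble(S_N = s_n, S_C = s_c, F_N = s_n / tot, F_C = s_c / tot)
}

#' Compare N@duplex vs C@duplex replicate fractions
#'
#' Two-sample, two-tailed, equal-variance (pooled) t-test of the replicate
#' F_N values against the replicate F_C values, with the conventional star
#' labels.
#'
#' @param f_n,f_c Numeric vectors of replicate fractions (>= 2 each).
#' @return A list: `t_statistic`, `p_value`, `stars`.
#' @export
compare_orientations <- function(f_n, f_c) {
  if (length(f_n) < 2 || length(f_c) < 2) {
    stop("need at least 2 replicates per orientation for the t-test",
         call. = FALSE)
  }
  tt <- stats::t.test(f_n, f_c, var.equal = TRUE)
  list(
    t_statistic = unname(tt$statistic),
    p_value = tt$p.value,
    stars = p_stars(tt$p.value)
  )
}

p_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "n.s."
}

#' Full footprint quantification of a replicate lane set
#'
#' Background-subtracts every replicate against the control lane, computes
#' per-replicate orientation fractions, their means and standard errors,
#' and the N-vs-C significance test. Fractions are computed per replicate
#' and then averaged (matching how replicate standard errors are reported
#' for 3-5 independent experiments), not on an averaged lane.
#'
#' @param lanes Tibble of lane profiles (`replicate`, `base_index`,
#'   `intensity`, `is_control`) including exactly one control lane, as
#'   produced by [simulate_cleavage_profiles()] or [read_profiles()].
#' @param regions A [region_map()].
#' @return A `footprint_result` object; see [tidy.footprint_result()].
#' @export
footprint_analysis <- function(lanes, regions) {
  stopifnot(inherits(regions, "region_map"))
  ctrl <- dplyr::filter(lanes, .data$is_control)
  reps <- dplyr::filter(lanes, !.data$is_control)
  if (length(unique(ctrl$replicate)) != 1) {
    stop("lane set must contain exactly one control lane", call. = FALSE)
  }
  per_rep <- reps |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_modify(function(df, key) {
      orientation_fraction(background_subtract(df, ctrl), regions)
    }) |>
    dplyr::ungroup()

  n <- nrow(per_rep)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  test <- if (n >= 2) compare_orientations(per_rep$F_N, per_rep$F_C) else
    list(t_statistic = NA_real_, p_value = NA_real_, stars = NA_character_)

  structure(
    list(
      replicates = per_rep,
      n_replicates = n,
      mean_F_N = mean(per_rep$F_N), mean_F_C = mean(per_rep$F_C),
      se_F_N = if (n >= 2) se(per_rep$F_N) else NA_real_,
      se_F_C = if (n >= 2) se(per_rep$F_C) else NA_real_,
      t_statistic = test$t_statistic,
      p_value = test$p_value,
      stars = test$stars,
      regions = regions
    ),
    class = "footprint_result"
  )
}

#' @export
print.footprint_result <- function(x, ...) {
  cat("<footprint_result>  n =", x$n_replicates, "replicates\n")
  cat(sprintf("  F_N = %.3f +/- %.3f   F_C = %.3f +/- %.3f\n",
              x$mean_F_N, x$se_F_N, x$mean_F_C, x$se_F_C))
  cat(sprintf("  t = %.3f, p = %.4g  %s  ->  %s\n",
              x$t_statistic, x$p_value, x$stars,
              classify_binding_orientation(x)))
  invisible(x)
}

#' Classify the preferred binding orientation
#'
#' Assigns the preference to the larger mean orientation fraction when the
#' N-vs-C difference is significant at 0.05; otherwise no preference.
#'
#' @param result A `footprint_result` from [footprint_analysis()].
#' @return `"N_at_duplex_preferred"`, `"C_at_duplex_preferred"` or
#'   `"no_preference"`.
#' @export
classify_binding_orientation <- function(result) {
  stopifnot(inherits(result, "footprint_result"))
  if (is.na(result$p_value) || result$p_value >= 0.05) return("no_preference")
  if (result$mean_F_N > result$mean_F_C) "N_at_duplex_preferred"
  else "C_at_duplex_preferred"
}
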