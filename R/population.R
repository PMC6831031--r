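#' Binding-population mixture over (arm x orientation) configurations
#'
#' A hexamer loaded on fork DNA can sit on either single-stranded arm in
#' either orientation: N-face toward the duplex junction (N@duplex) or
#' C-face toward it (C@duplex). A binding population assigns a probability
#' to each of the four configurations plus an unbound fraction; the five
#' must sum to one.
#'
#' @param arm3_N,arm3_C Probability of binding the 3'-arm (encircled strand)
#'   with N@duplex / C@duplex.
#' @param arm5_N,arm5_C Same for the 5'-arm (excluded strand).
#' @param unbound Probability of no hexamer bound.
#' @return A `binding_population` object with a `probs` tibble
#'   (`arm`, `orientation`, `prob`) and the `unbound` fraction.
#' @examples
#' binding_population(arm3_N = 0.23, arm3_C = 0.77)
#' @export
binding_population <- function(arm3_N = 0, arm3_C = 0,
                               arm5_N = 0, arm5_C = 0,
                               unbound = NULL) {
  p <- c(arm3_N = arm3_N, arm3_C = arm3_C, arm5_N = arm5_N, arm5_C = arm5_C)
  if (any(p < 0 | p > 1)) {
    stop("configuration probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(unbound)) unbound <- 1 - sum(p)
  if (unbound < -1e-12 || unbound > 1 + 1e-12) {
    stop("configuration probabilities sum to ", format(sum(p)),
         "; unbound fraction would fall outside [0, 1]", call. = FALSE)
  }
  unbound <- min(max(unbound, 0), 1)
  if (abs(sum(p) + unbound - 1) > 1e-12) {
    stop("configuration probabilities + unbound must sum to 1 (got ",
         format(sum(p) + unbound), ")", call. = FALSE)
  }
  probs <- tibble::tibble(
    arm = rep(c("arm3", "arm5"), each = 2),
    orientation = rep(c("N_at_duplex", "C_at_duplex"), times = 2),
    prob = unname(p)
  )
  structure(list(probs = probs, unbound = unbound),
            class = "binding_population")
}

#' @export
print.binding_population <- function(x, ...) {
  cat("<binding_population>  unbound:", format(x$unbound), "\n")
  print(x$probs)
  invisible(x)
}

#' Aggregate orientation probability of a population
#'
#' Sum of configuration probabilities with the given orientation across both
#' arms. `fraction = TRUE` divides by the total bound probability, giving
#' the orientation fraction a footprint experiment estimates.
#'
#' @param population A [binding_population()].
#' @param orientation `"N_at_duplex"` or `"C_at_duplex"`.
#' @param fraction Normalize by the bound fraction?
#' @return A single probability.
#' @export
aggregate_orientation <- function(population,
                                  orientation = c("N_at_duplex", "C_at_duplex"),
                                  fraction = FALSE) {
  stopifnot(inherits(population, "binding_population"))
  orientation <- match.arg(orientation)
  s <- sum(population$probs$prob[population$probs$orientation == orientation])
  if (fraction) {
    bound <- sum(population$probs$prob)
    if (bound <= 0) stop("population has no bound mass", call. = FALSE)
    s <- s / bound
  }
  s
}

#' Productive fraction of a population under a translocation rule
#'
#' Single-turnover unwinding amplitude equals the probability of the
#' productive configuration: the hexamer on the arm that leads 3'->5' into
#' the duplex (the 3'-arm / encircled strand), oriented so its leading face
#' points at the duplex -- N@duplex under an N-first rule, C@duplex under
#' C-first.
#'
#' @param population A [binding_population()].
#' @param productive_rule `"N_first"` or `"C_first"`.
#' @return Probability of the productive configuration.
#' @export
productive_probability <- function(population,
                                   productive_rule = c("N_first", "C_first")) {
  stopifnot(inherits(population, "binding_population"))
  productive_rule <- match.arg(productive_rule)
  ori <- if (productive_rule == "N_first") "N_at_duplex" else "C_at_duplex"
  with(population$probs, sum(prob[arm == "arm3" & orientation == ori]))
}

#' Swap N and C orientations throughout a population
#'
#' Used to build mirrored ground truths: a C-first world whose evidence is
#' the exact reflection of an N-first one.
#' @param population A [binding_population()].
#' @return A [binding_population()] with orientations exchanged.
#' @export
mirror_population <- function(population) {
  stopifnot(inherits(population, "binding_population"))
  p <- stats::setNames(population$probs$prob,
                       paste(population$probs$arm, population$probs$orientation,
                             sep = "."))
  binding_population(
    arm3_N = p[["arm3.C_at_duplex"]], arm3_C = p[["arm3.N_at_duplex"]],
    arm5_N = p[["arm5.C_at_duplex"]], arm5_C = p[["arm5.N_at_duplex"]],
    unbound = population$unbound
  )
}

#' Cleavage probe model for footprint simulation
#'
#' The cleavage reagent is conjugated near one face of the hexamer; cuts
#' land around the probe contact with a roughly Gaussian positional spread.
#' The hexamer also cuts the strand it does not encircle (the DNA-binding
#' domain is flexible enough to reach across the fork), captured as a
#' cross-strand cut probability that scales -- but does not reposition --
#' the contribution of configurations bound on the unlabelled strand's arm.
#'
#' @param footprint_span Footprint of the hexamer on DNA, nt.
#' @param probe_offset Offset (nt) of the cleavage centre from the assigned
#'   region's midpoint, applied away from the boundary shared with the other
#'   orientation's region. The default places each centre about three
#'   cleavage_sd from that boundary, so cross-region leakage is negligible
#'   and well over 90% of each kernel's (window-truncated) mass lies inside
#'   its assigned region.
#' @param cleavage_sd Gaussian spread of cut positions, nt.
#' @param cross_strand_prob Relative cut efficiency on the non-encircled
#'   strand, in \[0, 1\].
#' @param background_rate Uniform per-base background intensity (arbitrary
#'   densitometry units).
#' @param cleavage_mass Total above-background intensity a fully bound lane
#'   deposits (arbitrary units; cancels in all downstream ratios).
#' @return A `probe_model` object.
#' @export
probe_model <- function(footprint_span = 24,
                        probe_offset = 4,
                        cleavage_sd = 4,
                        cross_strand_prob = 0.3,
                        background_rate = 50,
                        cleavage_mass = 4e4) {
  stopifnot(footprint_span > 0, cleavage_sd > 0,
            cross_strand_prob >= 0, cross_strand_prob <= 1,
            background_rate >= 0, cleavage_mass > 0)
  structure(
    list(footprint_span = footprint_span, probe_offset = probe_offset,
         cleavage_sd = cleavage_sd, cross_strand_prob = cross_strand_prob,
         background_rate = background_rate, cleavage_mass = cleavage_mass),
    class = "probe_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
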