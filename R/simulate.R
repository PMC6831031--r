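#' Ground-truth record attached to every simulated dataset
#'
#' Each simulator stamps its output with the parameters that generated it,
#' so recovery tests can compare estimates against truth and datasets
#' round-trip through the writers/readers with their provenance.
#'
#' @param population A [binding_population()] or `NULL`.
#' @param productive_rule `"N_first"`, `"C_first"` or `NULL`.
#' @param kinetics Named list of true kinetic parameters.
#' @param seed Integer seed used.
#' @param ... Further metadata fields.
#' @return A `truth_record` object.
#' @export
truth_record <- function(population = NULL, productive_rule = NULL,
                         kinetics = list(), seed = NA_integer_, ...) {
  structure(
    list(population = population, productive_rule = productive_rule,
         kinetics = kinetics, seed = seed, extra = list(...)),
    class = "truth_record"
  )
}

#' Retrieve the truth record of a simulated dataset
#' @param x A simulated dataset.
#' @return The [truth_record()], or `NULL` for real data.
#' @export
get_truth <- function(x) attr(x, "truth", exact = TRUE)

set_truth <- function(x, truth) {
  attr(x, "truth") <- truth
  x
}

with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, !is.na(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# lognormal multiplier with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Discretized Gaussian cleavage kernel over the single-strand window,
# renormalized to unit mass. Errors if essentially no mass lands in-window.
cleavage_kernel <- function(center, sd, window, label) {
  bases <- seq.int(window[1], window[2])
  w <- stats::dnorm(bases, mean = center, sd = sd)
  if (sum(w) < 1e-8) {
    stop("cleavage kernel for configuration '", label,
         "' falls entirely outside the single-strand window [",
         window[1], ", ", window[2], "]", call. = FALSE)
  }
  stats::setNames(w / sum(w), bases)
}

#' Simulate footprint lane profiles from a binding population
#'
#' Generates per-base cleavage intensity profiles of the labelled strand for
#' a mixture of binding configurations, plus a protein-free control lane.
#' Each bound configuration deposits a Gaussian-spread packet of cleavage
#' centred in the region its orientation maps to (N@duplex near the
#' junction, C@duplex distal), truncated to the single-strand window;
#' configurations bound on the unlabelled strand's arm contribute at the
#' probe model's cross-strand efficiency. A uniform background underlies
#' every lane and multiplicative lognormal noise (coefficient of variation
#' `noise_cv`) acts per base.
#'
#' @param substrate A [fork_substrate()].
#' @param regions A [region_map()]; defaults to [default_region_map()].
#' @param population A [binding_population()].
#' @param probe A [probe_model()].
#' @param n_replicates Number of replicate lanes.
#' @param noise_cv Per-base lognormal noise CV.
#' @param seed Integer seed; identical arguments and seed reproduce the
#'   output bit-identically.
#' @return A tibble with columns `replicate`, `base_index`, `intensity`,
#'   `is_control`, carrying the generating [truth_record()] as an attribute.
#' @export
simulate_cleavage_profiles <- function(substrate,
                                       regions = default_region_map(substrate),
                                       population,
                                       probe = probe_model(),
                                       n_replicates = 5,
                                       noise_cv = 0.10,
                                       seed) {
  stopifnot(inherits(substrate, "fork_substrate"),
            inherits(regions, "region_map"),
            inherits(population, "binding_population"),
            inherits(probe, "probe_model"),
            n_replicates >= 1, noise_cv >= 0)
  L <- substrate$labelled_strand_len
  if (regions$strand_len != L) {
    stop("region map is for a ", regions$strand_len,
         "-nt strand but the substrate's labelled strand is ", L, " nt",
         call. = FALSE)
  }
  win <- ss_window(regions)

  # cleavage centres: region midpoints pushed probe_offset nt away from the
  # boundary the two regions share
  mid_n <- mean(regions$n_region)
  mid_c <- mean(regions$c_region)
  away <- sign(mid_n - mid_c)  # direction from C-region toward N-region
  center_n <- mid_n + away * probe$probe_offset
  center_c <- mid_c - away * probe$probe_offset

  labelled_arm <- if (substrate$labelled_strand == "encircled_3arm") "arm3" else "arm5"
  mean_profile <- rep(0, L)
  for (i in seq_len(nrow(population$probs))) {
    cfg <- population$probs[i, ]
    if (cfg$prob == 0) next
    strand_wt <- if (cfg$arm == labelled_arm) 1 else probe$cross_strand_prob
    center <- if (cfg$orientation == "N_at_duplex") center_n else center_c
    kern <- cleavage_kernel(center, probe$cleavage_sd, win,
                            paste(cfg$arm, cfg$orientation, sep = "/"))
    idx <- as.integer(names(kern))
    mean_profile[idx] <- mean_profile[idx] +
      probe$cleavage_mass * cfg$prob * strand_wt * kern
  }
  mean_profile <- mean_profile + probe$background_rate

  lanes <- with_seed(seed, {
    reps <- purrr::map(seq_len(n_replicates), function(r) {
      tibble::tibble(
        replicate = paste0("rep", r),
        base_index = seq_len(L),
        intensity = mean_profile * rlnorm_cv(L, noise_cv),
        is_control = FALSE
      )
    })
    ctrl <- tibble::tibble(
      replicate = "control",
      base_index = seq_len(L),
      intensity = probe$background_rate * rlnorm_cv(L, noise_cv),
      is_control = TRUE
    )
    dplyr::bind_rows(reps, list(ctrl))
  })
  set_truth(lanes, truth_record(
    population = population, seed = seed,
    kinetics = list(),
    substrate = substrate$name,
    aggregate_F_N = if (sum(population$probs$prob) > 0) {
      aggregate_orientation(population, "N_at_duplex", fraction = TRUE)
    } else NA_real_,
    probe = unclass(probe), noise_cv = noise_cv
  ))
}

#' Simulate a single-turnover unwinding time course
#'
#' Under single-turnover conditions (ATP plus excess trap DNA) only hexamers
#' already bound in the productive configuration unwind, so the true
#' fraction unwound follows `F(t) = p * (1 - exp(-k t))` with amplitude `p`
#' equal to the productive-configuration probability. Band intensities are
#' emitted as `Is = F * S + leak` and `Id = (1 - F) * S + leak` with
#' additive Gaussian noise, together with tagged zero-time and
#' boiled-control rows so the normalization of the fraction-unwound
#' calculation is exercised non-trivially.
#'
#' @param population A [binding_population()], or a single number taken
#'   directly as the productive probability `p`.
#' @param productive_rule `"N_first"` or `"C_first"`; which face leads into
#'   the duplex on the encircled strand.
#' @param k Unwinding rate, per minute.
#' @param times Sampling times in minutes; must start at 0 and be strictly
#'   increasing.
#' @param noise_sd Band noise as a fraction of the total signal `S`.
#' @param seed Integer seed.
#' @param signal,leak Total convertible band signal and per-band leak
#'   (arbitrary gel-densitometry units).
#' @return A tibble (`time_min`, `Is`, `Id`, `row_type`) with `row_type` in
#'   `obs`/`zero`/`boiled`, carrying its [truth_record()].
#' @export
simulate_unwinding_timecourse <- function(population,
                                          productive_rule = c("N_first", "C_first"),
                                          k,
                                          times = default_unwinding_times(),
                                          noise_sd = 0.02,
                                          seed,
                                          signal = 1000,
                                          leak = 50) {
  productive_rule <- match.arg(productive_rule)
  stopifnot(k > 0, noise_sd >= 0, signal > 0, leak >= 0)
  if (is.numeric(population) && length(population) == 1) {
    p <- population
    stopifnot(p >= 0, p <= 1)
    population <- NULL
  } else {
    stopifnot(inherits(population, "binding_population"))
    p <- productive_probability(population, productive_rule)
  }
  if (times[1] != 0) stop("times must include 0 as the first point", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }

  f_true <- p * (1 - exp(-k * times))
  tc <- with_seed(seed, {
    noisy <- function(x) pmax(x + stats::rnorm(length(x), 0, noise_sd * signal), 0)
    obs <- tibble::tibble(
      time_min = times,
      Is = noisy(f_true * signal + leak),
      Id = noisy((1 - f_true) * signal + leak),
      row_type = dplyr::if_else(times == 0, "zero", "obs")
    )
    boiled <- tibble::tibble(
      time_min = NA_real_,
      Is = noisy(signal + leak), Id = noisy(leak),
      row_type = "boiled"
    )
    dplyr::bind_rows(obs, boiled)
  })
  set_truth(tc, truth_record(
    population = population, productive_rule = productive_rule,
    kinetics = list(amplitude = p, k_per_min = k),
    seed = seed, noise_sd = noise_sd
  ))
}

#' Default gel sampling scheme for unwinding assays
#'
#' Twelve points over 0-240 min, log-like spacing chosen to resolve rates
#' around 0.07 per minute (half-time near 10 min).
#' @return Numeric vector of times in minutes.
#' @export
default_unwinding_times <- function() {
  c(0, 2, 5, 10, 20, 30, 45, 60, 90, 120, 180, 240)
}

#' Simulate an equilibrium anisotropy titration
#'
#' Cooperative (Hill) saturation `Y = Amax * x^n / (Kd^n + x^n)` with
#' additive Gaussian noise.
#'
#' @param Amax Maximal anisotropy change.
#' @param Kd Half-saturation concentration, nM.
#' @param n Hill coefficient.
#' @param concentrations Protein concentrations, nM (hexamer equivalents).
#' @param noise_sd Gaussian noise sd, anisotropy units.
#' @param seed Integer seed.
#' @return A tibble (`conc_nM`, `anisotropy`) with its [truth_record()].
#' @export
simulate_anisotropy_series <- function(Amax, Kd, n, concentrations,
                                       noise_sd = 0.003, seed) {
  stopifnot(Kd > 0, n > 0, noise_sd >= 0)
  if (length(concentrations) == 0) {
    stop("concentrations must be a non-empty vector", call. = FALSE)
  }
  if (any(concentrations < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  y <- Amax * concentrations^n / (Kd^n + concentrations^n)
  ser <- with_seed(seed, tibble::tibble(
    conc_nM = concentrations,
    anisotropy = y + stats::rnorm(length(y), 0, noise_sd)
  ))
  set_truth(ser, truth_record(
    kinetics = list(Amax = Amax, Kd = Kd, n = n), seed = seed
  ))
}

#' Condition descriptor for a stopped-flow experiment
#'
#' Enumerates the experimental axes the trace interpretation depends on:
#' where the donor dye sits on the hexamer, whether a streptavidin roadblock
#' is on the translocating strand, the substrate class, and whether ATP is
#' present. Unknown values are rejected.
#'
#' @param label_site `"N_terminus"` or `"C682"`.
#' @param block `"streptavidin_present"` or `"absent"`.
#' @param substrate_class One of `"fork_3long"`, `"fork_5long"`,
#'   `"ssDNA_3tail"`, `"ssDNA_5tail"`.
#' @param atp `"present"` or `"absent"`.
#' @return A `condition_descriptor` object.
#' @export
condition_descriptor <- function(label_site = c("N_terminus", "C682"),
                                 block = c("streptavidin_present", "absent"),
                                 substrate_class = c("fork_3long", "fork_5long",
                                                     "ssDNA_3tail", "ssDNA_5tail"),
                                 atp = c("present", "absent")) {
  structure(
    list(label_site = match.arg(label_site), block = match.arg(block),
         substrate_class = match.arg(substrate_class), atp = match.arg(atp)),
    class = "condition_descriptor"
  )
}

#' @export
print.condition_descriptor <- function(x, ...) {
  cat("<condition> label:", x$label_site, "| block:", x$block,
      "| substrate:", x$substrate_class, "| ATP:", x$atp, "\n")
  invisible(x)
}

#' @export
format.condition_descriptor <- function(x, ...) {
  paste(x$label_site, x$block, x$substrate_class, x$atp, sep = "|")
}

# Direction of the slow phase implied by condition, truth and geometry.
slow_phase_truth <- function(condition, truth_direction) {
  stopifnot(inherits(condition, "condition_descriptor"))
  if (condition$atp == "absent") return("none")
  if (condition$block == "streptavidin_present") {
    leads <- (condition$label_site == "N_terminus" && truth_direction == "N_first") ||
      (condition$label_site == "C682" && truth_direction == "C_first")
    if (leads) "increase" else "decrease"
  } else {
    # no roadblock: the helicase runs past the reporter and the complex
    # resolves -- net slow loss of sensitized emission for either label
    "decrease"
  }
}

#' Default split time base for stopped-flow traces
#'
#' Dense early segment (0-10 s) to resolve the binding/loading phase
#' (~0.2-0.6 per s) and a sparse late segment for the slow translocation
#' phase (~1e-3 per s).
#' @param t_end End of the sparse segment, s.
#' @param n_dense,n_sparse Points per segment.
#' @return List of `(t_end, n_points)` pairs.
#' @export
default_timebase <- function(t_end = 300, n_dense = 250, n_sparse = 250) {
  list(c(10, n_dense), c(t_end, n_sparse))
}

#' Simulate a stopped-flow fluorescence trace
#'
#' Two-phase exponential signal `v(t) = a1 exp(-k1 t) + a2 exp(-k2 t) + C`
#' on a split time base. The fast phase is always a signal increase
#' (complex formation); the slow phase's direction is derived from the
#' condition and the true translocation polarity: with a streptavidin block
#' the slow phase rises only when the labelled face leads (N-label under
#' N-first, C-label under C-first) and falls otherwise (dissociation);
#' without the block both labels decay slowly (movement past the reporter);
#' without ATP the slow phase is absent. The amplitude sign convention is
#' increase `<=>` a < 0.
#'
#' @param condition A [condition_descriptor()].
#' @param truth_direction True polarity, `"N_first"` or `"C_first"`.
#' @param fast Length-2 vector `(amplitude, rate s^-1)` of the fast phase.
#' @param slow_rate Slow-phase rate, s^-1.
#' @param slow_amplitude Magnitude of the slow phase (sign set by the
#'   decision table).
#' @param timebase List of `(t_end, n_points)` segments, contiguous and
#'   increasing; see [default_timebase()].
#' @param noise_sd Gaussian noise as a fraction of the full-scale amplitude.
#' @param seed Integer seed.
#' @return A tibble (`time_s`, `signal`, `segment`) with `condition` and
#'   [truth_record()] attributes.
#' @export
simulate_fret_trace <- function(condition,
                                truth_direction = c("N_first", "C_first"),
                                fast,
                                slow_rate,
                                slow_amplitude = 0.4,
                                timebase = default_timebase(),
                                noise_sd = 0.01,
                                seed) {
  truth_direction <- match.arg(truth_direction)
  stopifnot(inherits(condition, "condition_descriptor"),
            length(fast) == 2, fast[2] > 0, slow_rate > 0,
            slow_amplitude >= 0, noise_sd >= 0)
  ends <- vapply(timebase, `[`, numeric(1), 1)
  if (any(diff(c(0, ends)) <= 0)) {
    stop("timebase segments must be contiguous and strictly increasing",
         call. = FALSE)
  }

  slow_dir <- slow_phase_truth(condition, truth_direction)
  a1 <- -abs(fast[1])                     # increase by convention
  k1 <- fast[2]
  a2 <- switch(slow_dir,
               increase = -abs(slow_amplitude),
               decrease = abs(slow_amplitude),
               none = 0)
  k2 <- slow_rate
  C <- 1 + abs(a1) + abs(a2)              # keep the trace positive

  grid <- purrr::map2_dfr(timebase, seq_along(timebase), function(seg, i) {
    t0 <- if (i == 1) 0 else ends[i - 1]
    n <- seg[2]
    tt <- if (i == 1) seq(0, seg[1], length.out = n) else {
      dt <- (seg[1] - t0) / n
      seq(t0 + dt, seg[1], length.out = n)
    }
    tibble::tibble(time_s = tt, segment = i)
  })
  scale <- max(abs(a1) + abs(a2), 1e-12)
  trace <- with_seed(seed, {
    v <- a1 * exp(-k1 * grid$time_s) + a2 * exp(-k2 * grid$time_s) + C
    tibble::tibble(
      time_s = grid$time_s,
      signal = v + stats::rnorm(nrow(grid), 0, noise_sd * scale),
      segment = grid$segment
    )
  })
  attr(trace, "condition") <- condition
  set_truth(trace, truth_record(
    productive_rule = truth_direction,
    kinetics = list(a1 = a1, k1 = k1, a2 = a2, k2 = k2, C = C,
                    slow_direction = slow_dir),
    seed = seed, noise_sd = noise_sd
  ))
}
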