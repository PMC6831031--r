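# Small in-code fixtures shared across test files.

# A lane profile tibble with given intensities (1-based bases).
mk_lane <- function(intensity, replicate = "rep1", is_control = FALSE) {
  tibble::tibble(
    replicate = replicate,
    base_index = seq_along(intensity),
    intensity = intensity,
    is_control = is_control
  )
}

# Mark a lane as already background-subtracted (for direct Eq.-1 arithmetic).
as_corrected <- function(lane) {
  attr(lane, "background_subtracted") <- TRUE
  lane
}

# Region map over a 50-nt strand with the standard intervals.
std_regions <- function() region_map(c(20, 35), c(36, 50), "from_5prime", 50)

# Noise-free band time course with given true amplitude and rate.
mk_timecourse <- function(p, k, times = default_unwinding_times(), seed = 1,
                          noise_sd = 0) {
  simulate_unwinding_timecourse(p, "N_first", k = k, times = times,
                                noise_sd = noise_sd, seed = seed)
}

# Minimal hand-built multiexp_fit whose slow phase has a chosen amplitude/SE,
# for exercising sign-pattern logic without running the optimizer.
mk_multiexp <- function(slow_amplitude, slow_se, label_site = "N_terminus",
                        block = "streptavidin_present", degenerate = FALSE) {
  phases <- tibble::tibble(
    phase = 1:2,
    amplitude = c(-0.3, slow_amplitude),
    rate_s = c(0.3, 1.5e-3),
    se_amplitude = c(0.01, slow_se),
    se_rate = c(0.01, 1e-4)
  )
  structure(
    list(n_exp = 2L, phases = phases, C = 1, se_C = 0.01, rss = 0.1,
         n_points = 500L, aicc = -100, degenerate = degenerate,
         condition = condition_descriptor(label_site, block, "fork_3long",
                                          "present"),
         fitted = NULL),
    class = "multiexp_fit"
  )
}
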