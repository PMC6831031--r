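sub <- substrate_preset("fork_equal")
rmap <- default_region_map(sub)

test_that("all four simulators are bit-reproducible under a seed", {
  pop <- population_preset("fork_equal_wt")
  a <- simulate_cleavage_profiles(sub, rmap, pop, n_replicates = 3,
                                  noise_cv = 0.1, seed = 42)
  b <- simulate_cleavage_profiles(sub, rmap, pop, n_replicates = 3,
                                  noise_cv = 0.1, seed = 42)
  expect_identical(a, b)

  ta <- simulate_unwinding_timecourse(0.5, "N_first", k = 0.07, seed = 7)
  tb <- simulate_unwinding_timecourse(0.5, "N_first", k = 0.07, seed = 7)
  expect_identical(ta, tb)

  sa <- simulate_anisotropy_series(0.2, 150, 2, c(10, 50, 150, 500), 0.003, 9)
  sb <- simulate_anisotropy_series(0.2, 150, 2, c(10, 50, 150, 500), 0.003, 9)
  expect_identical(sa, sb)

  cond <- condition_descriptor("N_terminus", "streptavidin_present",
                               "fork_3long", "present")
  fa <- simulate_fret_trace(cond, "N_first", fast = c(0.3, 0.26),
                            slow_rate = 1.5e-3, seed = 3)
  fb <- simulate_fret_trace(cond, "N_first", fast = c(0.3, 0.26),
                            slow_rate = 1.5e-3, seed = 3)
  expect_identical(fa, fb)
})

test_that("a pure N@duplex population deposits its mass in the N region", {
  pop <- binding_population(arm3_N = 1)
  lanes <- simulate_cleavage_profiles(sub, rmap, pop, n_replicates = 1,
                                      noise_cv = 0, seed = 1)
  lane <- dplyr::filter(lanes, !is_control)
  ctrl <- dplyr::filter(lanes, is_control)
  corr <- background_subtract(lane, ctrl)
  n_mass <- sum(corr$intensity[corr$base_index >= 20 & corr$base_index <= 35])
  expect_gt(n_mass / sum(corr$intensity), 0.9)
  # nothing outside the single-strand window
  expect_equal(sum(corr$intensity[corr$base_index < 20]), 0)
})

test_that("an all-unbound population is indistinguishable from control", {
  pop <- binding_population(unbound = 1)
  lanes <- simulate_cleavage_profiles(sub, rmap, pop, n_replicates = 1,
                                      noise_cv = 0, seed = 1)
  lane <- dplyr::filter(lanes, !is_control)
  ctrl <- dplyr::filter(lanes, is_control)
  expect_equal(sum(background_subtract(lane, ctrl)$intensity), 0)
})

test_that("cleavage mass in the N region is affine in P(N@duplex)", {
  mass_at <- function(p) {
    pop <- binding_population(arm3_N = p, arm3_C = 1 - p)
    lanes <- simulate_cleavage_profiles(sub, rmap, pop, n_replicates = 1,
                                        noise_cv = 0, seed = 1)
    lane <- dplyr::filter(lanes, !is_control)
    ctrl <- dplyr::filter(lanes, is_control)
    corr <- background_subtract(lane, ctrl)
    sum(corr$intensity[corr$base_index >= 20 & corr$base_index <= 35])
  }
  m <- vapply(c(0, 0.5, 1), mass_at, numeric(1))
  expect_equal(m[2], (m[1] + m[3]) / 2, tolerance = 1e-10)
  expect_gt(m[3], m[1])
})

test_that("a kernel falling entirely outside the window is rejected", {
  pr <- probe_model(probe_offset = 500, cleavage_sd = 0.5)
  expect_error(
    simulate_cleavage_profiles(sub, rmap, binding_population(arm3_N = 1),
                               probe = pr, n_replicates = 1, noise_cv = 0,
                               seed = 1),
    "outside the single-strand window"
  )
})

test_that("unwinding time courses conserve band mass and honour closed forms", {
  tc <- mk_timecourse(p = 1, k = 0.1, times = c(0, 5, 10, 20, 40))
  expect_equal(diff(range(tc$Is + tc$Id)), 0, tolerance = 1e-9)

  f <- fraction_unwound(tc)
  expect_equal(f$F[f$time_min == 10], 1 - exp(-1), tolerance = 1e-9)

  # zero productive fraction: series identically zero
  f0 <- fraction_unwound(mk_timecourse(p = 0, k = 0.1))
  expect_true(all(abs(f0$F) < 1e-12))

  expect_error(
    simulate_unwinding_timecourse(0.5, "N_first", k = 0.1,
                                  times = c(0, 5, 5, 10), seed = 1),
    "strictly increasing"
  )
  expect_error(
    simulate_unwinding_timecourse(0.5, "N_first", k = 0.1,
                                  times = c(1, 5, 10), seed = 1),
    "include 0"
  )
})

test_that("the productive rule selects the leading-face configuration", {
  pop <- binding_population(arm3_N = 0.2, arm3_C = 0.5, arm5_N = 0.1,
                            arm5_C = 0.2)
  expect_equal(productive_probability(pop, "N_first"), 0.2)
  expect_equal(productive_probability(pop, "C_first"), 0.5)
  # mirroring swaps them
  expect_equal(productive_probability(mirror_population(pop), "N_first"), 0.5)
})

test_that("anisotropy simulation obeys the half-saturation identity", {
  for (n in c(0.5, 1, 2, 4)) {
    y <- simulate_anisotropy_series(0.2, 150, n, c(0, 150), 0, seed = 1)
    expect_equal(y$anisotropy[y$conc_nM == 0], 0)
    expect_equal(y$anisotropy[y$conc_nM == 150], 0.1, tolerance = 1e-12)
  }
  expect_error(simulate_anisotropy_series(0.2, 150, 2, numeric(0), 0, 1),
               "non-empty")
})

test_that("the slow-phase decision table follows label, block, ATP and truth", {
  cases <- list(
    list("N_terminus", "streptavidin_present", "N_first", "increase"),
    list("C682", "streptavidin_present", "N_first", "decrease"),
    list("C682", "streptavidin_present", "C_first", "increase"),
    list("N_terminus", "streptavidin_present", "C_first", "decrease"),
    list("N_terminus", "absent", "N_first", "decrease"),
    list("C682", "absent", "N_first", "decrease")
  )
  for (cs in cases) {
    cond <- condition_descriptor(cs[[1]], cs[[2]], "fork_3long", "present")
    tr <- simulate_fret_trace(cond, cs[[3]], fast = c(0.3, 0.3),
                              slow_rate = 1.5e-3, noise_sd = 0, seed = 1)
    expect_equal(get_truth(tr)$kinetics$slow_direction, cs[[4]],
                 info = paste(unlist(cs), collapse = "/"))
  }
  # ATP absent: single-phase trace, fitted second amplitude negligible
  noatp <- condition_descriptor("N_terminus", "streptavidin_present",
                                "fork_3long", "absent")
  tr <- simulate_fret_trace(noatp, "N_first", fast = c(0.3, 0.3),
                            slow_rate = 1.5e-3, noise_sd = 0.01, seed = 5)
  expect_equal(get_truth(tr)$kinetics$a2, 0)
  fit <- fit_multi_exponential(tr, 2)
  slow <- fit$phases[which.min(fit$phases$rate_s), ]
  expect_lt(abs(slow$amplitude), 0.05 * 0.3)
})

test_that("unknown condition values are rejected", {
  expect_error(condition_descriptor("mid_domain"), "arg")
  expect_error(condition_descriptor("N_terminus", "maybe"), "arg")
})

test_that("fret traces honour the split time base", {
  cond <- condition_descriptor("N_terminus", "streptavidin_present",
                               "fork_3long", "present")
  tr <- simulate_fret_trace(cond, "N_first", fast = c(0.3, 0.3),
                            slow_rate = 1.5e-3,
                            timebase = list(c(10, 100), c(300, 50)),
                            noise_sd = 0, seed = 1)
  expect_equal(sum(tr$segment == 1), 100)
  expect_equal(sum(tr$segment == 2), 50)
  expect_true(all(diff(tr$time_s) > 0))
  expect_error(
    simulate_fret_trace(cond, "N_first", fast = c(0.3, 0.3),
                        slow_rate = 1.5e-3,
                        timebase = list(c(10, 100), c(5, 50)),
                        noise_sd = 0, seed = 1),
    "contiguous"
  )
})
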