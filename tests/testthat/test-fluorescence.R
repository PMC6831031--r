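sf_cond <- condition_descriptor("N_terminus", "streptavidin_present",
                                "fork_3long", "present")

sim_trace <- function(seed, noise_sd = 0.01, slow_rate = 1.5e-3,
                      fast = c(0.5, 0.5), t_end = 3000,
                      cond = sf_cond, truth = "N_first") {
  simulate_fret_trace(cond, truth, fast = fast, slow_rate = slow_rate,
                      timebase = default_timebase(t_end), noise_sd = noise_sd,
                      seed = seed)
}

test_that("trace averaging is pointwise and keeps variance metadata", {
  tr <- sim_trace(1, noise_sd = 0)
  avg <- average_traces(list(tr, tr))
  expect_equal(avg$signal, tr$signal)
  expect_equal(avg$var, rep(0, nrow(tr)))

  # symmetric deviations about a mean cancel exactly
  up <- dplyr::mutate(tr, signal = signal + 0.1)
  dn <- dplyr::mutate(tr, signal = signal - 0.1)
  attr(up, "condition") <- attr(tr, "condition")
  attr(dn, "condition") <- attr(tr, "condition")
  avg2 <- average_traces(list(up, dn))
  expect_equal(avg2$signal, tr$signal, tolerance = 1e-12)
})

test_that("averaging seven replicates shrinks noise about sqrt(7)-fold", {
  truth <- sim_trace(99, noise_sd = 0)
  reps <- lapply(1:7, function(s) sim_trace(100 + s, noise_sd = 0.02))
  avg <- average_traces(reps)
  sd_single <- sd(reps[[1]]$signal - truth$signal)
  sd_avg <- sd(avg$signal - truth$signal)
  expect_equal(sd_single / sd_avg, sqrt(7), tolerance = 0.2)
})

test_that("averaging rejects mismatched grids and conditions", {
  a <- sim_trace(1)
  b <- sim_trace(2, t_end = 2000)
  expect_error(average_traces(list(a, b)), "time grid")
  c2 <- sim_trace(3, cond = condition_descriptor("C682",
                                                 "streptavidin_present",
                                                 "fork_3long", "present"),
                  truth = "C_first")
  expect_error(average_traces(list(a, c2)), "different condition")
  expect_error(average_traces(list(a)), "at least 2")
})

test_that("noiseless two-phase traces are recovered exactly", {
  tr <- sim_trace(1, noise_sd = 0, fast = c(0.5, 0.5), slow_rate = 1.5e-3)
  truth <- get_truth(tr)$kinetics
  fit <- fit_multi_exponential(tr, 2)
  expect_false(fit$degenerate)
  expect_equal(fit$phases$rate_s, c(truth$k1, truth$k2), tolerance = 1e-6)
  expect_equal(fit$phases$amplitude, c(truth$a1, truth$a2), tolerance = 1e-6)
  expect_equal(fit$C, truth$C, tolerance = 1e-7)
  expect_equal(fit$phases$direction, c("increase", "increase"))
})

test_that("fitted slow-phase sign matches the simulated direction", {
  hits <- vapply(1:20, function(s) {
    cond <- if (s %% 2) sf_cond else
      condition_descriptor("C682", "streptavidin_present", "fork_3long",
                           "present")
    tr <- sim_trace(300 + s, noise_sd = 0.01, cond = cond)
    fit <- fit_multi_exponential(tr, 2)
    slow <- fit$phases[which.min(fit$phases$rate_s), ]
    got <- if (slow$amplitude < 0) "increase" else "decrease"
    got == get_truth(tr)$kinetics$slow_direction
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("well-separated rates are recovered within 20%", {
  hits <- vapply(1:20, function(s) {
    tr <- sim_trace(500 + s, noise_sd = 0.01, fast = c(0.5, 0.5),
                    slow_rate = 2e-3)
    fit <- fit_multi_exponential(tr, 2)
    all(abs(fit$phases$rate_s - c(0.5, 2e-3)) / c(0.5, 2e-3) < 0.2)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("model-order selection identifies one- and two-phase truths", {
  tb <- list(c(10, 60), c(300, 60))
  one_phase <- vapply(1:40, function(s) {
    cond <- condition_descriptor("N_terminus", "streptavidin_present",
                                 "fork_3long", "absent")
    tr <- simulate_fret_trace(cond, "N_first", fast = c(0.5, 0.3),
                              slow_rate = 1e-3, timebase = tb,
                              noise_sd = 0.01, seed = 700 + s)
    select_exponential_order(tr)$n_exp
  }, numeric(1))
  expect_gte(mean(one_phase == 1), 0.95)

  two_phase <- vapply(1:10, function(s) {
    tr <- simulate_fret_trace(sf_cond, "N_first", fast = c(0.5, 0.5),
                              slow_rate = 2e-3,
                              timebase = list(c(10, 60), c(2000, 60)),
                              noise_sd = 0.01, seed = 800 + s)
    select_exponential_order(tr)$n_exp
  }, numeric(1))
  expect_gte(mean(two_phase == 2), 0.9)
})

test_that("joint split-time-base fitting matches uniform single-segment fitting", {
  tr <- sim_trace(42, noise_sd = 0.005)
  # uniform grid: weights must all be 1
  uni <- tibble::tibble(time_s = seq(0.1, 300, by = 0.1))
  uni$segment <- 1L
  expect_equal(mcmorient:::timebase_weights(uni), rep(1, nrow(uni)))

  # the same uniform trace split into two equal-density segments fits alike
  truth <- get_truth(sim_trace(43, noise_sd = 0))
  base_tr <- simulate_fret_trace(sf_cond, "N_first", fast = c(0.5, 0.5),
                                 slow_rate = 1.5e-3,
                                 timebase = list(c(150, 300), c(300, 300)),
                                 noise_sd = 0.01, seed = 44)
  split_tr <- base_tr
  joined_tr <- dplyr::mutate(base_tr, segment = 1L)
  attr(joined_tr, "condition") <- attr(base_tr, "condition")
  f1 <- fit_multi_exponential(split_tr, 2)
  f2 <- fit_multi_exponential(joined_tr, 2)
  expect_equal(f1$phases$rate_s, f2$phases$rate_s, tolerance = 1e-4)
  expect_equal(f1$phases$amplitude, f2$phases$amplitude, tolerance = 1e-3)
})

test_that("quench normalization subtracts background and anchors at zero", {
  conc <- c(0, 50, 100, 200, 400)
  lab <- tibble::tibble(conc_nM = conc, signal = c(100, 95, 90, 85, 82))
  unlab <- tibble::tibble(conc_nM = conc, signal = c(100, 95, 90, 85, 82))
  q0 <- normalize_quench(lab, unlab)
  expect_equal(q0$quench, rep(0, 5), tolerance = 1e-12)

  # pure quench q with no background drift recovers q
  q <- c(0, 0.1, 0.2, 0.3, 0.35)
  lab2 <- tibble::tibble(conc_nM = conc, signal = 100 * (1 - q))
  flat <- tibble::tibble(conc_nM = conc, signal = rep(80, 5))
  q2 <- normalize_quench(lab2, flat)
  expect_equal(q2$quench, q, tolerance = 1e-12)
  expect_equal(q2$quench[1], 0)

  # deeper quench for one label stays below the other at every concentration
  deep <- tibble::tibble(conc_nM = conc, signal = 100 * (1 - 1.5 * q))
  qN <- normalize_quench(lab2, flat)
  qC <- normalize_quench(deep, flat)
  expect_true(all(qC$quench[-1] > qN$quench[-1]))

  expect_error(normalize_quench(lab, unlab[1:3, ]), "concentration grid")
  bad <- tibble::tibble(conc_nM = conc, signal = c(0, 1, 2, 3, 4))
  expect_error(normalize_quench(bad, unlab), "positive")
})
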