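test_that("background subtraction clamps element-wise at zero", {
  lane <- mk_lane(c(5, 10, 3, 8))
  ctrl <- mk_lane(c(5, 10, 3, 8), "control", TRUE)
  expect_equal(background_subtract(lane, ctrl)$intensity, rep(0, 4))

  bumped <- mk_lane(c(5, 10, 3 + 2.5, 8))
  expect_equal(background_subtract(bumped, ctrl)$intensity, c(0, 0, 2.5, 0))

  # independent oracle: element-wise max(lane - control, 0)
  set.seed(11)
  l <- mk_lane(runif(30, 0, 10))
  c0 <- mk_lane(runif(30, 0, 10), "control", TRUE)
  expect_equal(background_subtract(l, c0)$intensity,
               pmax(l$intensity - c0$intensity, 0))

  expect_error(background_subtract(mk_lane(1:3), mk_lane(1:4, "c", TRUE)),
               "same bases")
})

test_that("orientation fractions are region-sum ratios", {
  # 30 units spread in the N region, 90 in the C region
  v <- numeric(50)
  v[c(22, 30)] <- 15
  v[c(40, 45, 50)] <- 30
  res <- orientation_fraction(as_corrected(mk_lane(v)), std_regions())
  expect_equal(res$S_N, 30)
  expect_equal(res$S_C, 90)
  expect_equal(res$F_N, 0.25)
  expect_equal(res$F_C, 0.75)

  v2 <- numeric(50); v2[c(25, 40)] <- 7
  res2 <- orientation_fraction(as_corrected(mk_lane(v2)), std_regions())
  expect_equal(res2$F_N, 0.5)

  expect_error(
    orientation_fraction(as_corrected(mk_lane(numeric(50))), std_regions()),
    "degenerate lane"
  )
  expect_error(orientation_fraction(mk_lane(v), std_regions()),
               "background-subtracted")
})

test_that("fractions always sum to one and ignore uniform background", {
  set.seed(21)
  for (i in 1:20) {
    v <- numeric(50)
    v[20:50] <- rexp(31)
    res <- orientation_fraction(as_corrected(mk_lane(v)), std_regions())
    expect_equal(res$F_N + res$F_C, 1, tolerance = 1e-9)
    expect_true(res$F_N >= 0 && res$F_N <= 1)
  }

  # adding a constant to both lane and control leaves F_N unchanged
  lane <- mk_lane(c(numeric(19), rexp(31)) + 5)
  ctrl <- mk_lane(rep(5, 50), "control", TRUE)
  base <- orientation_fraction(background_subtract(lane, ctrl), std_regions())
  lane2 <- dplyr::mutate(lane, intensity = intensity + 100)
  ctrl2 <- dplyr::mutate(ctrl, intensity = intensity + 100)
  shifted <- orientation_fraction(background_subtract(lane2, ctrl2),
                                  std_regions())
  expect_equal(shifted$F_N, base$F_N, tolerance = 1e-12)
})

test_that("the orientation t-test matches pooled-variance arithmetic", {
  same <- compare_orientations(c(0.4, 0.5, 0.6), c(0.4, 0.5, 0.6))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$stars, "n.s.")

  g1 <- c(0.2, 0.25, 0.22); g2 <- c(0.8, 0.75, 0.78)
  res <- compare_orientations(g1, g2)
  # closed-form pooled t with 4 df, computed independently
  sp2 <- (2 * var(g1) + 2 * var(g2)) / 4
  t_oracle <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$t_statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_oracle), 4), tolerance = 1e-12)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$stars, "***")

  expect_error(compare_orientations(0.5, c(0.4, 0.6)), "at least 2")
})

test_that("the t-test holds its nominal type-I error rate", {
  set.seed(101)
  rejections <- vapply(1:1000, function(i) {
    compare_orientations(rnorm(4, 0.5, 0.05), rnorm(4, 0.5, 0.05))$p_value < 0.05
  }, logical(1))
  rate <- mean(rejections)
  # binomial 3-sigma band around 0.05 for 1000 draws
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / 1000))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("mean F_N converges to the generative orientation fraction", {
  sub <- substrate_preset("fork_equal")
  rmap <- default_region_map(sub)
  for (p in c(0.2, 0.5, 0.8)) {
    lanes <- simulate_cleavage_profiles(
      sub, rmap, orientation_population(p),
      n_replicates = 3, noise_cv = 0.002, seed = 400 + round(100 * p)
    )
    fp <- footprint_analysis(lanes, rmap)
    # residual bias is bounded by the kernel's cross-region leakage
    expect_equal(fp$mean_F_N, p, tolerance = 0.02)
  }
})

test_that("orientation classification needs both size and significance", {
  sub <- substrate_preset("fork_equal")
  rmap <- default_region_map(sub)

  lanes_c <- simulate_cleavage_profiles(sub, rmap, orientation_population(0.23),
                                        n_replicates = 5, noise_cv = 0.1,
                                        seed = 31)
  fp_c <- footprint_analysis(lanes_c, rmap)
  expect_lt(fp_c$p_value, 0.01)
  expect_equal(classify_binding_orientation(fp_c), "C_at_duplex_preferred")

  lanes_n <- simulate_cleavage_profiles(sub, rmap, orientation_population(0.57),
                                        n_replicates = 5, noise_cv = 0.1,
                                        seed = 32)
  fp_n <- footprint_analysis(lanes_n, rmap)
  expect_equal(classify_binding_orientation(fp_n), "N_at_duplex_preferred")

  lanes_ns <- simulate_cleavage_profiles(sub, rmap, orientation_population(0.5),
                                         n_replicates = 3, noise_cv = 0.15,
                                         seed = 33)
  fp_ns <- footprint_analysis(lanes_ns, rmap)
  if (fp_ns$p_value >= 0.05) {
    expect_equal(classify_binding_orientation(fp_ns), "no_preference")
  }

  td <- tidy(fp_c)
  expect_equal(td$estimate[td$orientation == "N_at_duplex"], fp_c$mean_F_N)
  expect_equal(glance(fp_c)$classification, "C_at_duplex_preferred")
})
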