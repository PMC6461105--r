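make_fit <- function(modes = c(1, 10), shapes = c(0.05, 0.05),
                     areas = c(0.5, 0.5)) {
  structure(list(modes = c(low = modes[1], high = modes[2]),
                 shapes = c(low = shapes[1], high = shapes[2]),
                 areas = c(low = areas[1], high = areas[2]),
                 se_areas = c(low = 0.01, high = 0.01),
                 se_modes = c(low = 0, high = 0),
                 converged = TRUE, degenerate = FALSE),
            class = "lognorm2_fit")
}

test_that("threshold sits at the density crossing between the modes", {
  # equal shapes and areas: crossing at the geometric mean of the medians,
  # which tends to sqrt(m1 m2) as the shape narrows
  thr <- threshold_from_fit(make_fit(shapes = c(0.05, 0.05)))
  expect_equal(as.numeric(thr), sqrt(10) * exp(0.05^2), tolerance = 1e-6)
  expect_equal(as.numeric(thr), sqrt(10), tolerance = 0.005)
  expect_identical(attr(thr, "rule"), "density-crossing")
})

test_that("threshold falls back to the geometric mean without a crossing", {
  # a dominant broad low peak blankets a vanishing narrow high peak, so
  # the weighted densities never cross between the modes
  f <- make_fit(shapes = c(0.5, 1e-3), areas = c(1, 1e-9))
  expect_warning(thr <- threshold_from_fit(f), "geometric mean")
  expect_equal(as.numeric(thr), sqrt(10), tolerance = 1e-9)
  expect_error(threshold_from_fit(make_fit(modes = c(10, 1))), "degenerate")
})

test_that("framewise misclassification is rare for resolved peaks", {
  ens <- simulate_ensemble(sim_config(two_state_rates(2.1, 2.4),
                                      n_molecules = 100, seed = 14))
  f <- fit_two_lognormals(ens)
  thr <- threshold_from_fit(f)
  lab <- assign_states(ens, thr)
  # judge only frames that are purely one state (no within-frame mixing)
  pure_low <- ens$true_inactive > 1 - 1e-9
  pure_high <- ens$true_inactive < 1e-9
  mis <- (sum(lab[pure_low] != "low") + sum(lab[pure_high] != "high")) /
    (sum(pure_low) + sum(pure_high))
  expect_lt(mis, 0.02)
})

test_that("state assignment thresholds deterministically", {
  lab <- assign_states(c(1, 1, 9, 9), 3.16, frame_interval = 0.08)
  expect_identical(as.vector(lab), c("low", "low", "high", "high"))
  expect_warning(assign_states(c(5, 6, 7), 100, frame_interval = 0.08),
                 "outside")
})

test_that("dwell extraction censors boundary-touching runs", {
  lab <- matrix(c("high", "low", "low", "high"), ncol = 1)
  d <- extract_dwells(lab, "low", frame_interval = 0.08)
  expect_equal(nrow(d), 1L)
  expect_equal(d$duration, 0.16)
  expect_false(d$censored)
  # a run spanning the whole trace is fully censored
  d2 <- extract_dwells(matrix(rep("low", 4), ncol = 1), "low",
                       frame_interval = 0.08)
  expect_true(all(d2$censored))
  expect_equal(sum(!d2$censored), 0L)
  # durations are positive integer multiples of the frame interval
  ens <- small_ensemble(n_molecules = 10)
  lab3 <- assign_states(ens, threshold_from_fit(fit_two_lognormals(ens)))
  d3 <- extract_dwells(lab3, "low")
  expect_true(all(d3$duration > 0))
  expect_true(all(abs(d3$duration / 0.08 - round(d3$duration / 0.08)) < 1e-9))
})

test_that("mean complete low dwell approaches the exponential mean", {
  ens <- simulate_ensemble(sim_config(two_state_rates(2.1, 2.4),
                                      n_molecules = 200, seed = 19))
  lab <- assign_states(ens, threshold_from_fit(fit_two_lognormals(ens)))
  d <- extract_dwells(lab, "low")
  m <- mean(d$duration[!d$censored])
  expect_equal(m, 1 / 2.1, tolerance = 0.15)
})

test_that("the exponential mle equals the reciprocal sample mean", {
  # quantile-constructed sample rescaled to mean exactly 1/2.1
  q <- qexp(ppoints(200))
  q <- q / mean(q) / 2.1
  d <- structure(data.frame(molecule = 1L, duration = q, censored = FALSE),
                 state = "low", frame_interval = 0.08,
                 class = c("dwell_set", "data.frame"))
  est <- fit_single_exponential(d, "mle")
  expect_equal(est$k, 2.1, tolerance = 1e-12)
  expect_equal(est$se, 2.1 / sqrt(200), tolerance = 1e-12)
  # constant durations: mle is 1/tau
  d2 <- structure(data.frame(molecule = 1L, duration = rep(0.5, 50),
                             censored = FALSE),
                  state = "low", frame_interval = 0.08,
                  class = c("dwell_set", "data.frame"))
  expect_equal(fit_single_exponential(d2, "mle")$k, 2)
})

test_that("too few dwells are rejected with the count in the message", {
  d <- structure(data.frame(molecule = 1L, duration = rep(0.2, 5),
                            censored = FALSE),
                 state = "low", frame_interval = 0.08,
                 class = c("dwell_set", "data.frame"))
  expect_error(fit_single_exponential(d), "5")
})

test_that("mle and binned least squares agree on simulated dwells", {
  set.seed(23)
  dur <- rexp(1000, 2.1)
  d <- structure(data.frame(molecule = 1L, duration = dur,
                            censored = FALSE),
                 state = "low", frame_interval = 0.08,
                 class = c("dwell_set", "data.frame"))
  m1 <- fit_single_exponential(d, "mle")
  m2 <- fit_single_exponential(d, "binned_lsq")
  expect_equal(m1$k, 2.1, tolerance = 0.10)
  expect_equal(m2$k, 2.1, tolerance = 0.10)
  expect_lt(abs(m1$k - m2$k), 2 * sqrt(m1$se^2 + m2$se^2))
})

test_that("detailed balance derives the return rate from the equilibrium", {
  k1 <- derived_k_inactive(2.1, 52 / 46)
  expect_equal(round(k1$k, 1), 2.4)
  k2 <- derived_k_inactive(2.3, 23 / 77)
  expect_equal(round(k2$k, 1), 0.7)
  expect_equal(derived_k_inactive(1.7, 1)$k, 1.7)
  # errors combine in quadrature of relative errors
  ka <- structure(list(k = 2, se = 0.2, n_dwells = 100L, method = "mle"),
                  class = "rate_estimate")
  eq <- equilibrium_constant(50, 50, 5, 5)
  kd <- derived_k_inactive(ka, eq)
  expect_equal(kd$se / kd$k,
               sqrt((0.2 / 2)^2 + (eq$se / eq$K_eq)^2), tolerance = 1e-12)
})

test_that("residence times are reciprocal exit rates at printed precision", {
  expect_equal(round(residence_times(two_state_rates(2.1, 2.37))["inactive"],
                     1), c(inactive = 0.5))
  expect_equal(round(residence_times(two_state_rates(2.1, 2.37))["active"],
                     1), c(active = 0.4))
  expect_equal(round(residence_times(two_state_rates(2.3, 0.687))["active"],
                     1), c(active = 1.5))
})

test_that("histogram equilibrium agrees with the simulated rate ratio", {
  ens <- simulate_ensemble(sim_config(two_state_rates(2.1, 2.4),
                                      n_molecules = 300, seed = 61))
  p <- populations_from_fit(fit_two_lognormals(ens), "inactive-low")
  K_hist <- p$pct_inactive / p$pct_active
  expect_equal(K_hist, 2.4 / 2.1, tolerance = 0.15)
})
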