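test_that("pooling counts every frame exactly once", {
  ens <- small_ensemble(n_molecules = 2)
  h <- pool_histogram(ens)
  expect_equal(sum(h$counts), 2 * 500)
  expect_true(all(diff(h$breaks) > 0))
  # identical intensities end up in a single occupied bin
  h1 <- pool_histogram(rep(5, 100))
  expect_equal(sum(h1$counts > 0), 1L)
  expect_equal(sum(h1$counts), 100)
  expect_error(pool_histogram(numeric(0)), "no finite")
})

test_that("pooled histograms are reproducible from a fixed seed", {
  h1 <- pool_histogram(small_ensemble(seed = 9))
  h2 <- pool_histogram(small_ensemble(seed = 9))
  expect_identical(h1$counts, h2$counts)
  expect_identical(h1$breaks, h2$breaks)
})

test_that("two-log-normal fit recovers known mixture fractions and modes", {
  v <- mixture_sample(1e5, frac_low = 0.4, seed = 2)
  f <- fit_two_lognormals(v)
  expect_true(f$converged)
  expect_equal(unname(f$areas["low"]), 0.4, tolerance = 0.02 / 0.4)
  expect_equal(unname(f$areas["high"]), 0.6, tolerance = 0.02 / 0.6)
  # modes recovered within 5% (peaks separated by far more than 3 shapes)
  expect_equal(unname(f$modes["low"]), 1, tolerance = 0.05)
  expect_equal(unname(f$modes["high"]), 10, tolerance = 0.05)
  # area fractions need not sum exactly to one, but nearly
  expect_gt(sum(f$areas), 0.90)
  expect_lt(sum(f$areas), 1.02)
})

test_that("lsq and mle objectives agree on clean mixture data", {
  v <- mixture_sample(2e4, frac_low = 0.35, seed = 8)
  f1 <- fit_two_lognormals(v, method = "lsq")
  f2 <- fit_two_lognormals(v, method = "mle")
  expect_equal(unname(f1$areas["low"]), unname(f2$areas["low"]),
               tolerance = 0.02 / 0.35)
  expect_equal(unname(f1$modes), unname(f2$modes), tolerance = 0.02)
})

test_that("single-peak data produce a flagged degenerate fit", {
  set.seed(4)
  v <- rlnorm(2e4, log(10) + 0.04, 0.2)
  expect_warning(f <- fit_two_lognormals(v), "degenerate")
  expect_lt(min(f$areas), 0.02)
  expect_true(f$degenerate)
})

test_that("simulated dynamics recover the stationary low-peak area", {
  ens <- simulate_ensemble(sim_config(two_state_rates(2.1, 2.4),
                                      n_molecules = 300, seed = 21))
  f <- fit_two_lognormals(ens)
  expect_equal(unname(f$areas["low"]), 2.4 / 4.5, tolerance = 0.03 / (2.4 / 4.5))
})

test_that("fitted populations are stable under bin-width perturbation", {
  ens <- simulate_ensemble(sim_config(two_state_rates(2.1, 2.4),
                                      n_molecules = 200, seed = 33))
  v <- as.vector(ens$intensity)
  base_bw <- diff(pool_histogram(v)$breaks[1:2])
  areas <- sapply(c(0.75, 1, 1.25), function(scale) {
    br <- seq(min(v), max(v) + base_bw * scale, by = base_bw * scale)
    f <- fit_two_lognormals(pool_histogram(v, breaks = br))
    unname(f$areas["low"])
  })
  expect_lt(max(areas) - min(areas), 0.01)
})

test_that("peak areas map onto populations according to construct polarity", {
  v <- mixture_sample(5e4, frac_low = 0.23, seed = 6)
  f <- fit_two_lognormals(v)
  p_k224 <- populations_from_fit(f, "inactive-low")
  p_m373 <- populations_from_fit(f, "inactive-high")
  expect_equal(p_k224$pct_inactive, 23, tolerance = 0.08)
  expect_equal(p_k224$pct_active, 77, tolerance = 0.03)
  # the inverted construct reads the same areas with swapped meaning
  expect_equal(p_m373$pct_inactive, p_k224$pct_active)
  expect_equal(p_m373$pct_active, p_k224$pct_inactive)
  expect_gt(p_k224$se_inactive, 0)
})

test_that("equal areas give 50/50 under either polarity", {
  f <- structure(list(modes = c(low = 1, high = 10),
                      shapes = c(low = 0.2, high = 0.2),
                      areas = c(low = 0.5, high = 0.5),
                      se_areas = c(low = 0.01, high = 0.01),
                      se_modes = c(low = 0, high = 0),
                      converged = TRUE, degenerate = FALSE),
                 class = "lognorm2_fit")
  for (pol in c("inactive-low", "inactive-high")) {
    p <- populations_from_fit(f, pol)
    expect_equal(p$pct_inactive, 50)
    expect_equal(p$pct_active, 50)
  }
  expect_error(populations_from_fit(f, "sideways"))
})

test_that("round trip simulate -> pool -> fit -> populations recovers truth", {
  for (rates in list(c(2.1, 2.4), c(2.3, 0.7))) {
    ens <- simulate_ensemble(sim_config(two_state_rates(rates[1], rates[2]),
                                        n_molecules = 300, seed = 55))
    p <- populations_from_fit(fit_two_lognormals(ens), "inactive-low")
    truth <- 100 * rates[2] / sum(rates)
    expect_equal(p$pct_inactive, truth, tolerance = 3 / truth)
  }
})

test_that("opposite polarities bracket the truth from the same kinetics", {
  # frames containing a transition sit between the peaks and are absorbed
  # asymmetrically; the effect is antisymmetric in polarity, so the two
  # constructs straddle the true population and their mean recovers it
  fits <- lapply(c("inactive-low", "inactive-high"), function(pol) {
    ens <- simulate_ensemble(sim_config(two_state_rates(2.1, 2.4),
                                        n_molecules = 200, polarity = pol,
                                        seed = 77))
    populations_from_fit(fit_two_lognormals(ens), pol)
  })
  truth <- 100 * 2.4 / 4.5
  got <- c(fits[[1]]$pct_inactive, fits[[2]]$pct_inactive)
  expect_lt(abs(mean(got) - truth), 1.5)
  expect_true(all(abs(got - truth) < 4))
})

test_that("fit methods expose the usual model-object surface", {
  v <- mixture_sample(2e4, frac_low = 0.4, seed = 13)
  f <- fit_two_lognormals(v)
  cf <- coef(f)
  expect_named(cf, c("mode_low", "mode_high", "shape_low", "shape_high",
                     "area_low", "area_high"))
  s <- summary(f)
  expect_s3_class(s, "summary.lognorm2_fit")
  expect_equal(nrow(s$table), 2L)
  expect_length(residuals(f), length(f$histogram$counts))
  expect_equal(fitted(f) + residuals(f), f$histogram$counts)
  d <- predict(f, c(1, 5, 10))
  expect_length(d, 3L)
  expect_true(all(d >= 0))
  pdf(NULL)
  expect_silent(plot(f))
  dev.off()
})
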