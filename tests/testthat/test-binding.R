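test_that("discrimination is the ratio of equilibrium constants", {
  d <- ligand_discrimination(23 / 77, 99)
  expect_equal(d$discrimination, (23 / 77) / 99)
  expect_equal(round(d$fold_preference), 331)
  expect_equal(d$discrimination * d$fold_preference, 1)
  expect_equal(ligand_discrimination(0.7, 0.7)$discrimination, 1)
  # CD532 on phosphorylated kinase: ~6-fold preference for inactive
  d2 <- ligand_discrimination(23 / 77, 64 / 36)
  expect_equal(d2$discrimination, 0.168, tolerance = 0.002)
  expect_equal(round(d2$fold_preference), 6)
})

test_that("required discrimination reproduces the published table rows", {
  cases <- list(
    list(keq = keq_phos, folds = c(331, 64, 30),
         disc = c(0.003, 0.016, 0.033)),
    list(keq = keq_unphos, folds = c(88, 17, 8),
         disc = c(0.011, 0.059, 0.125)),
    list(keq = keq_phos_tpx2, folds = c(608, 117, 55),
         disc = c(0.002, 0.009, 0.018)))
  targets <- c(0.99, 0.95, 0.90)
  for (cs in cases) {
    for (i in seq_along(targets)) {
      disp <- format_discrimination(
        required_discrimination(cs$keq, targets[i]))
      expect_equal(disp$fold_preference, cs$folds[i])
      expect_equal(disp$discrimination, cs$disc[i])
    }
  }
  # already at target: fold exactly 1
  K <- 0.5
  d <- required_discrimination(K, K / (1 + K))
  expect_equal(d$fold_preference, 1)
  expect_error(required_discrimination(1, 1), "strictly between")
  expect_error(required_discrimination(1, 0), "strictly between")
})

test_that("overall K_d interpolates the conformation-specific constants", {
  expect_equal(kd_overall(200, 50, 23 / 77), 118.3, tolerance = 5e-4)
  # indistinguishable conformers
  for (K in c(0.01, 1, 50)) expect_equal(kd_overall(70, 70, K), 70)
  # single-conformer limits
  expect_equal(kd_overall(200, 50, 1e-12), 200, tolerance = 1e-9)
  expect_equal(kd_overall(200, 50, 1e12), 50, tolerance = 1e-9)
  expect_error(kd_overall(-1, 50, 1), "positive")
  # always between the two conformation-specific constants
  set.seed(2)
  for (i in 1:25) {
    ka <- 10^runif(1, -9, -5); ki <- 10^runif(1, -9, -5)
    K <- 10^runif(1, -2, 2)
    kd <- kd_overall(ka, ki, K)
    expect_gte(kd, min(ka, ki)); expect_lte(kd, max(ka, ki))
  }
})

test_that("closed form matches the four-species mass-balance oracle", {
  set.seed(7)
  for (i in 1:100) {
    ka <- 10^runif(1, -9, -5); ki <- 10^runif(1, -9, -5)
    K <- 10^runif(1, -1.5, 1.5)
    expect_equal(kd_overall(ka, ki, K), kd_overall_numeric(ka, ki, K),
                 tolerance = 1e-6)
  }
})

test_that("saturating ligand shifts the equilibrium by the discrimination", {
  # bound-state conformational ratio from the species balance equals
  # K_eq,free / D with D = kd_inactive / kd_active
  set.seed(11)
  for (i in 1:20) {
    ka <- 10^runif(1, -8, -6); ki <- 10^runif(1, -8, -6)
    K <- 10^runif(1, -1, 1)
    L <- 1e-3                               # saturating
    A <- 1; I <- K                          # free conformers
    AL <- A * L / ka; IL <- I * L / ki
    K_bound <- IL / AL
    D <- ki / ka
    expect_equal(K_bound, K / D, tolerance = 1e-9)
  }
})

test_that("the overall-K_d surface is monotone and symmetric at K_eq 1", {
  s <- kd_surface(23 / 77, n = 50)
  expect_true(all(diff(s$K) >= 0))          # along kd_active
  expect_true(all(diff(t(s$K)) >= 0))       # along kd_inactive
  expect_true(all(s$K >= min(outer(s$kd_active, s$kd_inactive, pmin))))
  s1 <- kd_surface(1, n = 20)
  expect_equal(s1$K, t(s1$K))
  s2 <- kd_surface(1, n = 2)
  expect_identical(dim(s2$K), c(2L, 2L))
})

test_that("a plateau flattens the response to the active-site constant", {
  # five-fold improvement in kd_active changes the overall K_d < 2-fold
  r <- kd_overall(1000e-9, 50e-9, 23 / 77) /
    kd_overall(200e-9, 50e-9, 23 / 77)
  expect_lt(r, 2)
  expect_gt(r, 1)
})

test_that("contour gap distances match a bisection oracle", {
  set.seed(5)
  for (i in 1:100) {
    K <- 10^runif(1, -1, 1)
    ka <- 10^runif(1, -7, -5); ki <- 10^runif(1, -7, -5)
    k0 <- kd_overall(ka, ki, K)
    cc <- k0 * runif(1, 0.2, 0.9)
    g <- contour_gap_distances(ka, ki, cc, K)
    if (is.finite(g$delta_active)) {
      root <- uniroot(function(x) kd_overall(x, ki, K) - cc,
                      c(ka * 1e-8, ka), tol = ka * 1e-13)$root
      expect_equal(g$delta_active, ka - root, tolerance = 1e-6)
    }
    if (is.finite(g$delta_inactive)) {
      root <- uniroot(function(x) kd_overall(ka, x, K) - cc,
                      c(ki * 1e-8, ki), tol = ki * 1e-13)$root
      expect_equal(g$delta_inactive, ki - root, tolerance = 1e-6)
    }
  }
})

test_that("contour gap edge cases behave", {
  K <- 23 / 77
  k0 <- kd_overall(1e-6, 1e-6, K)
  g0 <- contour_gap_distances(1e-6, 1e-6, k0, K)
  expect_equal(g0$delta_active, 0)
  expect_equal(g0$delta_inactive, 0)
  # symmetric point at K_eq 1: equal distances
  g1 <- contour_gap_distances(1e-6, 1e-6, 1e-7, 1)
  expect_equal(g1$delta_active, g1$delta_inactive, tolerance = 1e-12)
  # any contour below an uphill point is reachable along either axis
  # (the surface falls to zero along each axis), so distances are finite
  set.seed(3)
  for (i in 1:20) {
    K <- 10^runif(1, -1, 1)
    ka <- 10^runif(1, -7, -5); ki <- 10^runif(1, -7, -5)
    cc <- kd_overall(ka, ki, K) * runif(1, 0.05, 0.95)
    g <- contour_gap_distances(ka, ki, cc, K)
    expect_true(is.finite(g$delta_active) && g$delta_active > 0)
    expect_true(is.finite(g$delta_inactive) && g$delta_inactive > 0)
  }
  expect_error(contour_gap_distances(1e-8, 1e-8, 1e-6, 1), "below")
})

test_that("the equidistant locus is the diagonal when K_eq is one", {
  e <- equidistant_line(1e-7, 1, domain = c(1e-9, 1e-5))
  expect_gt(nrow(e), 10)
  expect_lt(max(abs(log(e$kd_inactive / e$kd_active))), 1e-6)
  expect_true(all(abs(e$residual) < 1e-6 * 1e-7))
})

test_that("tighter contours pull the equidistant locus to the diagonal", {
  K <- 23 / 77
  levels <- exp(seq(log(1.5e-6), log(8e-6), length.out = 8))
  devs <- sapply(c(1e-6, 1e-7, 1e-8), function(cc) {
    e <- equidistant_line(cc, K, domain = c(1e-9, 1e-5), levels = levels)
    expect_true(all(abs(e$residual) < 1e-6 * cc))
    max(abs(log(e$kd_inactive / e$kd_active)))
  })
  expect_true(all(diff(devs) < 0))
  # empty locus warns
  expect_warning(equidistant_line(1, 1, domain = c(1e-9, 1e-5)),
                 "empty curve")
})

test_that("plateau mask flags regions of low logarithmic sensitivity", {
  s <- kd_surface(23 / 77, n = 30)
  m <- plateau_mask(s, 0.25)
  sa <- attr(m, "sens_active")
  si <- attr(m, "sens_inactive")
  expect_equal(sa + si, matrix(1, 30, 30))
  # kd_active << kd_inactive / K_eq: inactive sensitivity below 0.25
  idx <- outer(s$kd_active, s$kd_inactive,
               function(a, i) a < 0.1 * i / (23 / 77))
  expect_true(all(si[idx] < 0.25))
  # sensitivities sum to one, so the joint mask needs threshold > 0.5
  expect_false(any(plateau_mask(s, 0)))
  expect_true(any(plateau_mask(s, 0.6)))
  # vanishing K_eq: inactive sensitivity vanishes everywhere
  s0 <- kd_surface(1e-9, n = 10)
  expect_lt(max(attr(plateau_mask(s0, 0.5), "sens_inactive")), 1e-3)
})

test_that("the discrimination table carries both TPX2 conventions", {
  t2 <- reproduce_table2()
  expect_equal(sum(t2$condition == "Unphosphorylated + TPX2"), 6L)
  inv <- t2[t2$convention == "inverted-as-printed", ]
  expect_equal(inv$fold_display, c(81, 16, 7))
  meas <- t2[t2$condition == "Unphosphorylated + TPX2" &
               t2$convention == "measured", ]
  expect_equal(meas$fold_display, c(121, 23, 11))
})
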