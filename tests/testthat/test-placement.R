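test_that("Bessel roots match bracketing-oracle values and are true roots", {
  # frozen values from an independent uniroot bracketing oracle
  expect_equal(bessel_roots("J0", 2), c(2.404826, 5.520078), tolerance = 1e-6)
  expect_equal(bessel_roots("J1", 2), c(3.831706, 7.015587), tolerance = 1e-6)
  r <- bessel_roots("J0", 6)
  expect_true(all(diff(r) > 0))
  expect_true(all(abs(besselJ(r, 0)) < 1e-12))
  r1 <- bessel_roots("J1", 6)
  expect_true(all(abs(besselJ(r1, 1)) < 1e-12))
  expect_error(bessel_roots("J0", 0), "positive integer")
})

test_that("pre-exponentials encode the feed-elimination structure", {
  p_center <- diffusion_problem("axial", 1, 1, feed_position = 0.5)
  for (z in c(0, 0.3, 1))
    expect_equal(preexponential(p_center, 1, z), 0, tolerance = 1e-14)
  p_end <- diffusion_problem("axial", 1, 1, feed_position = 0)
  expect_equal(preexponential(p_end, 1, 0), 2)
  # radial feed at alpha1/beta1 kills the first radial term
  ab <- bessel_roots("J0", 1) / bessel_roots("J1", 1)
  p_rad <- diffusion_problem("radial", 1, 1, feed_position = ab)
  for (r in c(0, 0.4, 0.9))
    expect_lt(abs(preexponential(p_rad, 1, r)), 1e-12)
  expect_error(preexponential(p_end, 1, 2), "outside")
})

test_that("rate constants follow the eigenvalue formulas", {
  p <- diffusion_problem("axial", 1, 1)
  expect_equal(rate_constant(p, 1), pi^2)
  expect_equal(rate_constant(p, 2), 4 * pi^2)
  expect_true(all(diff(rate_constant(p, 1:10)) > 0))
  pr <- diffusion_problem("radial", 2, 3)
  expect_equal(rate_constant(pr, 1), bessel_roots("J1", 1)^2 * 3 / 4)
  pt <- diffusion_problem("tangential", 2 * pi, 1, eval_radius = 1)
  expect_equal(rate_constant(pt, 1), 1)
})

test_that("concentration series equilibrates, conserves the mean, and matches a finite-volume oracle", {
  p <- diffusion_problem("axial", 1, 1, feed_position = 0.3)
  t_large <- 21 / rate_constant(p, 1)
  z <- seq(0, 1, length.out = 11)
  expect_equal(concentration_series(p, z, t_large), rep(1, 11),
               tolerance = 1e-8)
  # spatial mean exactly 1 (cosine modes integrate to zero)
  zq <- seq(0.5 / 2000, 1 - 0.5 / 2000, length.out = 2000)
  for (tt in c(0.01, 0.05, 0.2))
    expect_equal(mean(concentration_series(p, zq, tt)), 1, tolerance = 1e-8)
  # radial mean with area weight 2 pi r dr
  pr <- diffusion_problem("radial", 1, 1, feed_position = 0.2, n_terms = 80)
  rq <- seq(0.5 / 4000, 1 - 0.5 / 4000, length.out = 4000)
  u <- concentration_series(pr, rq, 0.02)
  expect_equal(sum(u * rq) / sum(rq), 1, tolerance = 1e-6)
  # independent finite-volume oracle
  fv <- fv_axial_diffusion(z0 = 0, t_end = 0.05)
  u_fv <- fv$u[1]
  u_series <- concentration_series(
    diffusion_problem("axial", 1, 1, feed_position = 0, n_terms = 50),
    fv$z[1], 0.05)
  expect_lt(abs(u_series - u_fv) / u_fv, 0.005)
  expect_error(concentration_series(p, 0.5, -1), "non-negative")
})

test_that("closed-form sigma matches quadrature and is monotone", {
  p <- diffusion_problem("axial", 1, 1, feed_position = 0.3)
  zq <- seq(0.5 / 1e4, 1 - 0.5 / 1e4, length.out = 1e4)
  for (tt in c(0.02, 0.05, 0.1)) {
    u <- concentration_series(p, zq, tt)
    expect_equal(sigma_axial(p, tt), sqrt(mean((1 - u)^2)), tolerance = 1e-8)
  }
  ts <- seq(0.001, 0.5, length.out = 50)
  expect_true(all(diff(sigma_axial(p, ts)) < 0))
  # centre feed: only even modes contribute
  pc <- diffusion_problem("axial", 1, 1, feed_position = 0.5)
  m <- seq(2, 100, by = 2)
  expect_equal(sigma_axial(pc, 0.01),
               sqrt(sum(2 * cos(m * pi * 0.5)^2 * exp(-2 * m^2 * pi^2 * 0.01))),
               tolerance = 1e-12)
  # finite truncation sum at t = 0
  m_all <- 1:50
  expect_equal(sigma_axial(p, 0),
               sqrt(sum(2 * cos(m_all * pi * 0.3)^2)), tolerance = 1e-12)
  expect_error(sigma_axial(diffusion_problem("radial", 1, 1), 1), "axial")
})

test_that("1D mixing times: top feed, centre feed, and the four-fold ratio", {
  p_top <- diffusion_problem("axial", 1, 1, feed_position = 1)
  p_mid <- diffusion_problem("axial", 1, 1, feed_position = 0.5)
  t_top <- mixing_time_1d(p_top)
  t_mid <- mixing_time_1d(p_mid)
  expect_equal(t_top, 0.3386464, tolerance = 1e-5)   # bisection oracle
  expect_equal(t_mid, 0.0846616, tolerance = 1e-5)
  expect_equal(t_top / t_mid, 4.00, tolerance = 0.01 / 4)
  expect_equal(sigma_axial(p_top, t_top), 0.05, tolerance = 1e-7)
  expect_error(mixing_time_1d(p_top, threshold = 1.2), "threshold")
})

test_that("the mixing-time funnel has its minimum at the centre and is symmetric", {
  z0s <- seq(0, 1, length.out = 101)
  t95s <- vapply(z0s, function(z0)
    mixing_time_1d(diffusion_problem("axial", 1, 1, feed_position = z0)),
    numeric(1))
  t_mid <- t95s[51]
  expect_true(all(t95s >= t_mid - 1e-12))
  expect_equal(t95s, rev(t95s), tolerance = 1e-10)
})

test_that("optimal axial positions follow the odd half-fraction rule", {
  expect_equal(optimal_axial_positions(1), 0.5)
  expect_equal(optimal_axial_positions(2), c(0.25, 0.75))
  expect_equal(optimal_axial_positions(4), c(0.125, 0.375, 0.625, 0.875))
  expect_error(optimal_axial_positions(0), "positive integer")
})

test_that("optimal radial placement: fractions, weights, counts, residuals", {
  p1 <- optimal_radial_placement(1)
  expect_equal(p1$radial_fractions, 0.6276, tolerance = 1e-4)
  expect_equal(p1$weights, 1)
  expect_equal(p1$tangential_counts, 1L)
  p2 <- optimal_radial_placement(2)
  expect_equal(p2$radial_fractions, c(0.3428, 0.7868), tolerance = 1e-4)
  expect_equal(p2$weights, c(0.302, 0.698), tolerance = 2e-3)
  expect_equal(p2$weights[2] / p2$weights[1], 2.31, tolerance = 0.01 / 2.31)
  expect_equal(p2$tangential_counts, c(1L, 2L))
  # dense-solve oracle for the 2x2 weight system
  a <- bessel_roots("J0", 2); b <- bessel_roots("J1", 2)
  M <- rbind(besselJ(b[1] * a / b[2], 0), c(1, 1))
  expect_equal(p2$weights, as.numeric(solve(M, c(0, 1))), tolerance = 1e-12)
  for (N in 1:4) {
    p <- optimal_radial_placement(N)
    expect_equal(sum(p$weights), 1, tolerance = 1e-10)
    expect_lt(p$residual, 1e-10)
    bN <- bessel_roots("J1", N)[N]
    expect_true(all(abs(besselJ(bN * p$radial_fractions, 0)) < 1e-11))
    expect_true(all(diff(p$radial_fractions) > 0))
  }
})

test_that("limiting-rate multipliers and their eigenvalue consistency", {
  expect_equal(limiting_rate_multiplier(2, "center_feed"), 4)
  expect_equal(limiting_rate_multiplier(3, "center_feed"), 9)
  expect_equal(limiting_rate_multiplier(4, "end_feed"), 64)
  # consistency: N points at the optimal positions leave the domain as N
  # centred subdomains of height H/N; the first surviving subdomain mode
  # (m = 2, centred feed) reproduces the multiplier
  H <- 2.7; d <- 0.3
  k_center_full <- rate_constant(diffusion_problem("axial", H, d), 2)
  k_end_full <- rate_constant(diffusion_problem("axial", H, d), 1)
  for (N in c(2, 3, 4)) {
    k_sub <- rate_constant(diffusion_problem("axial", H / N, d), 2)
    expect_equal(k_sub / k_center_full,
                 limiting_rate_multiplier(N, "center_feed"))
    expect_equal(k_sub / k_end_full,
                 limiting_rate_multiplier(N, "end_feed"))
  }
  # feeds at the optimal positions cancel all modes m = 1..N-1 of the
  # full domain (equal-weight sum of pre-exponentials vanishes)
  for (N in 2:4) {
    z0s <- optimal_axial_positions(N)
    for (m in seq_len(N - 1)) {
      amp <- sum(vapply(z0s, function(z0)
        preexponential(diffusion_problem("axial", 1, 1, feed_position = z0),
                       m, 0), numeric(1))) / N
      expect_lt(abs(amp), 1e-12)
    }
  }
})

test_that("scale-up equivalents follow the power and volume correlations", {
  expect_equal(scale_equivalents(2)$power_factor, 8)
  expect_equal(scale_equivalents(10)$volume_factor, 31623, tolerance = 1e-4)
  expect_equal(scale_equivalents(1)[c("power_factor", "volume_factor")],
               list(power_factor = 1, volume_factor = 1))
  expect_error(scale_equivalents(-1), "positive")
})

test_that("diffusion problem validates its domain", {
  expect_error(diffusion_problem("axial", -1, 1), "size")
  expect_error(diffusion_problem("axial", 1, 1, feed_position = 2), "feed_position")
  expect_error(diffusion_problem("tangential", 2 * pi / 2.5, 1, eval_radius = 1),
               "integer k")
  expect_silent(diffusion_problem("tangential", pi, 1, eval_radius = 0.6))
})
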