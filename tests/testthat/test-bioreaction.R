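test_that("ideal reactor reproduces the reference concentrations", {
  s <- ideal_reactor_state(kinetic_params())
  expect_equal(s$S * 1000, 16.7, tolerance = 0.05 / 16.7)  # mg/L, 3 s.f.
  expect_equal(s$O, 0.113, tolerance = 1e-3 / 0.113)  # mg/L
  z <- ideal_reactor_state(kinetic_params(), F = 0)
  expect_equal(z$S, 0)
  expect_equal(z$O, kinetic_params()$Oe)
  expect_error(ideal_reactor_state(kinetic_params(), F = 11),
               "infeasible feed")
})

test_that("oxygen solubility follows Henry's law with mid-column hydrostatics", {
  expect_equal(oxygen_solubility(reactor_catalog("R4")), 12.69,
               tolerance = 5e-3 / 12.69)
  # no hydrostatic head, 1 atm: hand-evaluated Henry's law
  flat <- reactor_spec("flat", "stirred_tank", tank_diameter = 2,
                       working_volume = pi * 0.002, aspect_ratio = 0.001,
                       n_impellers = 1, impeller_ratio = 1 / 3,
                       stirrer_speed = 1)
  expect_equal(oxygen_solubility(flat, head_pressure = 101325), 7.07,
               tolerance = 2e-3)
  expect_equal(oxygen_solubility(flat, henry = 0), 0)
})

test_that("single compartment recovers the ideal reactor", {
  op <- transport_operator(single_comp_network())
  fc <- data.frame(index = 1L, weight = 1)
  kp <- kinetic_params()
  sf <- solve_substrate_field(op, fc, kp)
  expect_equal(sf$S, ideal_reactor_state(kp)$S, tolerance = 1e-8)
  O <- solve_oxygen_field(op, sf, kp)
  expect_equal(O, ideal_reactor_state(kp)$O, tolerance = 1e-6)
})

test_that("steady state closes the substrate and oxygen balances", {
  net <- build_network(toy_tank_spec(), grid = c(6, 3, 4))
  op <- transport_operator(net)
  kp <- kinetic_params()
  fc <- locate_feed_compartments(net, feed_arrangement("Top"))
  sf <- solve_substrate_field(op, fc, kp)
  expect_true(all(sf$S > 0))
  uptake <- kp$qS * kp$X * sf$S / (sf$S + kp$KS)
  expect_equal(vol_mean(uptake, op$volumes), kp$F, tolerance = 1e-8)
  O <- solve_oxygen_field(op, sf, kp)
  expect_true(all(O > 0 & O <= kp$Oe))
  resp <- O / (O + kp$KO)
  expect_true(all(resp > 0 & resp < 1))
  transfer <- kp$kLa * (kp$Oe - O)
  consumption <- 1000 * kp$YOS * uptake * resp
  expect_equal(vol_mean(transfer, op$volumes),
               vol_mean(consumption, op$volumes),
               tolerance = 1e-8 * vol_mean(transfer, op$volumes))
  # the substrate maximum sits in the feed zone (top layer)
  comp <- net$compartments
  expect_equal(comp$iz[which.max(sf$S)], max(comp$iz))
  # oxygen is depleted where substrate is abundant
  expect_lt(stats::cor(sf$S, O), 0)
})

test_that("sparse pseudo-time solution matches a dense Newton oracle", {
  net <- build_network(toy_tank_spec(), grid = c(4, 2, 2))  # 16 compartments
  op <- transport_operator(net)
  kp <- kinetic_params()
  fc <- locate_feed_compartments(net, feed_arrangement("Top"))
  sf <- solve_substrate_field(op, fc, kp)
  oracle <- dense_substrate_oracle(op, fc, kp)
  expect_equal(sf$S, oracle, tolerance = 1e-8)
})

test_that("derived fields: uptake time-scale and instantaneous yield", {
  kp <- kinetic_params()
  d <- derived_fields(0.0167, kp)
  expect_equal(d$tau_S, (0.0167 + 0.025) / 10)      # ~15 s in hours
  expect_equal(derived_fields(1e6, kp)$y_XS, 0.475, tolerance = 1e-6)
  S0 <- kp$KS / (kp$YXS * kp$qS / kp$qd - 1)        # yield zero crossing
  expect_equal(S0 * 1000, 1.32, tolerance = 0.005 / 1.32)  # 3 s.f.
  expect_equal(derived_fields(S0, kp)$y_XS, 0, tolerance = 1e-12)
  expect_error(derived_fields(c(0.1, 0), kp), "positive")
})

test_that("field statistics: Monod concavity gap and Taylor correction", {
  u <- field_statistics(rep(0.02, 5), rep(1, 5))
  expect_equal(u$sd, 0)
  expect_equal(u$averaged_monod, u$monod_of_mean)
  st <- field_statistics(c(0.005, 0.045), c(1, 1), KS = 0.025)
  expect_equal(st$averaged_monod, 0.4048, tolerance = 1e-4)
  expect_equal(st$monod_of_mean, 0.5)
  expect_gt(st$monod_of_mean - st$averaged_monod, 0)
  # Jensen's inequality on random positive fields, and the second-order
  # Taylor expansion for mild heterogeneity
  set.seed(42)
  for (i in 1:100) {
    f <- stats::rlnorm(30, log(0.02), 0.8)
    v <- stats::runif(30, 0.5, 2)
    s <- field_statistics(f, v)
    expect_lte(s$averaged_monod, s$monod_of_mean + 1e-12)
  }
  mild <- field_statistics(0.02 * (1 + stats::rnorm(200, 0, 0.02)),
                           rep(1, 200))
  expect_equal(mild$averaged_monod,
               mild$monod_of_mean - mild$taylor_correction,
               tolerance = 1e-4)
})
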