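test_that("toy tank network has the expected size and balances exactly", {
  net <- build_network(toy_tank_spec(), grid = c(4, 2, 1))
  expect_equal(nrow(net$compartments), 8)
  expect_lt(check_continuity(net), 1e-12)
  expect_equal(sum(net$compartments$volume), pi / 4 * 2)
})

test_that("catalog networks reproduce the printed geometries", {
  r4 <- build_network(reactor_catalog("R4"))
  expect_equal(r4$height, 3.33 * 2.09)
  expect_equal(sum(r4$compartments$volume), 23.8, tolerance = 1e-12)
  expect_lt(check_continuity(r4), 1e-12)
  b13 <- build_network(reactor_catalog("B13"))
  expect_equal(b13$height, 20.0)
  expect_equal(sum(b13$compartments$volume), 40.2 * (1 - 0.233))
  expect_lt(check_continuity(b13), 1e-12)
})

test_that("continuity check flags a perturbed edge", {
  net <- build_network(toy_tank_spec(), grid = c(4, 2, 2))
  net$flows$rate[1] <- net$flows$rate[1] * 1.01
  expect_error(check_continuity(net), "continuity violated at compartment")
})

test_that("transport operator conserves mass and fixes the uniform field", {
  for (net in list(build_network(toy_tank_spec(), grid = c(6, 3, 4)),
                   build_network(reactor_catalog("B13"), grid = c(10, 3, 4)))) {
    op <- transport_operator(net)
    sc <- max(abs(op$A))
    expect_lt(max(abs(op$A %*% rep(1, length(op$volumes)))), 1e-12 * sc)
    expect_lt(max(abs(Matrix::t(op$A) %*% op$volumes)), 1e-12 * sc)
    expect_true(all(op$A[cbind(1:3, 1:3)] <= 0))
  }
})

test_that("two-compartment antisymmetric mode decays at 4q/V", {
  q <- 0.37; V <- 2.4
  op <- transport_operator(two_comp_network(q, V))
  ev <- eigen(as.matrix(op$A))$values
  expect_equal(sort(Re(ev)), c(-4 * q / V, 0), tolerance = 1e-12)
})

test_that("chain slowest eigenvalue converges to the diffusion limit at O(n^-2)", {
  # n-cell exchange chain ~ axial diffusion with d = q dz H / V;
  # slowest nonzero rate -> pi^2 d / H^2
  q <- 0.05; V <- 1; H <- 1
  err <- vapply(c(25, 50, 100, 200), function(n) {
    op <- transport_operator(chain_network(n, q, V, H))
    lam <- sort(-Re(eigen(as.matrix(op$A), only.values = TRUE)$values))[2]
    d_eff <- q * (H / n) * H / V
    abs(lam - pi^2 * d_eff / H^2) / (pi^2 * d_eff / H^2)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  # halving the spacing reduces the error ~4x
  expect_equal(err[1] / err[2], 4, tolerance = 0.2)
  expect_equal(err[3] / err[4], 4, tolerance = 0.2)
})

test_that("feed locator maps arrangements to the expected compartments", {
  net <- build_network(reactor_catalog("R4"))
  top <- locate_feed_compartments(net, feed_arrangement("Top"))
  ctop <- net$compartments[net$compartments$index == top$index, ]
  expect_equal(ctop$iz, net$grid[1])
  expect_equal(ctop$ir, 1L)
  # centre feed on an even grid straddles the mid-plane symmetrically
  ctr <- locate_feed_compartments(net, feed_arrangement("A1R1T1"))
  cc <- net$compartments[match(ctr$index, net$compartments$index), ]
  expect_equal(sum(ctr$weight), 1)
  expect_equal(mean(cc$z), net$height / 2)
  # A4R2T2: 4 levels x 6 points, inner:outer ring weights 0.302:0.698
  arr <- feed_arrangement("A4R2T2")
  expect_equal(nrow(arr$points), 24)
  w_by_r <- tapply(arr$points$weight, round(arr$points$r_frac, 3), sum)
  expect_equal(as.numeric(w_by_r), c(0.302, 0.698), tolerance = 2e-3)
  fc <- locate_feed_compartments(net, arr)
  expect_equal(sum(fc$weight), 1)
  expect_gt(nrow(fc), 8)
  # explicit point outside the vessel
  bad <- feed_arrangement(points = data.frame(z = 100, r = 0, phi = 0))
  expect_error(locate_feed_compartments(net, bad), "outside")
})

test_that("calibration is a fixed point and flows scale linearly with time", {
  net <- build_network(toy_tank_spec(), grid = c(6, 2, 4))
  op <- transport_operator(net)
  fc <- locate_feed_compartments(net, feed_arrangement("Top"))
  t95 <- simulate_tracer(op, fc)$t95
  cal <- calibrate_flow_scale(net, target_t95 = t95)
  expect_equal(attr(cal, "scale"), 1, tolerance = 1e-6)
  dbl <- scale_network(net, 2)
  t95_dbl <- simulate_tracer(transport_operator(dbl),
                             locate_feed_compartments(dbl, feed_arrangement("Top")))$t95
  expect_equal(t95_dbl, t95 / 2, tolerance = 1e-6)
})

test_that("grid refinement preserves the placement-effect ratio", {
  spec <- reactor_catalog("R1")
  ratio <- vapply(list(c(12, 6, 6), c(24, 12, 6)), function(g) {
    net <- calibrate_flow_scale(build_network(spec, grid = g))
    op <- transport_operator(net)
    tt <- simulate_tracer(op, locate_feed_compartments(net, feed_arrangement("Top")))$t95
    tc <- simulate_tracer(op, locate_feed_compartments(net, feed_arrangement("A1R1T1")))$t95
    tt / tc
  }, numeric(1))
  expect_lt(abs(ratio[2] - ratio[1]) / ratio[1], 0.15)
})

test_that("removing inter-stage exchange makes a multi-impeller tank non-mixing", {
  spec <- reactor_spec("toy2", "stirred_tank", tank_diameter = 1,
                       working_volume = pi / 4 * 2, aspect_ratio = 2,
                       n_impellers = 2, impeller_ratio = 1 / 3,
                       stirrer_speed = 1)
  net <- build_network(spec, grid = c(8, 2, 2),
                       flow = flow_params(interstage_exchange = 0))
  op <- transport_operator(net)
  fc <- locate_feed_compartments(net, feed_arrangement("Top"))
  expect_error(simulate_tracer(op, fc), "failed to mix")
})

test_that("network export round-trips through CSV", {
  net <- build_network(toy_tank_spec(), grid = c(4, 2, 2))
  nodes <- tempfile(fileext = ".csv"); edges <- tempfile(fileext = ".csv")
  write_network_csv(net, nodes, edges)
  fl <- utils::read.csv(edges)
  expect_equal(fl$rate, net$flows$rate)
  nd <- utils::read.csv(nodes)
  expect_equal(nd$volume, net$compartments$volume)
})
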