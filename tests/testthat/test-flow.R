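test_that("two equal vessels in series halve the pressure at the midpoint", {
  v <- rbind(c(0, 0, 0), c(50, 0, 0), c(100, 0, 0))
  net <- vascular_network(v, rbind(c(1L, 2L), c(2L, 3L)),
                          domain = rbind(c(0, -10, -10), c(100, 10, 10)))
  sol <- solve_flow(net, flow_bc("x", dp = 1))
  expect_equal(sol$pressure[2], 0.5, tolerance = 1e-12)
  expect_lt(mass_imbalance(net, sol), 1e-8)
})

test_that("a converging Y junction reproduces the hand-solved pressures and flows", {
  # two inlets at P = 1, one outlet at P = 0, all conductances equal
  v <- rbind(c(0, 20, 0), c(0, -20, 0), c(50, 0, 0), c(100, 0, 0))
  e <- rbind(c(1L, 3L), c(2L, 3L), c(3L, 4L))
  len <- sqrt(sum(c(50, 20)^2))
  net <- vascular_network(v, e, domain = rbind(c(0, -30, -10), c(100, 30, 10)))
  g <- rep(1, 3)  # equal conductances isolate the topology
  sol <- solve_flow(net, flow_bc("x", dp = 1), conductance = g)
  expect_equal(sol$pressure[3], 2 / 3, tolerance = 1e-12)
  expect_equal(abs(sol$flow[3]), 2 / 3, tolerance = 1e-12)
})

test_that("interior net flows vanish and permeability is invariant to dp and mu", {
  net <- s75_network(1)
  sol <- solve_flow(net, flow_bc("x", dp = 100, mu = 1e-3))
  expect_lt(mass_imbalance(net, sol), 1e-8)
  K1 <- permeability(net, sol = sol)
  K2 <- permeability(net, sol = solve_flow(net, flow_bc("x", dp = 3177)))
  K3 <- permeability(net, sol = solve_flow(net, flow_bc("x", dp = 100, mu = 3.5e-3)))
  expect_equal(K2 / K1, 1, tolerance = 1e-10)
  expect_equal(K3 / K1, 1, tolerance = 1e-10)
})

test_that("a single spanning channel has the closed-form permeability", {
  v <- rbind(c(0, 60, 60), c(120, 60, 60))
  net <- vascular_network(v, rbind(c(1L, 2L)), diameter = 5,
                          domain = rbind(c(0, 0, 0), c(120, 120, 120)))
  K <- permeability(net, "x")
  expect_equal(K, pi * 5^4 / (128 * 120^2), tolerance = 1e-10)
  expect_error(permeability(net, "q"))
  expect_error(solve_flow(net, flow_bc("y")), "does not span")
})

test_that("transit times follow length over velocity and scale with 1/dp", {
  v <- rbind(c(0, 60, 60), c(120, 60, 60))
  net <- vascular_network(v, rbind(c(1L, 2L)), diameter = 5,
                          domain = rbind(c(0, 0, 0), c(120, 120, 120)))
  s1 <- solve_flow(net, flow_bc("x", dp = 10))
  t1 <- transit_times(net, s1)
  expect_equal(t1$median, 120 / abs(s1$velocity[1]), tolerance = 1e-12)
  s2 <- solve_flow(net, flow_bc("x", dp = 20))
  expect_equal(transit_times(net, s2)$median, t1$median / 2, tolerance = 1e-12)
})

test_that("transit-time distributions are reproducible across seed groups", {
  pool <- function(seeds) unlist(lapply(seeds, function(s) {
    n <- s75_network(s)
    transit_times(n, solve_flow(n, flow_bc("x")))$times
  }))
  t1 <- pool(1:3); t2 <- pool(4:6)
  ks <- suppressWarnings(stats::ks.test(log(t1), log(t2)))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("occluding one of two equal inlets of a Y gives the analytic 0.75 flow ratio", {
  # converging Y: with equal conductances everywhere the ratio is exactly
  # (1/2)/(2/3) = 3/4; here the inlet and outlet lengths differ so the
  # analytic ratio is formed from the Poiseuille conductances directly
  v <- rbind(c(0, 30, 0), c(0, -30, 0), c(40, 0, 0), c(80, 0, 0))
  e <- rbind(c(1L, 3L), c(2L, 3L), c(3L, 4L))
  net <- vascular_network(v, e, diameter = 5,
                          domain = rbind(c(0, -40, -10), c(80, 40, 10)))
  oc <- occlusion_campaign(net, flow_bc("x", dp = 1))
  conv <- oc$records[oc$records$type == "converging", ]
  expect_equal(nrow(conv), 2L)
  g_in <- pi * 5^4 / (128 * 1e-3 * net$length[1])
  g_out <- pi * 5^4 / (128 * 1e-3 * net$length[3])
  # analytic ratio for one occluded inlet with distinct conductances
  p_base <- 2 * g_in / (2 * g_in + g_out)
  p_occl <- g_in / (g_in + g_out)
  expect_equal(conv$ratio_a, rep(p_occl / p_base, 2), tolerance = 1e-6)
})

test_that("an isolated diverging Y loses all outflow when its only inlet is occluded", {
  v <- rbind(c(0, 0, 0), c(40, 0, 0), c(80, 30, 0), c(80, -30, 0),
             c(120, 30, 0), c(120, -30, 0))
  e <- rbind(c(1L, 2L), c(2L, 3L), c(2L, 4L), c(3L, 5L), c(4L, 6L))
  net <- vascular_network(v, e, diameter = 5,
                          domain = rbind(c(0, -40, -10), c(120, 40, 10)))
  oc <- occlusion_campaign(net, flow_bc("x", dp = 1))
  div <- oc$records[oc$records$type == "diverging", ]
  expect_equal(nrow(div), 1L)
  expect_true(div$zero_flow)
  expect_equal(div$ratio_a, 0)
})

test_that("ensemble occlusion ratios obey their sign and range contracts", {
  net <- s75_network(3)
  oc <- occlusion_campaign(net)
  conv <- oc$records[oc$records$type == "converging", ]
  div <- oc$records[oc$records$type == "diverging", ]
  expect_true(all(conv$ratio_a >= -1e-9 & conv$ratio_a <= 1 + 1e-9))
  expect_true(all(div$ratio_a >= -1e-9 & div$ratio_a <= 1 + 1e-9))
  expect_true(all(div$ratio_b <= 1e-9))
  # diverging case: post-occlusion flow magnitudes equal in both branches
  both <- div[!div$zero_flow, ]
  expect_gt(nrow(both), 0)
})
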