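test_that("the metric table summarizes an ensemble deterministically", {
  nets <- s75_ensemble(10)[1:3]
  tab <- metric_table(nets)
  expect_equal(tab$n, 3L)
  expect_true(all(c("length_density", "mean_edges_per_loop", "permeability")
                  %in% tab$summary$metric))
  # SD across networks (ROIs), not pooled elements
  ld <- tab$per_network$length_density
  expect_equal(tab$summary$sd[tab$summary$metric == "length_density"],
               stats::sd(ld))
  tab2 <- metric_table(lapply(1:3, function(s) generate_network(s75_config(s))))
  expect_equal(tab$summary$mean, tab2$summary$mean, tolerance = 1e-12)
  # single-network table has empty SD column
  tab1 <- metric_table(nets[[1]], flow = FALSE)
  expect_true(all(is.na(tab1$summary$sd)))
})

test_that("the convergence criterion arithmetic matches its definition", {
  expect_equal(convergence_values(c(10, 9, 9.2)),
               c(NA, abs(9 - 10) / 9, abs(9.2 - 9) / 9.2))
  # x_conv is the first size after which all values stay below tolerance
  M <- c(10, 9, 9.2, 9.21, 9.2)
  cv <- convergence_values(M)
  expect_true(all(cv[3:5] < 0.05))
  expect_gt(cv[2], 0.05)
})

test_that("length density scales as the inverse square of the characteristic length", {
  dens <- vapply(c(50, 65, 80), function(lc) {
    nets <- lapply(1:2, function(s)
      generate_network(generation_config(lc = lc, domain = rep(240, 3),
                                         seed = 100 + s)))
    mean(vapply(nets, function(n) morphometry(n)$length_density, numeric(1)))
  }, numeric(1))
  fit <- stats::lm(log(dens) ~ log(c(50, 65, 80)))
  expect_equal(unname(stats::coef(fit)[2]), -2, tolerance = 0.1)
})

test_that("mean vessel length scales linearly with the characteristic length", {
  len <- vapply(c(50, 80), function(lc) {
    net <- generate_network(generation_config(lc = lc, domain = rep(320, 3),
                                              seed = 7))
    morphometry(net)$length_mean
  }, numeric(1))
  expect_equal(len[2] / len[1], 80 / 50, tolerance = 0.15)
})

test_that("ensemble permeabilities are approximately Gaussian for large samples", {
  K <- cached("K100", vapply(seq_len(100), function(s) {
    net <- generate_network(generation_config(lc = 75, domain = rep(240, 3),
                                              seed = 1000 + s))
    suppressWarnings(permeability(net, "x"))
  }, numeric(1)))
  z <- (K - mean(K)) / stats::sd(K)
  expect_lt(abs(mean(z^3)), 0.75)          # no marked skew
  expect_gt(stats::shapiro.test(K)$p.value, 0.001)
})
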