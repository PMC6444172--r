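test_that("the distance field around a single axial vessel follows the geometry", {
  v <- rbind(c(0, 10.5, 10.5), c(21, 10.5, 10.5))
  net <- vascular_network(v, rbind(c(1L, 2L)), diameter = 5,
                          domain = rbind(c(0, 0, 0), c(21, 21, 21)))
  f <- compute_evd(net, 1)
  # voxel centred 10 um off the centreline: EVD = 10 - 2.5
  expect_equal(f$dist[11, 21, 11], 10 - 2.5, tolerance = 1e-9)
  # voxel on the centreline is intravascular
  expect_true(is.na(f$dist[11, 11, 11]))
  expect_true(f$mask[11, 11, 11])
  expect_error(compute_evd(net, 0), "positive")
})

test_that("the accelerated field equals the brute-force oracle on a 20^3 box", {
  net <- crop_network(s75_network(1), rbind(c(60, 60, 60), c(120, 120, 120)))
  f <- compute_evd(net, 3)
  want <- evd_brute(net, 3)
  want[want < 0] <- NA_real_
  expect_equal(f$dist, want, tolerance = 1e-9)
})

test_that("parallel vessel planes give the closed-form maximum EVD", {
  # axial vessels on a square grid with spacing s in y, plates spanning x
  s <- 20
  ys <- seq(10, 90, by = s)
  v <- do.call(rbind, lapply(ys, function(y) rbind(c(0, y, 50), c(100, y, 50))))
  e <- cbind(seq(1, 2 * length(ys), by = 2), seq(2, 2 * length(ys), by = 2))
  net <- vascular_network(v, e, diameter = 5,
                          domain = rbind(c(0, 0, 49), c(100, 100, 51)))
  f <- compute_evd(net, 1)
  # far from z-boundary effects the max over y between two vessels is
  # s/2 - r at the mid-plane
  mid <- f$dist[50, 20, 2]
  expect_equal(mid, s / 2 - 2.5, tolerance = 0.8)  # voxel-centre offset
})

test_that("maxima on a regular grid give the exact box-counting curve", {
  # a synthetic field whose local maxima sit on a regular 20-um grid
  net <- s75_network(1)
  f <- compute_evd(net, 2)
  es <- evd_statistics(f)
  expect_lte(es$max, sqrt(sum((net$domain[2, ] - net$domain[1, ])^2)) / 2)
  expect_gte(es$mean_local_max, es$mean)

  # synthetic field whose only local maxima sit on a regular 20-um grid:
  # distance to the nearest grid point is separable across axes
  centres <- (1:120 - 0.5) * 2
  grid1 <- seq(10, 230, 20)
  f1 <- vapply(centres, function(t) min((t - grid1)^2), numeric(1))
  fake <- f
  fake$dist <- 5 - sqrt(outer(outer(f1, f1, "+"), f1, "+"))
  fake$mask[] <- FALSE
  bc <- box_count_local_maxima(fake, radii = 240 / c(12, 8, 6, 4, 3, 2, 1))
  expect_equal(bc$N, (240 / bc$r)^3)
  expect_error(box_count_local_maxima(fake, radii = c(3, 2, 1)), "ascending")
})

test_that("generated networks are space-filling with convex tissue domains", {
  net <- s75_network(1)
  f <- cached("evd_s75_1", compute_evd(net, 2))
  bc <- box_count_local_maxima(f)
  sl <- bc$slope[bc$r >= 75 & bc$r <= 150]
  sl <- sl[is.finite(sl)]
  expect_true(length(sl) >= 1)
  expect_true(all(abs(sl + 3) <= 0.2))
  # slope flattens to 0 once one box covers the domain
  expect_equal(bc$N[bc$r == 240], 1)
  es <- evd_statistics(f)
  expect_gt(es$convexity_index, 0.7)
  expect_lt(es$convexity_index, 1.1)
})

test_that("morphometry reproduces lattice closed forms and flags degenerate input", {
  cln <- build_cln(60, c(240, 240, 240))
  mo <- morphometry(cln)
  expect_equal(mo$length_density, 833 + 1 / 3, tolerance = 1e-9)
  empty <- vascular_network(matrix(numeric(0), ncol = 3),
                            matrix(integer(0), ncol = 2),
                            domain = rbind(c(0, 0, 0), c(10, 10, 10)))
  mo0 <- morphometry(empty)
  expect_equal(mo0$length_density, 0)
  expect_equal(mo0$edge_density, 0)
  expect_false(isTRUE(mo0$evd_defined))
})
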