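test_that("interpolation reproduces tabulated nodes and the Pb K-edge jump", {
  tab <- attenuation_table("Al")
  # node identity away from edges
  idx <- c(5, 10, 15)
  expect_equal(mu("Al", tab$energies[idx]), tab$mu_over_rho[idx],
               tolerance = 1e-12)
  expect_equal(muen("air", 60), 0.03041, tolerance = 1e-12)
  # K-edge jump: attenuation just above the Pb K edge exceeds just below
  expect_gt(mu("Pb", 89), mu("Pb", 87))
  expect_gt(mu("Pb", 90) / mu("Pb", 87), 3)
  # query exactly at the duplicated edge energy returns the supra-edge value
  expect_equal(mu("Pb", 88.005), 7.683, tolerance = 1e-9)
})

test_that("mid-grid queries match a direct two-point log-log oracle", {
  for (m in c("Al", "Cu", "Pb", "water")) {
    tab <- attenuation_table(m)
    n <- length(tab$energies)
    # pick interior segments away from edges and hand-interpolate
    for (i in unique(pmin(c(10L, 14L, 18L), n - 1L))) {
      e0 <- tab$energies[i]; e1 <- tab$energies[i + 1L]
      if (e1 == e0) next
      eq <- sqrt(e0 * e1)
      w <- log(eq / e0) / log(e1 / e0)
      oracle <- exp((1 - w) * log(tab$mu_over_rho[i]) +
                      w * log(tab$mu_over_rho[i + 1L]))
      expect_equal(mu(m, eq), oracle, tolerance = 1e-3)
    }
  }
})

test_that("interpolated values never overshoot their bracketing nodes", {
  for (m in attenuation_materials()) {
    tab <- attenuation_table(m)
    n <- length(tab$energies)
    lo <- tab$energies[-n]; hi <- tab$energies[-1L]
    keep <- hi > lo
    eq <- sqrt(lo[keep] * hi[keep])
    v <- mu(m, eq)
    ylo <- pmin(tab$mu_over_rho[-n], tab$mu_over_rho[-1L])[keep]
    yhi <- pmax(tab$mu_over_rho[-n], tab$mu_over_rho[-1L])[keep]
    expect_true(all(v >= ylo - 1e-12 & v <= yhi + 1e-12))
  }
})

test_that("energy absorption does not exceed attenuation above 20 keV", {
  for (m in c("air", "water", "Al")) {
    tab <- attenuation_table(m)
    e <- tab$energies[tab$energies > 20]
    expect_true(all(muen(m, e) < mu(m, e) + 1e-12))
  }
})

test_that("mixture rule reproduces mass-weighted elemental coefficients", {
  mix <- mixture_table(c(Al = 0.3, Cu = 0.7), density = 5)
  # exact at the union grid nodes
  e_nodes <- c(20, 40, 60, 100)
  i <- match(e_nodes, mix$energies)
  expect_equal(mix$mu_over_rho[i],
               0.3 * mu("Al", e_nodes) + 0.7 * mu("Cu", e_nodes),
               tolerance = 1e-9)
  # between nodes the log-log interpolant of the mixture tracks the
  # mass-weighted sum of the component interpolants closely
  e_mid <- c(35, 70, 110)
  expect_equal(pbeq:::loglog_interp(mix$energies, e_mid, mix$mu_over_rho),
               0.3 * mu("Al", e_mid) + 0.7 * mu("Cu", e_mid),
               tolerance = 5e-3)
})

test_that("unknown materials and out-of-range energies are rejected", {
  expect_error(mu("unobtainium", 50), "unknown material")
  expect_error(mu("Pb", 0.5), "outside")
  expect_error(mu("Pb", 200), "outside")
  expect_error(muen("W", 50), "not tabulated")
})
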