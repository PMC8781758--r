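test_that("side integrals reduce to plain moments of y when alpha = 0", {
  for (d in c(0.7, 2, 3.5)) {
    expect_equal(side_integral(0, d, side = "compression", order = 1), d^2 / 2)
    expect_equal(side_integral(0, d, side = "tension", order = 1), -d^2 / 2)
    expect_equal(side_integral(0, d, side = "compression", order = 2), d^3 / 3)
    expect_equal(side_integral(0, d, side = "tension", order = 2), d^3 / 3)
  }
})

test_that("closed forms agree with adaptive quadrature over the admissible range", {
  # deterministic grid of (alpha, depth) pairs spanning both sides of zero,
  # skipping pairs too close to the admissibility walls
  alphas <- seq(-1.6, 1.8, by = 0.2)
  depths <- seq(0.5, 5.5, by = 0.5)
  n <- 0
  for (a in alphas) for (d in depths) {
    if (d >= 0.95 * admissible_depth(a, 6)) next
    n <- n + 1
    for (side in c("compression", "tension")) for (ord in 1:2) {
      cf <- side_integral(a, d, 6, side, ord)
      qu <- quad_side_integral(a, d, 6, side, ord)
      expect_equal(cf, qu, tolerance = 1e-10)
    }
  }
  expect_gte(n, 100)
})

test_that("series and closed-form branches agree near alpha = 0", {
  # the kernel switches to a series for |alpha * depth / h_ref| < 0.05
  for (a in c(-0.101, -0.099, 0.099, 0.101)) {  # straddle the switch at d = 3
    expect_equal(side_integral(a, 3, side = "compression", order = 1),
                 quad_side_integral(a, 3, 6, "compression", 1),
                 tolerance = 1e-12)
    expect_equal(side_integral(a, 3, side = "compression", order = 2),
                 quad_side_integral(a, 3, 6, "compression", 2),
                 tolerance = 1e-12)
  }
})

test_that("inadmissible (alpha, depth) pairs are rejected", {
  expect_error(side_integral(2.1, 3, side = "compression"), "inadmissible")
  expect_error(side_integral(-4, 3, side = "tension"), "inadmissible")
  expect_error(side_integral(0.5, -1), "positive")
})

test_that("force balance: symmetric sections balance, homogeneous closed form", {
  m <- gradient_modulus_model(20000, 0.4, 0.4)
  expect_equal(force_balance_residual(m, make_axis(3, 3, 1000)), 0)
  m0 <- gradient_modulus_model(20000, 0, 0)
  expect_equal(force_balance_residual(m0, make_axis(3.1, 2.9, 1000)),
               (3.1^2 - 2.9^2) / 2)
  expect_equal(force_balance_residual(m0, make_axis(3.1, 2.9, 1000)), 0.6)
})

test_that("force residual increases monotonically in h_C at fixed gradients", {
  m <- gradient_modulus_model(20000, 0.6, -0.2)
  h <- 6
  hC <- seq(1.5, 4.5, length.out = 25)
  res <- vapply(hC, function(x)
    force_balance_residual(m, make_axis(x, h - x, 1000)), numeric(1))
  expect_true(all(diff(res) > 0))
})

test_that("moment balance: Euler-Bernoulli closed form and M/E0 invariance", {
  # homogeneous beam: residual vanishes when M = E0 w h^3 / (12 rho)
  E0 <- 20000; w <- 6; h <- 6; rho <- 1200
  m0 <- gradient_modulus_model(E0, 0, 0)
  ax <- make_axis(h / 2, h / 2, rho)
  M <- E0 * w * h^3 / (12 * rho)
  expect_equal(moment_balance_residual(m0, ax, M, w), 0, tolerance = 1e-12)
  # doubling both M and E0 leaves the residual unchanged
  m <- gradient_modulus_model(E0, 0.5, 0.2)
  ax2 <- make_axis(3.2, 2.8, 900)
  r1 <- moment_balance_residual(m, ax2, 2376, w)
  m2 <- gradient_modulus_model(2 * E0, 0.5, 0.2)
  expect_equal(moment_balance_residual(m2, ax2, 2 * 2376, w), r1)
})
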