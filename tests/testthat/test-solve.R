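test_that("forward model reproduces the homogeneous Euler-Bernoulli limit", {
  fw <- forward_strains(0, 0, E0_default, default_geom, moment_meas)
  sigma <- 6 * moment_meas / (default_geom$width_w * default_geom$height_h^2)
  expect_equal(fw$eps_C_ue, sigma / E0_default * 1e6, tolerance = 1e-12)
  expect_equal(fw$eps_T_ue, sigma / E0_default * 1e6, tolerance = 1e-12)
  expect_equal(fw$axis$h_C, 3, tolerance = 1e-12)
})

test_that("equal gradients put the neutral axis exactly at mid-depth", {
  for (a in c(-0.5, 0.3, 1.0)) {
    fw <- forward_strains(a, a, E0_default, default_geom, moment_meas)
    expect_equal(fw$axis$h_C, fw$axis$h_T, tolerance = 1e-12)
    expect_equal(fw$eps_C_ue, fw$eps_T_ue, tolerance = 1e-9)
  }
})

test_that("solved h_C decreases as the compression side stiffens", {
  hc <- vapply(seq(-0.4, 1.2, length.out = 9), function(a)
    forward_strains(a, 0.1, E0_default, default_geom, moment_meas)$axis$h_C,
    numeric(1))
  expect_true(all(diff(hc) < 0))
})

test_that("inverse solve recovers known gradients (round trip both ways)", {
  grid <- expand.grid(aC = seq(-0.5, 1.0, length.out = 5),
                      aT = seq(-0.5, 1.0, length.out = 5))
  h <- default_geom$height_h
  for (i in seq_len(nrow(grid))) {
    fw <- forward_strains(grid$aC[i], grid$aT[i], E0_default, default_geom,
                          moment_meas)
    st <- solve_alphas(fw$eps_C_ue, fw$eps_T_ue, default_geom, E0_default,
                       moment_meas)
    expect_lt(abs(st$model$alpha_C - grid$aC[i]), 1e-6)
    expect_lt(abs(st$model$alpha_T - grid$aT[i]), 1e-6)
    expect_lt(abs(st$force_residual), 1e-9 * h^2)
    expect_lt(abs(st$moment_residual), 1e-9 * h^3)
    # strains round-trip through the solved state
    fw2 <- forward_strains(st$model$alpha_C, st$model$alpha_T, E0_default,
                           default_geom, moment_meas)
    expect_equal(fw2$eps_C_ue, fw$eps_C_ue, tolerance = 1e-9)
    expect_equal(fw2$eps_T_ue, fw$eps_T_ue, tolerance = 1e-9)
  }
})

test_that("homogeneous strains solve to zero gradients", {
  eps <- sigma_meas / E0_default * 1e6
  st <- solve_alphas(eps, eps, default_geom, E0_default, moment_meas)
  expect_equal(st$model$alpha_C, 0, tolerance = 1e-8)
  expect_equal(st$model$alpha_T, 0, tolerance = 1e-8)
})

test_that("swapping the strain pair mirrors the solution", {
  fw <- forward_strains(0.7, -0.2, E0_default, default_geom, moment_meas)
  st <- solve_alphas(fw$eps_T_ue, fw$eps_C_ue, default_geom, E0_default,
                     moment_meas)
  expect_equal(st$model$alpha_C, -0.2, tolerance = 1e-6)
  expect_equal(st$model$alpha_T, 0.7, tolerance = 1e-6)
})

test_that("unsolvable inputs raise informative errors", {
  # grossly asymmetric strains push h_C near the wall: no admissible solution
  expect_error(solve_alphas(50000, 100, default_geom, E0_default, moment_meas),
               "solve_alphas")
  # admissibility windows for the two sides that cannot both hold
  expect_error(forward_strains(2.3, -3.2, E0_default, default_geom, moment_meas),
               "no admissible")
})
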