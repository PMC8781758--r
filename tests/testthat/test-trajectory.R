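test_that("strain_trajectory validates ordering and positivity", {
  expect_error(strain_trajectory(c(0, 0.5, 0.5), c(1, 1, 1), c(1, 1, 1)),
               "strictly increasing")
  expect_error(strain_trajectory(c(0, 0.5, 1), c(1, 0, 1), c(1, 1, 1)),
               "eps_C_ue")
  tr <- strain_trajectory(c(0, 0.5, 1), c(2800, 2900, 3000),
                          c(2800, 2810, 2820), specimen_id = "X")
  expect_s3_class(tr, "strain_trajectory")
  expect_identical(attr(tr, "specimen_id"), "X")
})

test_that("constant homogeneous strains give zero gradients and no migration", {
  eps <- sigma_meas / E0_default * 1e6
  tr <- strain_trajectory(seq(0, 1, 0.25), rep(eps, 5), rep(eps, 5))
  res <- analyze_trajectory(tr, default_geom, E0_default, moment_meas)
  expect_true(all(res$solved))
  expect_true(all(abs(res$alpha_C) < 1e-8))
  expect_true(all(abs(res$alpha_T) < 1e-8))
  expect_true(all(abs(res$axis_offset_mm) < 1e-12))
})

test_that("a drifting-gradient forward fixture is recovered along the trajectory", {
  fx <- generate_forward_fixture(
    alpha_C_path = function(t) -0.6 * t,
    alpha_T_path = function(t) 0.2 * t - 0.1,
    E0 = E0_default, geom = default_geom, sigma_meas = sigma_meas,
    n_points = 7)
  res <- analyze_trajectory(fx$trajectory, default_geom, E0_default,
                            fx$moment_M)
  expect_true(all(res$solved))
  expect_lt(max(abs(res$alpha_C - fx$truth$alpha_C)), 1e-6)
  expect_lt(max(abs(res$alpha_T - fx$truth$alpha_T)), 1e-6)
})

test_that("axis offset is negative exactly when compression strain dominates", {
  tr <- strain_trajectory(seq(0, 1, length.out = 5),
                          c(2700, 2800, 2819, 2900, 3100),
                          c(2900, 2810, 2819, 2850, 2800))
  res <- analyze_trajectory(tr, default_geom, E0_default, moment_meas)
  expect_identical(res$axis_offset_mm < 0, res$eps_C_ue > res$eps_T_ue)
  expect_equal(res$axis_offset_mm[3], 0, tolerance = 1e-12)
})

test_that("rising compressive strain at fixed tensile strain deepens h_C", {
  tr <- strain_trajectory(seq(0, 1, length.out = 6),
                          seq(2819, 3400, length.out = 6), rep(2807, 6))
  res <- analyze_trajectory(tr, default_geom, E0_default, moment_meas)
  expect_true(all(diff(res$h_C_mm) > 0))
})

test_that("unsolvable records stop with the life fraction, or are flagged", {
  tr <- strain_trajectory(c(0, 0.5, 1), c(2819, 50000, 2900),
                          c(2807, 100, 2810))
  expect_error(
    analyze_trajectory(tr, default_geom, E0_default, moment_meas),
    "t = 0.5")
  res <- analyze_trajectory(tr, default_geom, E0_default, moment_meas,
                            on_error = "flag")
  expect_identical(res$solved, c(TRUE, FALSE, TRUE))
  expect_true(is.na(res$alpha_C[2]))
})

test_that("modulus evolution table reproduces the pointwise profile", {
  fx <- generate_forward_fixture(function(t) -0.5 * t, function(t) 0.1 * t,
                                 E0 = E0_default, geom = default_geom,
                                 n_points = 5)
  res <- analyze_trajectory(fx$trajectory, default_geom, E0_default,
                            fx$moment_M)
  tab <- modulus_evolution_report(res, n_y = 7)
  expect_true(all(tab$E_MPa[tab$y_mm == 0] == E0_default))
  # spot check rows against modulus_profile
  for (i in sample(nrow(tab), 10)) {
    j <- which(res$t == tab$t[i])
    m <- gradient_modulus_model(E0_default, res$alpha_C[j], res$alpha_T[j])
    expect_equal(tab$E_MPa[i], modulus_profile(m, tab$y_mm[i]))
  }
  # homogeneous trajectory: every entry is E0
  eps <- sigma_meas / E0_default * 1e6
  tr0 <- strain_trajectory(c(0, 0.5, 1), rep(eps, 3), rep(eps, 3))
  res0 <- analyze_trajectory(tr0, default_geom, E0_default, moment_meas)
  tab0 <- modulus_evolution_report(res0)
  expect_true(all(abs(tab0$E_MPa - E0_default) < 1e-6))
})

test_that("averaging trajectories averages the strain columns", {
  t1 <- strain_trajectory(c(0, 1), c(3000, 3100), c(2900, 2950), "a")
  t2 <- strain_trajectory(c(0, 1), c(2800, 2900), c(2700, 2750), "b")
  av <- average_trajectories(list(t1, t2))
  expect_equal(av$eps_C_ue, c(2900, 3000))
  expect_equal(av$eps_T_ue, c(2800, 2850))
  t3 <- strain_trajectory(c(0, 0.5), c(1, 2), c(1, 2), "c")
  expect_error(average_trajectories(list(t1, t3)), "grid")
})
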