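test_that("mesh construction: counts, contact nodes, area partition", {
  mesh <- build_mesh(default_geom, 42, 6)
  expect_equal(nrow(mesh$coords), 43 * 7)
  expect_equal(nrow(mesh$conn), 42 * 6)
  # contact x-positions land exactly on node columns
  expect_equal(mesh$coords[mesh$support_nodes, "x"], c(0, 42),
               ignore_attr = TRUE)
  expect_equal(mesh$coords[mesh$load_nodes, "x"], c(4, 38),
               ignore_attr = TRUE)
  expect_equal(mesh$nx * mesh$ny * mesh$dx * mesh$dy,
               mesh$length_L * default_geom$height_h)
  expect_error(build_mesh(default_geom, 40, 6), "contact")
  expect_error(build_mesh(default_geom, 42, 5), "even")
})

test_that("patch test: uniform tension reproduces constant strain exactly", {
  mesh <- build_mesh(default_geom, 21, 4)
  E <- 15000; nu <- 0.3; w <- default_geom$width_w; sigma <- 50
  nnx <- mesh$nx + 1L; nny <- mesh$ny + 1L
  left <- which(mesh$coords[, "x"] == 0)
  right <- which(mesh$coords[, "x"] == mesh$length_L)
  forces <- numeric(2L * nrow(mesh$coords))
  fnode <- sigma * w * mesh$dy
  forces[2L * right - 1L] <- fnode
  edge <- right[mesh$coords[right, "y"] %in% c(0, default_geom$height_h)]
  forces[2L * edge - 1L] <- fnode / 2
  fixed <- c(2L * left - 1L, 2L * left[1])
  sol <- fem_solve(mesh, rep(E, nrow(mesh$conn)), nu, w, fixed, forces)
  prof <- bimodbeam:::.strain_profile(mesh, sol$u, mesh$length_L / 3)
  expect_equal(prof$eps_xx, rep(sigma / E, mesh$ny + 1L), tolerance = 1e-12)
})

test_that("four-point bend: equilibrium, linearity, homogeneous accuracy", {
  mesh <- build_mesh(default_geom, 84, 16)
  m0 <- gradient_modulus_model(E0_default, 0, 0)
  ax <- make_axis(3, 3, 1000)
  F <- four_point_load(sigma_meas, default_geom)
  fem <- assemble_and_solve(mesh, m0, ax, F)
  # reactions balance the applied load
  expect_lt(fem$reaction_balance, 1e-8)
  # doubling the load doubles the displacements
  fem2 <- assemble_and_solve(mesh, m0, ax, 2 * F)
  expect_equal(fem2$u, 2 * fem$u, tolerance = 1e-9)
  # homogeneous beam: neutral axis at mid-depth, surface strain near sigma/E
  expect_equal(fem$neutral_axis_y, 3, tolerance = mesh$dy / 2)
  expect_equal(fem$eps_bottom, sigma_meas / E0_default, tolerance = 0.02)
  expect_equal(-fem$eps_top, sigma_meas / E0_default, tolerance = 0.02)
})

test_that("neutral-axis extraction interpolates sign changes and rejects one-signed fields", {
  prof <- data.frame(y_mm = 0:4, eps_xx = c(2, 1, -1, -2, -3))
  expect_equal(extract_neutral_axis(prof), 1.5)  # antisymmetric pair -> midpoint
  expect_error(extract_neutral_axis(data.frame(y_mm = 0:2, eps_xx = c(1, 2, 3))),
               "no sign change")
})

test_that("graded section: FEM neutral axis matches the analytical model", {
  st <- solve_alphas(3369, 2919, default_geom, E0_default, moment_meas)
  mesh <- build_mesh(default_geom, 84, 16)
  fem <- assemble_and_solve(mesh, st$model, st$axis,
                            2 * moment_meas / default_geom$lever_arm_a)
  expect_lt(abs(fem$neutral_axis_y - st$axis$h_T) / default_geom$height_h,
            0.02)
  # surface strains agree with the measured pair within a few percent
  expect_equal(-fem$eps_top * 1e6, 3369, tolerance = 0.02)
  expect_equal(fem$eps_bottom * 1e6, 2919, tolerance = 0.02)
})

test_that("comparison table mirrors the trajectory and stays within 2% of h", {
  fx <- generate_forward_fixture(function(t) -0.5 * t, function(t) 0.12 * t,
                                 E0 = E0_default, geom = default_geom,
                                 n_points = 4)
  res <- analyze_trajectory(fx$trajectory, default_geom, E0_default,
                            fx$moment_M)
  cmp <- compare_fem_analytical(res, nx = 84, ny = 16)
  expect_equal(nrow(cmp), 4)
  expect_true(all(abs(cmp$deviation_pct) < 2))
  expect_equal(cmp$h_T_analytical_mm, res$h_T_mm)
})
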