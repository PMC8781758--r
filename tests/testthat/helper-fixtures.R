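# Shared study-condition fixtures: the default 6 x 6 mm beam, measurement
# stress 66 MPa, and the homogeneous-initial E0 from the averaged
# pre-fatigue strains (2819 / 2807 microstrain).

default_geom <- specimen_geometry()
sigma_meas <- 66
moment_meas <- bending_moment_from_stress(sigma_meas, default_geom)
E0_default <- calibrate_E0(2819, 2807, sigma_meas)

# homogeneous reference strain (dimensionless) at the measurement stress
eps_homog <- sigma_meas / E0_default

make_axis <- function(h_C, h_T, rho) {
  structure(list(h_C = h_C, h_T = h_T, rho = rho),
            class = "neutral_axis_state")
}

# quadrature oracle for the side integrals (independent of the closed form)
quad_side_integral <- function(alpha, depth, h_ref = 6,
                               side = "compression", order = 1L) {
  f <- if (side == "compression") {
    function(y) (1 - log(1 - alpha * y / h_ref)) * y^order
  } else {
    function(y) (1 - log(1 + alpha * y / h_ref)) * y^order
  }
  lim <- if (side == "compression") c(0, depth) else c(-depth, 0)
  stats::integrate(f, lim[1], lim[2], rel.tol = 1e-13,
                   abs.tol = 0)$value
}
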