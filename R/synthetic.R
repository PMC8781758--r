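# Synthetic strain trajectories with the structure of the measured data:
# a two-phase piecewise-linear compressive strain with a breakpoint near
# 28% of life, a slowly rising tensile strain (~4% total), initial
# magnitudes near the measured averages, and additive Gaussian noise as a
# stand-in for the (unreported) DIC measurement uncertainty.

#' Parameters of the synthetic trajectory generator
#'
#' Defaults mirror the study conditions: initial strains 2819/2807
#' microstrain (the averaged pre-fatigue measurements), compressive
#' breakpoint at 28% of life, a 4% total tensile rise, eleven measurement
#' points, and 20 microstrain additive noise (the order of DIC strain
#' resolution). The compressive phase rises (400 then 150 microstrain) are a
#' rapid-then-slow shape consistent with the reported two-phase behaviour.
#'
#' @param eps_C0,eps_T0 Initial strain magnitudes (microstrain).
#' @param breakpoint_t Life fraction of the compressive-strain kink.
#' @param phase1_rise,phase2_rise Compressive strain increments (microstrain)
#'   over each phase.
#' @param tensile_total_rise_frac Total fractional rise of the tensile strain.
#' @param n_points Number of life-fraction samples (>= 5).
#' @param noise_sd Additive Gaussian noise s.d. (microstrain, >= 0).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `trajectory_generator_params`.
#' @export
trajectory_generator_params <- function(eps_C0 = 2819, eps_T0 = 2807,
                                        breakpoint_t = 0.28,
                                        phase1_rise = 400, phase2_rise = 150,
                                        tensile_total_rise_frac = 0.04,
                                        n_points = 11L, noise_sd = 20,
                                        seed = NULL) {
  if (!(breakpoint_t > 0 && breakpoint_t < 1))
    stop("trajectory_generator_params: 'breakpoint_t' must be inside (0, 1)")
  if (n_points < 5L) stop("trajectory_generator_params: 'n_points' must be >= 5")
  if (noise_sd < 0) stop("trajectory_generator_params: 'noise_sd' must be >= 0")
  if (eps_C0 <= 0 || eps_T0 <= 0)
    stop("trajectory_generator_params: initial strains must be positive")
  structure(list(eps_C0 = eps_C0, eps_T0 = eps_T0,
                 breakpoint_t = breakpoint_t,
                 phase1_rise = phase1_rise, phase2_rise = phase2_rise,
                 tensile_total_rise_frac = tensile_total_rise_frac,
                 n_points = as.integer(n_points), noise_sd = noise_sd,
                 seed = seed), class = "trajectory_generator_params")
}

# noiseless generator means at life fractions tt
.generator_means <- function(p, tt) {
  eps_C <- ifelse(tt <= p$breakpoint_t,
                  p$eps_C0 + p$phase1_rise * tt / p$breakpoint_t,
                  p$eps_C0 + p$phase1_rise +
                    p$phase2_rise * (tt - p$breakpoint_t) / (1 - p$breakpoint_t))
  eps_T <- p$eps_T0 * (1 + p$tensile_total_rise_frac * tt)
  list(eps_C = eps_C, eps_T = eps_T)
}

#' Generate a synthetic strain trajectory
#'
#' Piecewise-linear compressive strain with a kink at `breakpoint_t`,
#' linearly rising tensile strain, i.i.d. Gaussian noise added to both
#' series. Life fractions are a uniform grid on \[0, 1\]; the kink falls
#' between observations for the default 11-point grid. Reproducible: the
#' same seed yields a bit-identical trajectory.
#'
#' @param params A [trajectory_generator_params()].
#' @param specimen_id Label for the generated trajectory.
#' @return A [strain_trajectory()]; the noiseless means are attached as
#'   attribute `truth`.
#' @export
generate_trajectory <- function(params = trajectory_generator_params(),
                                specimen_id = "synthetic") {
  stopifnot(inherits(params, "trajectory_generator_params"))
  tt <- seq(0, 1, length.out = params$n_points)
  mu <- .generator_means(params, tt)
  eps_C <- mu$eps_C; eps_T <- mu$eps_T
  if (params$noise_sd > 0) {
    if (!is.null(params$seed)) set.seed(params$seed)
    eps_C <- eps_C + stats::rnorm(length(tt), 0, params$noise_sd)
    eps_T <- eps_T + stats::rnorm(length(tt), 0, params$noise_sd)
  }
  out <- strain_trajectory(tt, eps_C, eps_T, specimen_id = specimen_id)
  attr(out, "truth") <- data.frame(t = tt, eps_C_ue = mu$eps_C,
                                   eps_T_ue = mu$eps_T)
  attr(out, "params") <- params
  out
}

#' Exact forward-model fixture with known gradient parameters
#'
#' Builds a trajectory whose strains are the exact forward-model output for
#' prescribed gradient paths, so that inverse-recovery can be tested against
#' ground truth. Gradient paths may be numeric vectors (one value per life
#' fraction) or functions of the life fraction.
#'
#' @param alpha_C_path,alpha_T_path Numeric vectors of length `n_points`, or
#'   functions `f(t)`.
#' @param E0 Neutral-axis modulus (MPa).
#' @param geom A [specimen_geometry()].
#' @param sigma_meas Measurement stress (MPa) setting the bending moment.
#' @param n_points Number of life fractions (uniform on \[0, 1\]).
#' @param noise_sd Optional additive noise s.d. (microstrain).
#' @param seed Seed used when `noise_sd > 0`.
#' @param h_ref Reference length (mm).
#' @return A list of class `forward_fixture`: `trajectory`
#'   (a [strain_trajectory()]), `truth` (data frame of t, alpha_C, alpha_T
#'   and the exact strains), `E0`, `geom`, `moment_M`, `h_ref`.
#' @export
generate_forward_fixture <- function(alpha_C_path, alpha_T_path, E0,
                                     geom = specimen_geometry(),
                                     sigma_meas = 66, n_points = 11L,
                                     noise_sd = 0, seed = NULL, h_ref = 6) {
  tt <- seq(0, 1, length.out = n_points)
  aC <- if (is.function(alpha_C_path)) vapply(tt, alpha_C_path, numeric(1))
        else rep_len(alpha_C_path, n_points)
  aT <- if (is.function(alpha_T_path)) vapply(tt, alpha_T_path, numeric(1))
        else rep_len(alpha_T_path, n_points)
  M <- bending_moment_from_stress(sigma_meas, geom)
  eps_C <- eps_T <- numeric(n_points)
  for (i in seq_len(n_points)) {
    fw <- tryCatch(forward_strains(aC[i], aT[i], E0, geom, M, h_ref),
                   error = function(e) e)
    if (inherits(fw, "error"))
      stop(sprintf("generate_forward_fixture: inadmissible gradients at t = %g: %s",
                   tt[i], conditionMessage(fw)))
    eps_C[i] <- fw$eps_C_ue; eps_T[i] <- fw$eps_T_ue
  }
  truth <- data.frame(t = tt, alpha_C = aC, alpha_T = aT,
                      eps_C_ue = eps_C, eps_T_ue = eps_T)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    eps_C <- eps_C + stats::rnorm(n_points, 0, noise_sd)
    eps_T <- eps_T + stats::rnorm(n_points, 0, noise_sd)
  }
  structure(list(trajectory = strain_trajectory(tt, eps_C, eps_T,
                                                specimen_id = "forward_fixture"),
                 truth = truth, E0 = E0, geom = geom, moment_M = M,
                 h_ref = h_ref),
            class = "forward_fixture")
}
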