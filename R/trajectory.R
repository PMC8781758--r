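#' Strain trajectory over fatigue life
#'
#' A table of surface strain pairs sampled over fatigue life: life fraction
#' `t` in \[0, 1\] (strictly increasing, first record the pre-fatigue
#' baseline) with maximum compressive and tensile strain magnitudes in
#' microstrain.
#'
#' @param t Life fractions, strictly increasing in \[0, 1\].
#' @param eps_C_ue Compressive strain magnitudes (microstrain, > 0).
#' @param eps_T_ue Tensile strain magnitudes (microstrain, > 0).
#' @param specimen_id Specimen label.
#' @return A data frame of class `strain_trajectory` with attribute
#'   `specimen_id`.
#' @export
strain_trajectory <- function(t, eps_C_ue, eps_T_ue, specimen_id = "S1") {
  n <- length(t)
  if (n == 0L) stop("strain_trajectory: empty input")
  if (length(eps_C_ue) != n || length(eps_T_ue) != n)
    stop("strain_trajectory: column lengths differ")
  if (any(!is.finite(t)) || any(t < 0) || any(t > 1))
    stop("strain_trajectory: 't' must lie in [0, 1]")
  bad <- which(diff(t) <= 0)
  if (length(bad))
    stop(sprintf("strain_trajectory: life fractions not strictly increasing at row %d",
                 bad[1] + 1L))
  for (nm in c("eps_C_ue", "eps_T_ue")) {
    v <- get(nm)
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad))
      stop(sprintf("strain_trajectory: '%s' must be positive and finite (row %d)",
                   nm, bad[1]))
  }
  out <- data.frame(t = as.numeric(t), eps_C_ue = as.numeric(eps_C_ue),
                    eps_T_ue = as.numeric(eps_T_ue))
  attr(out, "specimen_id") <- specimen_id
  class(out) <- c("strain_trajectory", "data.frame")
  out
}

#' Average several specimens' trajectories
#'
#' Element-wise mean of the strain columns across trajectories sharing the
#' same life-fraction grid. Use when gradients are to be solved on averaged
#' strains rather than per specimen; both modes are legitimate and the
#' package supports either.
#'
#' @param trajs A list of [strain_trajectory()] objects with identical `t`.
#' @param specimen_id Label for the averaged trajectory.
#' @return A [strain_trajectory()].
#' @export
average_trajectories <- function(trajs, specimen_id = "average") {
  stopifnot(length(trajs) >= 1L)
  t0 <- trajs[[1]]$t
  for (tr in trajs) {
    stopifnot(inherits(tr, "strain_trajectory"))
    if (length(tr$t) != length(t0) || any(abs(tr$t - t0) > 1e-12))
      stop("average_trajectories: trajectories must share the same life-fraction grid")
  }
  strain_trajectory(
    t0,
    rowMeans(sapply(trajs, `[[`, "eps_C_ue")),
    rowMeans(sapply(trajs, `[[`, "eps_T_ue")),
    specimen_id = specimen_id)
}

#' Solve the gradient model along a fatigue trajectory
#'
#' Runs [solve_alphas()] on every record of a trajectory and assembles the
#' neutral-axis migration, gradient evolution and extreme-fibre stresses.
#' The neutral-axis offset is reported as `h_T - h/2` — the signed height of
#' the axis above mid-depth, negative when the axis has migrated toward the
#' tension side (which happens exactly when eps_C > eps_T).
#'
#' @param traj A [strain_trajectory()].
#' @param geom A [specimen_geometry()].
#' @param E0 Neutral-axis modulus (MPa).
#' @param moment_M Bending moment at the measurement stress (N mm).
#' @param h_ref Reference length (mm).
#' @param options A [solver_options()].
#' @param on_error `"stop"` aborts naming the failing life fraction;
#'   `"flag"` records the failure and continues.
#' @return A data frame of class `trajectory_result`, one row per record:
#'   `t`, strains, `h_C_mm`, `h_T_mm`, `rho_mm`, `alpha_C`, `alpha_T`,
#'   `force_residual`, `moment_residual`, `axis_offset_mm`,
#'   `sigma_top_MPa`, `sigma_bottom_MPa`, `solved`. Solver inputs are kept
#'   as attributes (`geom`, `E0`, `moment_M`, `h_ref`).
#' @export
analyze_trajectory <- function(traj, geom, E0, moment_M, h_ref = 6,
                               options = solver_options(),
                               on_error = c("stop", "flag")) {
  stopifnot(inherits(traj, "strain_trajectory"),
            inherits(geom, "specimen_geometry"))
  on_error <- match.arg(on_error)
  h <- geom$height_h
  n <- nrow(traj)
  out <- data.frame(
    t = traj$t, eps_C_ue = traj$eps_C_ue, eps_T_ue = traj$eps_T_ue,
    h_C_mm = NA_real_, h_T_mm = NA_real_, rho_mm = NA_real_,
    alpha_C = NA_real_, alpha_T = NA_real_,
    force_residual = NA_real_, moment_residual = NA_real_,
    axis_offset_mm = NA_real_,
    sigma_top_MPa = NA_real_, sigma_bottom_MPa = NA_real_,
    solved = FALSE)
  for (i in seq_len(n)) {
    st <- tryCatch(
      solve_alphas(traj$eps_C_ue[i], traj$eps_T_ue[i], geom, E0, moment_M,
                   h_ref, options),
      error = function(e) e)
    if (inherits(st, "error")) {
      if (on_error == "stop")
        stop(sprintf("analyze_trajectory: record at t = %g failed: %s",
                     traj$t[i], conditionMessage(st)))
      next
    }
    out$h_C_mm[i] <- st$axis$h_C
    out$h_T_mm[i] <- st$axis$h_T
    out$rho_mm[i] <- st$axis$rho
    out$alpha_C[i] <- st$model$alpha_C
    out$alpha_T[i] <- st$model$alpha_T
    out$force_residual[i] <- st$force_residual
    out$moment_residual[i] <- st$moment_residual
    out$axis_offset_mm[i] <- st$axis$h_T - h / 2
    out$sigma_top_MPa[i] <- stress_profile(st$model, st$axis, st$axis$h_C)
    out$sigma_bottom_MPa[i] <- stress_profile(st$model, st$axis, -st$axis$h_T)
    out$solved[i] <- TRUE
  }
  attr(out, "geom") <- geom
  attr(out, "E0") <- E0
  attr(out, "moment_M") <- moment_M
  attr(out, "h_ref") <- h_ref
  attr(out, "specimen_id") <- attr(traj, "specimen_id")
  class(out) <- c("trajectory_result", "data.frame")
  out
}

#' Modulus-evolution table E(y, t)
#'
#' Samples the solved modulus profile on a through-thickness grid at every
#' life fraction, in long format for plotting. Heights are measured from
#' the instantaneous neutral axis (y = 0 is always on the grid and maps to
#' exactly E0).
#'
#' @param result A [analyze_trajectory()] result.
#' @param n_y Number of grid points per side of the axis.
#' @return A data frame with columns `t`, `y_mm`, `E_MPa`.
#' @export
modulus_evolution_report <- function(result, n_y = 13L) {
  stopifnot(inherits(result, "trajectory_result"))
  h_ref <- attr(result, "h_ref")
  E0 <- attr(result, "E0")
  rows <- lapply(which(result$solved), function(i) {
    model <- gradient_modulus_model(E0, result$alpha_C[i], result$alpha_T[i],
                                    h_ref)
    y <- c(seq(-result$h_T_mm[i], 0, length.out = n_y),
           seq(0, result$h_C_mm[i], length.out = n_y)[-1])
    data.frame(t = result$t[i], y_mm = y, E_MPa = modulus_profile(model, y))
  })
  do.call(rbind, rows)
}
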