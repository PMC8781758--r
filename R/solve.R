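# Forward and inverse solvers for the bimodular gradient-beam model.
#
# The system is separable: for fixed alpha_C the force balance defines
# alpha_T implicitly through a strictly increasing 1-D equation, and the
# moment balance then closes a strictly increasing outer 1-D equation in
# alpha_C. Both are solved by safeguarded bracketing (uniroot) within the
# admissibility bounds of the logarithm domain.

#' Solver options
#'
#' @param tol_alpha Absolute x-tolerance passed to the 1-D root finders.
#' @param n_scan Number of points in the outer bracket scan.
#' @param margin Relative stand-off from the admissibility walls.
#' @return A list of class `solver_options`.
#' @export
solver_options <- function(tol_alpha = 1e-13, n_scan = 81L, margin = 1e-10) {
  structure(list(tol_alpha = tol_alpha, n_scan = as.integer(n_scan),
                 margin = margin), class = "solver_options")
}

# admissible open interval for alpha at a given side depth
.alpha_bounds <- function(depth, h_ref, margin) {
  c(lo = -(exp(1) - 1) * h_ref / depth * (1 - margin),
    hi = h_ref / depth * (1 - margin))
}

#' Invert the force and moment balance for the gradient parameters
#'
#' Given one measured surface strain pair, the neutral-axis split (h_C, h_T)
#' and curvature radius rho follow directly from the strains; the two
#' gradient parameters are then the root of the coupled force and moment
#' balance. The inner equation (force balance, alpha_T given alpha_C) and
#' the outer equation (moment balance in alpha_C) are each strictly
#' monotone, so the solution found by nested bracketing is unique.
#'
#' @param eps_C_ue Compressive surface strain magnitude (microstrain).
#' @param eps_T_ue Tensile surface strain magnitude (microstrain).
#' @param geom A [specimen_geometry()].
#' @param E0 Neutral-axis modulus (MPa), see [calibrate_E0()].
#' @param moment_M Applied bending moment (N mm) at the measurement stress.
#' @param h_ref Reference length of the logarithm (mm).
#' @param options A [solver_options()].
#' @return An object of class `solved_state`: fields `eps_C_ue`, `eps_T_ue`,
#'   `axis` (neutral-axis state), `model` (the solved
#'   [gradient_modulus_model()]), `force_residual` (mm^2) and
#'   `moment_residual` (mm^3).
#' @export
solve_alphas <- function(eps_C_ue, eps_T_ue, geom, E0, moment_M,
                         h_ref = 6, options = solver_options()) {
  stopifnot(inherits(geom, "specimen_geometry"))
  h <- geom$height_h
  axis <- neutral_axis_from_strains(eps_C_ue * 1e-6, eps_T_ue * 1e-6, h)
  hC <- axis$h_C; hT <- axis$h_T
  target <- moment_M * axis$rho / (geom$width_w * E0)

  bT <- .alpha_bounds(hT, h_ref, options$margin)
  bC <- .alpha_bounds(hC, h_ref, options$margin)

  inner <- function(aC) {
    v <- .side_kernel(aC, hC, h_ref, 1L)
    g <- function(aT) .side_kernel(aT, hT, h_ref, 1L) - v
    glo <- g(bT["lo"]); ghi <- g(bT["hi"])
    if (glo > 0 || ghi < 0) return(NA_real_)
    stats::uniroot(g, lower = bT["lo"], upper = bT["hi"],
                   f.lower = glo, f.upper = ghi,
                   tol = options$tol_alpha)$root
  }
  outer_res <- function(aC) {
    aT <- inner(aC)
    if (is.na(aT)) return(NA_real_)
    .side_kernel(aC, hC, h_ref, 2L) + .side_kernel(aT, hT, h_ref, 2L) - target
  }

  grid <- seq(bC["lo"], bC["hi"], length.out = options$n_scan)
  vals <- vapply(grid, outer_res, numeric(1))
  ok <- which(is.finite(vals))
  if (length(ok) < 2L)
    stop(sprintf(paste0(
      "solve_alphas: no admissible alpha_C found in [%.4g, %.4g] ",
      "(force balance unsatisfiable at every scanned point)"),
      bC["lo"], bC["hi"]))
  sgn <- sign(vals[ok])
  flip <- which(diff(sgn) != 0)
  if (!length(flip)) {
    # an exact zero on the grid still counts
    z <- ok[which(vals[ok] == 0)]
    if (length(z)) {
      aC <- grid[z[1]]
    } else {
      stop(sprintf(paste0(
        "solve_alphas: no sign change of the moment residual over alpha_C ",
        "in [%.4g, %.4g] (residual range [%.4g, %.4g])"),
        grid[ok[1]], grid[ok[length(ok)]], min(vals[ok]), max(vals[ok])))
    }
  } else {
    i1 <- ok[flip[1]]; i2 <- ok[flip[1] + 1L]
    aC <- stats::uniroot(outer_res, lower = grid[i1], upper = grid[i2],
                         f.lower = vals[i1], f.upper = vals[i2],
                         tol = options$tol_alpha)$root
  }
  aT <- inner(aC)
  model <- gradient_modulus_model(E0, aC, aT, h_ref)
  structure(list(
    eps_C_ue = eps_C_ue, eps_T_ue = eps_T_ue, axis = axis, model = model,
    force_residual = force_balance_residual(model, axis),
    moment_residual = moment_balance_residual(model, axis, moment_M,
                                              geom$width_w)),
    class = "solved_state")
}

#' Forward model: surface strains from known gradient parameters
#'
#' Inverse of [solve_alphas()]: for given gradients the force balance fixes
#' the neutral-axis split h_C (unique root of a strictly increasing function
#' of h_C), the moment balance then yields the curvature radius
#' rho = w E0 (AMC + AMT) / M, and the surface strains follow from
#' eps = depth / rho.
#'
#' @param alpha_C,alpha_T Gradient parameters.
#' @param E0 Neutral-axis modulus (MPa).
#' @param geom A [specimen_geometry()].
#' @param moment_M Applied bending moment (N mm).
#' @param h_ref Reference length (mm).
#' @param tol x-tolerance of the h_C root solve.
#' @return A list with `eps_C_ue`, `eps_T_ue` (microstrain), `axis` and the
#'   `model`.
#' @export
forward_strains <- function(alpha_C, alpha_T, E0, geom, moment_M,
                            h_ref = 6, tol = 1e-13) {
  stopifnot(inherits(geom, "specimen_geometry"))
  if (moment_M <= 0) stop("forward_strains: 'moment_M' must be positive")
  h <- geom$height_h
  eps <- 1e-9 * h
  lo <- max(eps, h - admissible_depth(alpha_T, h_ref) * (1 - 1e-12))
  hi <- min(h - eps, admissible_depth(alpha_C, h_ref) * (1 - 1e-12))
  if (lo >= hi)
    stop(sprintf(
      "forward_strains: no admissible neutral-axis split for alpha_C = %g, alpha_T = %g",
      alpha_C, alpha_T))
  S <- function(hC) .side_kernel(alpha_C, hC, h_ref, 1L) -
    .side_kernel(alpha_T, h - hC, h_ref, 1L)
  Slo <- S(lo); Shi <- S(hi)
  if (Slo > 0 || Shi < 0)
    stop(sprintf(
      "forward_strains: force balance has no root in h_C within (%.4g, %.4g)",
      lo, hi))
  hC <- stats::uniroot(S, lower = lo, upper = hi,
                       f.lower = Slo, f.upper = Shi, tol = tol)$root
  hT <- h - hC
  AM <- .side_kernel(alpha_C, hC, h_ref, 2L) + .side_kernel(alpha_T, hT, h_ref, 2L)
  rho <- geom$width_w * E0 * AM / moment_M
  axis <- structure(list(h_C = hC, h_T = hT, rho = rho),
                    class = "neutral_axis_state")
  list(eps_C_ue = hC / rho * 1e6, eps_T_ue = hT / rho * 1e6,
       axis = axis,
       model = gradient_modulus_model(E0, alpha_C, alpha_T, h_ref))
}
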