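# Closed-form section integrals of the graded modulus profile.
#
# Both sides reduce to the same one-sided kernel. With c = alpha / h_ref and
# x = c * d:
#   order 1:  I1(alpha, d) = int_0^d [1 - ln(1 - c y)] y   dy
#   order 2:  I2(alpha, d) = int_0^d [1 - ln(1 - c y)] y^2 dy
# Integration by parts gives
#   I1 = 3/4 d^2 + d/(2c) + (1/(2c^2) - d^2/2)   ln(1 - x)
#   I2 = 4/9 d^3 + d^2/(6c) + d/(3c^2) + (1/(3c^3) - d^3/3) ln(1 - x)
# with removable singularities at c = 0 handled by the series
#   I1 = d^2 [1/2 + sum_k x^k / (k (k+2))],
#   I2 = d^3 [1/3 + sum_k x^k / (k (k+3))].
# Substituting y -> -y on the tension side shows that the tension force
# integral over [-d, 0] equals -I1(alpha_T, d) and the tension moment
# integral equals +I2(alpha_T, d).

.side_kernel <- function(alpha, depth, h_ref, order) {
  cc <- alpha / h_ref
  x <- cc * depth
  if (abs(x) < 0.05) {
    # series branch: the closed form cancels catastrophically as c -> 0
    k <- 1:16
    if (order == 1L) depth^2 * (0.5 + sum(x^k / (k * (k + 2))))
    else depth^3 * (1 / 3 + sum(x^k / (k * (k + 3))))
  } else if (order == 1L) {
    0.75 * depth^2 + depth / (2 * cc) +
      (1 / (2 * cc^2) - depth^2 / 2) * log1p(-x)
  } else {
    (4 / 9) * depth^3 + depth^2 / (6 * cc) + depth / (3 * cc^2) +
      (1 / (3 * cc^3) - depth^3 / 3) * log1p(-x)
  }
}

#' Side integrals of the graded section (force and moment kernels)
#'
#' Closed-form first- and second-moment integrals of the dimensionless
#' modulus shape over one side of the section. Order 1 with
#' `side = "compression"` is the force-balance kernel AFC(alpha_C) =
#' int_0^hC \[1 - ln(1 - alpha_C y / h_ref)\] y dy; with `side = "tension"`
#' it is AFT(alpha_T) = int_{-hT}^0 \[1 - ln(1 + alpha_T y / h_ref)\] y dy
#' (negative). Order 2 gives the moment kernels AMC / AMT (both positive).
#'
#' @param alpha Gradient parameter of the side.
#' @param depth Side depth (mm): h_C for compression, h_T for tension.
#' @param h_ref Reference length of the logarithm (mm).
#' @param side `"compression"` or `"tension"`.
#' @param order 1 (force kernel, mm^2) or 2 (moment kernel, mm^3).
#' @return The integral value.
#' @export
side_integral <- function(alpha, depth, h_ref = 6,
                          side = c("compression", "tension"), order = 1L) {
  side <- match.arg(side)
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("side_integral: 'order' must be 1 or 2")
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0)
    stop("side_integral: 'depth' must be a positive number")
  if (depth >= admissible_depth(alpha, h_ref))
    stop(sprintf(
      "side_integral: inadmissible pair alpha = %g, depth = %g (bound %g)",
      alpha, depth, admissible_depth(alpha, h_ref)))
  v <- .side_kernel(alpha, depth, h_ref, order)
  if (side == "tension" && order == 1L) -v else v
}

#' Force-balance residual of the graded section
#'
#' Net longitudinal force per unit width and unit (E0 / rho):
#' AFC(alpha_C; h_C) + AFT(alpha_T; h_T). Zero when the section carries no
#' net axial force, i.e. at a valid neutral-axis/gradient combination.
#'
#' @param model A [gradient_modulus_model()].
#' @param axis A [neutral_axis_from_strains()] state.
#' @return Residual (mm^2); exactly zero in the mirror-symmetric case.
#' @export
force_balance_residual <- function(model, axis) {
  stopifnot(inherits(model, "gradient_modulus_model"),
            inherits(axis, "neutral_axis_state"))
  side_integral(model$alpha_C, axis$h_C, model$h_ref, "compression", 1L) +
    side_integral(model$alpha_T, axis$h_T, model$h_ref, "tension", 1L)
}

#' Moment-balance residual of the graded section
#'
#' AMC(alpha_C; h_C) + AMT(alpha_T; h_T) - M rho / (w E0). Zero when the
#' internal moment of the graded stress profile equals the applied bending
#' moment. Doubling M and E0 together leaves the residual unchanged.
#'
#' @param model A [gradient_modulus_model()].
#' @param axis A [neutral_axis_from_strains()] state.
#' @param moment_M Applied bending moment (N mm).
#' @param width_w Beam width (mm).
#' @return Residual (mm^3).
#' @export
moment_balance_residual <- function(model, axis, moment_M, width_w) {
  stopifnot(inherits(model, "gradient_modulus_model"),
            inherits(axis, "neutral_axis_state"))
  if (moment_M <= 0) stop("moment_balance_residual: 'moment_M' must be positive")
  if (width_w <= 0) stop("moment_balance_residual: 'width_w' must be positive")
  side_integral(model$alpha_C, axis$h_C, model$h_ref, "compression", 2L) +
    side_integral(model$alpha_T, axis$h_T, model$h_ref, "tension", 2L) -
    moment_M * axis$rho / (width_w * model$E0)
}
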