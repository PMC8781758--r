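#' Logarithmic gradient modulus model
#'
#' The bimodular functionally graded section model. With y measured from the
#' current neutral axis (positive toward the compression side), the modulus is
#' \deqn{E(y) = E_0 [1 - \ln(1 - \alpha_C y / h_{ref})], \quad 0 \le y \le h_C}
#' \deqn{E(y) = E_0 [1 - \ln(1 + \alpha_T y / h_{ref})], \quad -h_T \le y < 0.}
#' Both sides share the neutral-axis modulus `E0`, which is assumed constant
#' over fatigue life; the dimensionless gradients `alpha_C` and `alpha_T`
#' evolve with fatigue. Positive alpha stiffens the side away from the axis,
#' negative alpha softens it. `h_ref` is the reference length in the
#' logarithm (default 6 mm, the nominal specimen height).
#'
#' Admissibility requires the logarithm argument to stay positive and
#' E(y) > 0 over the side depth: alpha < h_ref / depth on the positive side
#' and alpha > -(e - 1) h_ref / depth on the negative side.
#'
#' @param E0 Modulus at the neutral axis (MPa).
#' @param alpha_C Compression-side gradient (dimensionless).
#' @param alpha_T Tension-side gradient (dimensionless).
#' @param h_ref Reference length in the logarithm argument (mm).
#' @return An object of class `gradient_modulus_model`.
#' @export
gradient_modulus_model <- function(E0, alpha_C = 0, alpha_T = 0, h_ref = 6) {
  if (!is.numeric(E0) || length(E0) != 1L || !is.finite(E0) || E0 <= 0)
    stop("gradient_modulus_model: 'E0' must be a positive finite number")
  if (h_ref <= 0) stop("gradient_modulus_model: 'h_ref' must be positive")
  for (nm in c("alpha_C", "alpha_T")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("gradient_modulus_model: '%s' must be a finite number", nm))
  }
  structure(list(E0 = E0, alpha_C = alpha_C, alpha_T = alpha_T, h_ref = h_ref),
            class = "gradient_modulus_model")
}

#' Maximum admissible side depth for a gradient value
#'
#' Largest depth d such that the modulus profile stays defined and positive
#' over the whole side: d < h_ref / alpha for alpha > 0 (logarithm domain),
#' d < (e - 1) h_ref / |alpha| for alpha < 0 (E > 0), unbounded at alpha = 0.
#'
#' @param alpha Gradient parameter.
#' @param h_ref Reference length (mm).
#' @return Admissible depth bound (mm), possibly `Inf`.
#' @export
admissible_depth <- function(alpha, h_ref = 6) {
  if (alpha > 0) h_ref / alpha
  else if (alpha < 0) (exp(1) - 1) * h_ref / abs(alpha)
  else Inf
}

#' Through-thickness modulus profile
#'
#' Evaluates E(y) of a [gradient_modulus_model()] at heights `y` measured
#' from the neutral axis (mm, positive toward compression). Continuous at
#' y = 0 with value exactly `E0`.
#'
#' @param model A [gradient_modulus_model()].
#' @param y Heights relative to the neutral axis (mm); vectorised.
#' @return Modulus values (MPa).
#' @export
modulus_profile <- function(model, y) {
  stopifnot(inherits(model, "gradient_modulus_model"))
  alpha <- ifelse(y >= 0, model$alpha_C, model$alpha_T)
  arg <- 1 - alpha * abs(y) / model$h_ref
  if (any(arg <= 0))
    stop("modulus_profile: logarithm argument <= 0 (inadmissible alpha/depth)")
  E <- model$E0 * (1 - log(arg))
  if (any(E <= 0))
    stop("modulus_profile: non-positive modulus (inadmissible alpha/depth)")
  E
}

#' Neutral-axis position from a surface strain pair
#'
#' Plane sections give eps = y / rho, so the measured surface strain
#' magnitudes split the height in proportion: h_C = h eps_C / (eps_C + eps_T),
#' h_T = h eps_T / (eps_C + eps_T), and the neutral-layer radius of curvature
#' is rho = h / (eps_C + eps_T).
#'
#' @param eps_C Compressive surface strain magnitude (dimensionless, > 0).
#' @param eps_T Tensile surface strain magnitude (dimensionless, > 0).
#' @param height_h Beam height h (mm).
#' @return An object of class `neutral_axis_state` with fields `h_C`, `h_T`
#'   (mm, depths of the compressed and stretched zones) and `rho` (mm).
#' @export
neutral_axis_from_strains <- function(eps_C, eps_T, height_h) {
  if (!is.numeric(eps_C) || length(eps_C) != 1L || !is.finite(eps_C) || eps_C <= 0)
    stop("neutral_axis_from_strains: 'eps_C' must be a positive number")
  if (!is.numeric(eps_T) || length(eps_T) != 1L || !is.finite(eps_T) || eps_T <= 0)
    stop("neutral_axis_from_strains: 'eps_T' must be a positive number")
  if (!is.numeric(height_h) || length(height_h) != 1L || height_h <= 0)
    stop("neutral_axis_from_strains: 'height_h' must be a positive number")
  s <- eps_C + eps_T
  structure(list(h_C = height_h * eps_C / s,
                 h_T = height_h * eps_T / s,
                 rho = height_h / s),
            class = "neutral_axis_state")
}

#' Through-thickness longitudinal stress profile
#'
#' sigma(y) = E(y) * y / rho: zero at the neutral axis, sign following y
#' (positive on the compression side in the model's coordinate).
#'
#' @param model A [gradient_modulus_model()].
#' @param axis A [neutral_axis_from_strains()] state.
#' @param y Heights relative to the neutral axis (mm); vectorised.
#' @return Stress values (MPa).
#' @export
stress_profile <- function(model, axis, y) {
  stopifnot(inherits(axis, "neutral_axis_state"))
  if (axis$rho <= 0) stop("stress_profile: 'rho' must be positive")
  modulus_profile(model, y) * y / axis$rho
}
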