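#' Four-point-bend specimen geometry
#'
#' Describes the rectangular beam cross-section and the spans of the
#' four-point-bending fixture. All lengths are in millimetres. The lever arm
#' `lever_arm_a` is the distance between an outer support and the adjacent
#' inner loading point; the outer span is `loading_span_b + 2 * lever_arm_a`.
#'
#' @param width_w Beam width w (mm).
#' @param height_h Beam height h (mm), the bent dimension.
#' @param lever_arm_a Distance a between inner and outer contact points (mm).
#' @param loading_span_b Inner span b between the loading points (mm).
#' @return An object of class `specimen_geometry`.
#' @examples
#' specimen_geometry()          # the 6 x 6 mm, a = 4, b = 34 default fixture
#' @export
specimen_geometry <- function(width_w = 6, height_h = 6,
                              lever_arm_a = 4, loading_span_b = 34) {
  args <- list(width_w = width_w, height_h = height_h,
               lever_arm_a = lever_arm_a, loading_span_b = loading_span_b)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("specimen_geometry: '%s' must be a positive finite number", nm))
  }
  structure(args, class = "specimen_geometry")
}

#' Fatigue loading protocol
#'
#' Stress levels (MPa) and cycling parameters of the fatigue test. Strain
#' images are captured at the suspended `measurement_stress`, not at the
#' fatigue peak, so the inverse model is driven by the measurement stress.
#'
#' @param fatigue_stress Peak cyclic stress (MPa).
#' @param min_stress Valley stress of the cycle (MPa).
#' @param measurement_stress Stress at which strain fields are imaged (MPa).
#' @param frequency Cycling frequency (Hz).
#' @param cycle_interval Number of cycles between strain measurements.
#' @return An object of class `loading_protocol`.
#' @export
loading_protocol <- function(fatigue_stress = 120, min_stress = 12,
                             measurement_stress = 66, frequency = 10,
                             cycle_interval = 200) {
  if (!(min_stress >= 0 && min_stress < measurement_stress &&
        measurement_stress <= fatigue_stress))
    stop("loading_protocol: need 0 <= min_stress < measurement_stress <= fatigue_stress")
  if (frequency <= 0 || cycle_interval <= 0)
    stop("loading_protocol: frequency and cycle_interval must be positive")
  structure(list(fatigue_stress = fatigue_stress, min_stress = min_stress,
                 measurement_stress = measurement_stress, frequency = frequency,
                 cycle_interval = cycle_interval), class = "loading_protocol")
}

#' Machine load for a target outer-fibre stress
#'
#' Total testing-machine force F (N) that produces nominal outer-fibre stress
#' `sigma` (MPa) in the pure-bending span of a homogeneous beam:
#' F = sigma * w * h^2 / (3 a).
#'
#' @param sigma Nominal outer-fibre stress (MPa).
#' @param geom A [specimen_geometry()].
#' @return Total applied load F (N); each inner contact carries F/2.
#' @export
four_point_load <- function(sigma, geom) {
  stopifnot(inherits(geom, "specimen_geometry"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("four_point_load: 'sigma' must be a positive number")
  sigma * geom$width_w * geom$height_h^2 / (3 * geom$lever_arm_a)
}

#' Bending moment in the inner span for a target outer-fibre stress
#'
#' The pure-bending moment between the inner contacts, M = (F/2) * a =
#' sigma * w * h^2 / 6 (N mm). The lever arm cancels: M depends only on the
#' stress and the cross-section.
#'
#' @inheritParams four_point_load
#' @return Bending moment M (N mm).
#' @export
bending_moment_from_stress <- function(sigma, geom) {
  stopifnot(inherits(geom, "specimen_geometry"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("bending_moment_from_stress: 'sigma' must be a positive number")
  sigma * geom$width_w * geom$height_h^2 / 6
}

#' Calibrate the neutral-axis modulus E0
#'
#' The gradient model anchors the modulus at the neutral axis, `E0`, which is
#' held constant over fatigue life. Mode `"homogeneous_initial"` chooses the
#' homogeneous-beam value that makes the pre-fatigue strain sum exact with
#' zero gradients: E0 = 2 * sigma_meas / (eps_C0 + eps_T0), strains supplied
#' in microstrain. Mode `"fixed"` returns a user-supplied value.
#'
#' @param eps_C0_ue Initial compressive surface strain magnitude (microstrain).
#' @param eps_T0_ue Initial tensile surface strain magnitude (microstrain).
#' @param sigma_meas Measurement stress (MPa).
#' @param mode `"homogeneous_initial"` or `"fixed"`.
#' @param value Modulus (MPa) used when `mode = "fixed"`.
#' @return Modulus E0 in MPa.
#' @export
calibrate_E0 <- function(eps_C0_ue, eps_T0_ue, sigma_meas,
                         mode = c("homogeneous_initial", "fixed"),
                         value = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(value) || !is.numeric(value) || value <= 0)
      stop("calibrate_E0: mode 'fixed' needs a positive 'value'")
    return(as.numeric(value))
  }
  if (eps_C0_ue <= 0 || eps_T0_ue <= 0)
    stop("calibrate_E0: initial strains must be positive")
  s <- (eps_C0_ue + eps_T0_ue) * 1e-6
  if (s == 0) stop("calibrate_E0: zero strain sum")
  2 * sigma_meas / s
}
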