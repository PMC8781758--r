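# End-to-end pipeline: simulate or ingest a strain trajectory, invert the
# gradient model along it, fit the strain evolution, tabulate the modulus
# surface and cross-check the neutral axis with the finite-element model.

#' Default pipeline configuration
#'
#' Nested list mirroring the config file schema. Units: mm, MPa, N mm,
#' microstrain.
#'
#' @return A named list with sections `geometry`, `loading`, `model`,
#'   `solver`, `generator`, `fem`, plus `input_csv`, `output_dir`, `seed`.
#' @export
default_config <- function() {
  list(
    geometry = list(width_w = 6, height_h = 6, lever_arm_a = 4,
                    loading_span_b = 34),
    loading = list(fatigue_stress = 120, min_stress = 12,
                   measurement_stress = 66, frequency = 10,
                   cycle_interval = 200),
    model = list(h_ref = 6, E0_mode = "homogeneous_initial", E0_value = NULL),
    solver = list(tol_alpha = 1e-13, n_scan = 81, margin = 1e-10),
    generator = list(eps_C0 = 2819, eps_T0 = 2807, breakpoint_t = 0.28,
                     phase1_rise = 400, phase2_rise = 150,
                     tensile_total_rise_frac = 0.04, n_points = 11,
                     noise_sd = 20),
    fem = list(enabled = TRUE, nx = 126, ny = 24, nu = 0.3),
    input_csv = NULL,
    output_dir = "results",
    seed = 1L)
}

.merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(base))
      stop(sprintf("config: unknown key '%s%s'", path, nm))
    if (is.list(base[[nm]]) && !is.null(user[[nm]])) {
      if (!is.list(user[[nm]]))
        stop(sprintf("config: '%s%s' must be a section", path, nm))
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]],
                                  paste0(path, nm, "."))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read and validate a pipeline configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`); unknown keys are rejected,
#' missing keys take the [default_config()] values.
#'
#' @param path Config file path.
#' @return A validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_run_config: no such file '%s'", path))
  ext <- tolower(sub(".*\\.", "", basename(path)))
  user <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
          else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
          else stop("read_run_config: expected a .yaml/.yml or .json file")
  .merge_config(default_config(), user)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) obtain a trajectory — read `input_csv` if configured,
#' otherwise generate a synthetic one with the configured seed; (2)
#' calibrate E0 and invert the gradient model at every life fraction; (3)
#' fit the two-segment compressive and linear tensile strain evolutions;
#' (4) tabulate the modulus surface E(y, t); (5) cross-check the
#' neutral-axis trajectory against the finite-element model (if enabled).
#' All artifacts plus a run manifest are written to `output_dir`.
#'
#' @param config A config list ([default_config()] shape) or path to a
#'   config file.
#' @param output_dir Optional override of `config$output_dir`.
#' @return Invisibly, a list: `trajectory`, `result`, `fits`, `modulus`,
#'   `fem_comparison` (or NULL), `paths`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- .merge_config(default_config(), config)
  out <- if (is.null(output_dir)) config$output_dir else output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  geom <- do.call(specimen_geometry, config$geometry)
  loading <- do.call(loading_protocol, config$loading)

  if (!is.null(config$input_csv)) {
    traj <- read_trajectory_csv(config$input_csv)
    if (is.list(traj) && !inherits(traj, "strain_trajectory"))
      traj <- average_trajectories(traj)
  } else {
    gp <- config$generator
    params <- trajectory_generator_params(
      eps_C0 = gp$eps_C0, eps_T0 = gp$eps_T0, breakpoint_t = gp$breakpoint_t,
      phase1_rise = gp$phase1_rise, phase2_rise = gp$phase2_rise,
      tensile_total_rise_frac = gp$tensile_total_rise_frac,
      n_points = gp$n_points, noise_sd = gp$noise_sd, seed = config$seed)
    traj <- generate_trajectory(params)
  }

  E0 <- calibrate_E0(traj$eps_C_ue[1], traj$eps_T_ue[1],
                     loading$measurement_stress,
                     mode = config$model$E0_mode,
                     value = config$model$E0_value)
  moment_M <- bending_moment_from_stress(loading$measurement_stress, geom)
  opts <- solver_options(tol_alpha = config$solver$tol_alpha,
                         n_scan = config$solver$n_scan,
                         margin = config$solver$margin)
  result <- analyze_trajectory(traj, geom, E0, moment_M,
                               h_ref = config$model$h_ref, options = opts)

  seg <- fit_two_segments(result$t, result$eps_C_ue)
  lin <- fit_linear(result$t, result$eps_T_ue)
  fits <- list(
    compressive = list(breakpoint_t = seg$breakpoint_t,
                       slope_1 = seg$slope_1, intercept_1 = seg$intercept_1,
                       slope_2 = seg$slope_2, intercept_2 = seg$intercept_2,
                       r_squared = seg$r_squared),
    tensile = list(slope = lin$slope, intercept = lin$intercept,
                   r_squared = lin$r_squared))

  modulus <- modulus_evolution_report(result)

  fem_cmp <- NULL
  if (isTRUE(config$fem$enabled))
    fem_cmp <- compare_fem_analytical(result, nx = config$fem$nx,
                                      ny = config$fem$ny, nu = config$fem$nu)

  paths <- list(
    trajectory = file.path(out, "trajectory.csv"),
    solved = file.path(out, "solved_states.csv"),
    fits = file.path(out, "fits.json"),
    modulus = file.path(out, "modulus_evolution.csv"),
    manifest = file.path(out, "manifest.json"))
  write_trajectory_csv(traj, paths$trajectory)
  write_solved_csv(result, paths$solved)
  write_fits_json(fits, paths$fits)
  write_table_csv(modulus, paths$modulus)
  if (!is.null(fem_cmp)) {
    paths$fem_comparison <- file.path(out, "fem_comparison.csv")
    write_table_csv(fem_cmp, paths$fem_comparison)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("bimodbeam")),
    config = config,
    seed = config$seed,
    E0_MPa = E0,
    moment_Nmm = moment_M,
    n_records = nrow(result),
    n_solved = sum(result$solved),
    max_abs_force_residual = max(abs(result$force_residual), na.rm = TRUE),
    max_abs_moment_residual = max(abs(result$moment_residual), na.rm = TRUE),
    max_abs_fem_deviation_pct = if (is.null(fem_cmp)) NULL
                                else max(abs(fem_cmp$deviation_pct)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  invisible(list(trajectory = traj, result = result, fits = fits,
                 modulus = modulus, fem_comparison = fem_cmp,
                 paths = paths, manifest = manifest))
}
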