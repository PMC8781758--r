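# Validated readers and writers for the package's CSV dialects.
# Dialect: comma-delimited, '.' decimal, UTF-8, '#' comment lines, header
# required. Writers emit full double precision so a write/read round trip
# is lossless to better than 1e-12 relative.

.write_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num],
                    function(x) trimws(formatC(x, digits = 17, format = "g")))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a strain-trajectory CSV
#'
#' Expects columns `specimen_id`, `t`, `eps_C_ue`, `eps_T_ue` (comma
#' delimited, `#` comments allowed). Life fractions must already be strictly
#' increasing per specimen — unsorted input is an error, never silently
#' sorted.
#'
#' @param path CSV file path.
#' @return A [strain_trajectory()], or a named list of them when the file
#'   holds several specimens.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_trajectory_csv: no such file '%s'", path))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("specimen_id", "t", "eps_C_ue", "eps_T_ue")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("read_trajectory_csv: missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (nrow(df) == 0L) stop("read_trajectory_csv: empty data section")
  for (nm in c("t", "eps_C_ue", "eps_T_ue")) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("read_trajectory_csv: non-numeric '%s' at data row %d",
                   nm, bad[1]))
    df[[nm]] <- v
  }
  out <- lapply(split(df, df$specimen_id), function(d) {
    bad <- which(diff(d$t) <= 0)
    if (length(bad))
      stop(sprintf(
        "read_trajectory_csv: life fractions not strictly increasing for '%s' at data row %d",
        d$specimen_id[1], bad[1] + 1L))
    strain_trajectory(d$t, d$eps_C_ue, d$eps_T_ue, specimen_id = d$specimen_id[1])
  })
  if (length(out) == 1L) out[[1]] else out
}

#' Write a strain trajectory to CSV
#'
#' @param traj A [strain_trajectory()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "strain_trajectory"))
  df <- data.frame(specimen_id = attr(traj, "specimen_id"),
                   t = traj$t, eps_C_ue = traj$eps_C_ue,
                   eps_T_ue = traj$eps_T_ue)
  .write_csv(df, path)
}

#' Write a solved-state table to CSV
#'
#' One row per life fraction: strains, neutral-axis state, gradients and
#' balance residuals.
#'
#' @param result An [analyze_trajectory()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_solved_csv <- function(result, path) {
  stopifnot(inherits(result, "trajectory_result"))
  cols <- c("t", "eps_C_ue", "eps_T_ue", "h_C_mm", "h_T_mm", "rho_mm",
            "alpha_C", "alpha_T", "force_residual", "moment_residual")
  .write_csv(as.data.frame(result)[cols], path)
}

#' Write a plain data frame in the package CSV dialect
#'
#' @param df A data frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_table_csv <- function(df, path) .write_csv(df, path)

#' Write segmented/linear fit results as JSON
#'
#' @param fits A named list (e.g. the `fits` element of [run_pipeline()]).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  jsonlite::write_json(fits, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
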