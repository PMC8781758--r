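#' Ordinary least-squares line fit
#'
#' Simple linear regression y ~ t with r^2 = 1 - SSE/SST. When y is exactly
#' constant (SST = 0) the fit is degenerate: r^2 is reported as 1 with
#' `degenerate = TRUE`.
#'
#' @param t Predictor (>= 3 points, non-constant).
#' @param y Response.
#' @return A list: `slope`, `intercept`, `r_squared`, `sse`, `degenerate`.
#' @export
fit_linear <- function(t, y) {
  n <- length(t)
  if (n < 3L) stop("fit_linear: need at least 3 points")
  if (length(y) != n) stop("fit_linear: lengths differ")
  if (stats::var(t) == 0) stop("fit_linear: degenerate design, 't' is constant")
  fit <- stats::lm.fit(cbind(1, t), y)
  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r_squared = if (sst == 0) 1 else 1 - sse / sst,
       sse = sse,
       degenerate = sst == 0)
}

#' Two-segment (breakpoint) linear fit
#'
#' Fits two independent least-squares lines to `(t, y)` split at an interior
#' partition, choosing the partition that minimises the pooled residual sum
#' of squares. Every interior gap with at least two points on each side is a
#' candidate. The reported breakpoint is refined within the selected gap as
#' the intersection of the two fitted lines (clamped to the gap; the gap
#' midpoint if the lines are parallel), so a kink lying between observations
#' is still recovered exactly from noiseless data.
#'
#' The pooled r^2 uses one total sum of squares about the global mean:
#' r^2 = 1 - (SSE1 + SSE2)/SST.
#'
#' @param t Life fractions, strictly increasing (>= 5 points).
#' @param y Strain series.
#' @return A list of class `segmented_fit`: `breakpoint_t`, `slope_1`,
#'   `intercept_1`, `slope_2`, `intercept_2`, `r_squared`, `sse`,
#'   `partition_index` (last point of segment 1).
#' @export
fit_two_segments <- function(t, y) {
  n <- length(t)
  if (n < 5L) stop("fit_two_segments: need at least 5 points")
  if (length(y) != n) stop("fit_two_segments: lengths differ")
  if (any(diff(t) <= 0)) stop("fit_two_segments: 't' must be strictly increasing")
  best <- NULL
  for (k in 2:(n - 2L)) {
    f1 <- tryCatch(fit_linear(t[1:k], y[1:k]), error = function(e) NULL)
    f2 <- tryCatch(fit_linear(t[(k + 1L):n], y[(k + 1L):n]),
                   error = function(e) NULL)
    if (is.null(f1) || is.null(f2)) next  # degenerate candidate: skip
    sse <- f1$sse + f2$sse
    if (is.null(best) || sse < best$sse) best <- list(k = k, f1 = f1, f2 = f2, sse = sse)
  }
  if (is.null(best)) stop("fit_two_segments: no admissible partition")
  k <- best$k
  dslope <- best$f2$slope - best$f1$slope
  scale <- abs(best$f1$slope) + abs(best$f2$slope) + 1
  bp <- if (abs(dslope) < 1e-10 * scale) (t[k] + t[k + 1L]) / 2
        else (best$f1$intercept - best$f2$intercept) / dslope
  bp <- min(max(bp, t[k]), t[k + 1L])
  sst <- sum((y - mean(y))^2)
  structure(list(
    breakpoint_t = bp,
    slope_1 = best$f1$slope, intercept_1 = best$f1$intercept,
    slope_2 = best$f2$slope, intercept_2 = best$f2$intercept,
    r_squared = if (sst == 0) 1 else 1 - best$sse / sst,
    sse = best$sse,
    partition_index = k), class = "segmented_fit")
}
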