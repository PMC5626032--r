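#' Min-max scale an RFU trace
#'
#' Scales a fluorescence trace to `(rfu - min(rfu)) / (max(rfu) - min(rfu))`
#' so the initial even suspension reads 1 and the final plateau, once all
#' cells have reached the well bottom, reads 0. Scaling removes well-to-well
#' differences in starting cell density; the bounds used are recorded so the
#' transform is invertible. Bounds are the global min/max of the observed
#' trace. When the minimum occurs before the last 10% of reads the trace has
#' not visibly plateaued at its end; the returned `min_in_tail` attribute is
#' `FALSE` then, and downstream results carry the flag.
#'
#' @param times Elapsed minutes (same length as `rfu`).
#' @param rfu Raw RFU values; at least 4 finite values, not all equal.
#' @return A tibble of class `scaled_trace` with columns `time_min` and
#'   `scaled`, and attributes `rfu_min`, `rfu_max`, `min_in_tail`.
#' @examples
#' scale_rfu(c(0, 10, 20), c(10, 6, 2))
#' @export
scale_rfu <- function(times, rfu) {
  keep <- is.finite(rfu) & is.finite(times)
  times <- times[keep]
  rfu <- rfu[keep]
  if (length(rfu) < 3L) abort("Need at least 3 finite RFU values to scale.")
  rmin <- min(rfu)
  rmax <- max(rfu)
  if (rmax <= rmin) {
    abort("no fluorescence decline detected (constant RFU trace)")
  }
  scaled <- (rfu - rmin) / (rmax - rmin)
  tail_start <- stats::quantile(times, 0.9, names = FALSE)
  structure(
    tibble::tibble(time_min = times, scaled = scaled),
    class = c("scaled_trace", class(tibble::tibble())),
    rfu_min = rmin,
    rfu_max = rmax,
    min_in_tail = times[which.min(rfu)] >= tail_start
  )
}

#' Depth transform of a scaled trace
#'
#' The inverse-square emission model gives scaled RFU = 1/(1 + d)^2 with d
#' the distance sunk in units of the culture depth; taking the square root
#' and multiplying by the depth yields a signal in mm that declines linearly
#' in time at the (depth-scaled) sinking rate, with intercept equal to the
#' culture depth.
#'
#' @param scaled Scaled values in `[0, 1]` (a numeric vector or a
#'   `scaled_trace` from [scale_rfu()]).
#' @param depth_mm Culture depth in mm (default 3.8).
#' @return Numeric vector `sqrt(scaled) * depth_mm`, in mm.
#' @examples
#' depth_transform(c(1, 0.25, 0), 3.8)
#' @export
depth_transform <- function(scaled, depth_mm = 3.8) {
  if (inherits(scaled, "scaled_trace")) scaled <- scaled$scaled
  if (any(scaled < 0, na.rm = TRUE)) {
    abort("Scaled values must be nonnegative.")
  }
  if (depth_mm <= 0) abort("`depth_mm` must be positive.")
  sqrt(scaled) * depth_mm
}

#' Forward inverse-square sinking model
#'
#' The generative counterpart of the fitting model: a homogeneous population
#' sinking at scaled rate `s` (per minute, in units of the culture depth)
#' produces scaled RFU `1 / (1 + t s)^2` at elapsed time `t`. Its square
#' root, `1 / (1 + t s)`, linearizes to `1 - t s` for small `t s`.
#'
#' @param t_min Elapsed time in minutes (`>= 0`), vectorized.
#' @param s_per_min Scaled sinking rate per minute (`>= 0`).
#' @return Scaled RFU values in `(0, 1]`.
#' @examples
#' forward_scaled(10, 0.01)  # 1 / 1.1^2
#' @export
forward_scaled <- function(t_min, s_per_min) {
  if (any(t_min < 0)) abort("`t_min` must be nonnegative.")
  if (any(s_per_min < 0)) abort("`s_per_min` must be nonnegative.")
  1 / (1 + t_min * s_per_min)^2
}

#' Convert a fitted decline slope to a sinking rate
#'
#' The fitted slope of the depth signal (mm min\eqn{^{-1}}) is the distance
#' sunk per minute; multiplying by 1440 min d\eqn{^{-1}} and dividing by
#' 1000 mm m\eqn{^{-1}} gives m d\eqn{^{-1}}. When the slope comes from a
#' fit of the dimensionless scaled signal instead, pass the culture depth so
#' the slope is first converted to mm min\eqn{^{-1}}.
#'
#' @param slope Magnitude of the fitted decline per minute (`>= 0`): in
#'   mm min\eqn{^{-1}} when `depth_mm = 1` (the default, for fits performed
#'   on the depth signal), or dimensionless per minute otherwise.
#' @param depth_mm Culture depth in mm; the multiplier applied to a
#'   dimensionless slope. Default 1 (slope already in mm).
#' @return Sinking rate in m d\eqn{^{-1}}.
#' @examples
#' slope_to_rate(1)                # 1.44 m/d
#' slope_to_rate(0.01, depth_mm = 3.8)
#' @export
slope_to_rate <- function(slope, depth_mm = 1) {
  if (any(slope < 0)) {
    abort("`slope` must be a nonnegative magnitude; take abs() of a decline.")
  }
  if (depth_mm <= 0) abort("`depth_mm` must be positive.")
  slope * depth_mm * MIN_PER_DAY_OVER_MM_PER_M
}

#' Stokes settling velocity
#'
#' Reference utility for the theoretical settling velocity of a small
#' particle, `v_s = 2 g r^2 (rho_particle - rho_water) / (9 eta phi)`.
#' Negative values mean positive buoyancy (the particle floats). This is
#' informational — useful for choosing realistic simulation rates — and is
#' never used in rate estimation from traces.
#'
#' @param r Particle radius, m.
#' @param rho_particle Particle density, kg m\eqn{^{-3}}.
#' @param rho_water Water density, kg m\eqn{^{-3}}.
#' @param eta Dynamic viscosity, kg m\eqn{^{-1}} s\eqn{^{-1}}.
#' @param phi Form resistance (dimensionless, 1 for a sphere; > 1 means the
#'   particle sinks slower than the equal-volume sphere).
#' @param g Gravitational acceleration, m s\eqn{^{-2}}.
#' @return Settling velocity in m s\eqn{^{-1}}.
#' @examples
#' stokes_velocity(r = 5e-6, rho_particle = 1125, rho_water = 1025,
#'                 eta = 1e-3)
#' @export
stokes_velocity <- function(r, rho_particle, rho_water, eta, phi = 1,
                            g = 9.8) {
  if (any(r <= 0)) abort("`r` must be positive.")
  if (any(eta <= 0)) abort("`eta` must be positive.")
  if (any(phi <= 0)) abort("`phi` must be positive.")
  2 * g * r^2 * (rho_particle - rho_water) / (9 * eta * phi)
}
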