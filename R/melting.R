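#' Construct a melting curve
#'
#' A melting test records the cumulative dripped mass and the sample core
#' temperature at a fixed cadence (typically every 10 s) while a frozen
#' sample thaws at room temperature on a mesh above a balance.
#'
#' @param time_s time in seconds, strictly increasing.
#' @param drip_mass_g cumulative dripped mass in g, non-decreasing.
#' @param core_temp_C sample core temperature in degC.
#' @param initial_mass_g initial frozen sample mass in g.
#' @return A data.frame of class `melting_curve` with an `initial_mass_g`
#'   attribute.
#' @export
melting_curve <- function(time_s, drip_mass_g, core_temp_C, initial_mass_g) {
  if (any(diff(time_s) <= 0))
    validation_error("time must be strictly increasing")
  if (length(drip_mass_g) != length(time_s) ||
      length(core_temp_C) != length(time_s))
    validation_error("time, drip mass and core temperature must have equal length")
  if (any(diff(drip_mass_g) < 0))
    validation_error("cumulative drip mass must be non-decreasing")
  if (!is.numeric(initial_mass_g) || initial_mass_g <= 0)
    validation_error("initial_mass_g must be positive")
  if (any(drip_mass_g < 0) || any(drip_mass_g > initial_mass_g * 1.05))
    validation_error("drip mass must lie in [0, initial mass] (5 % tolerance)")
  structure(
    data.frame(time_s = time_s, drip_mass_g = drip_mass_g,
               core_temp_C = core_temp_C),
    class = c("melting_curve", "data.frame"),
    initial_mass_g = initial_mass_g
  )
}

# Linearly interpolated first upward crossing time of `y` through `level`.
# Returns the continuous time at which the series first reaches `level`.
first_crossing_time <- function(t, y, level) {
  k <- which(y >= level)[1]
  if (is.na(k)) return(NA_real_)
  if (k == 1L || y[k] == y[k - 1L]) return(t[k])
  t[k - 1L] + (t[k] - t[k - 1L]) * (level - y[k - 1L]) / (y[k] - y[k - 1L])
}

#' Extract the five melting parameters from a melting curve
#'
#' Derives the standard descriptors of a thaw test:
#' \describe{
#'   \item{lag_time_min}{time until the first droplet drips down. The
#'     cumulative drip mass first reaches the drop threshold a delay of
#'     `threshold / drip slope` after melt onset, so the estimate is the
#'     linearly interpolated threshold-crossing time minus that delay
#'     (using the fitted fast-phase slope); this debiases the estimate at
#'     slow drip rates.}
#'   \item{total_melting_time_min}{time until the last droplet — the
#'     (interpolated) time at which the drip mass first reaches
#'     `(1 - end_fraction)` of its final value.}
#'   \item{melting_rate_pct_per_min}{slope of the fast melting phase:
#'     ordinary least squares of drip mass (% of initial mass) vs. time
#'     over the samples between `band[1]` and `band[2]` of the final
#'     dripped mass.}
#'   \item{onset_temp_C}{core temperature of the first drop: linearly
#'     interpolated at the observed threshold-crossing time.}
#'   \item{temp_rate_C_per_min}{(core temperature at the total melting
#'     time minus at t = 0) divided by the total melting time.}
#' }
#'
#' @param curve a [melting_curve()].
#' @param drop_threshold_g drip mass that counts as the first droplet
#'   (default 0.5 g).
#' @param band fast-phase bounds as fractions of the final dripped mass
#'   (default `c(0.2, 0.8)`).
#' @param end_fraction fraction of the final mass still to drip when the
#'   melt is declared finished (default 0.005).
#' @return A list of class `melting_parameters` with the five fields above.
#' @export
extract_melting_parameters <- function(curve, drop_threshold_g = 0.5,
                                       band = c(0.2, 0.8),
                                       end_fraction = 0.005) {
  if (!inherits(curve, "melting_curve"))
    validation_error("expected a melting_curve")
  final <- curve$drip_mass_g[nrow(curve)]
  if (final <= drop_threshold_g)
    validation_error("no melt detected: final drip mass at or below the drop threshold")
  t_min <- curve$time_s / 60
  t_cross <- first_crossing_time(t_min, curve$drip_mass_g, drop_threshold_g)
  total <- first_crossing_time(t_min, curve$drip_mass_g,
                               (1 - end_fraction) * final)
  in_band <- curve$drip_mass_g >= band[1] * final &
    curve$drip_mass_g <= band[2] * final
  if (sum(in_band) < 3L)
    validation_error("fewer than 3 samples in the fast-melting band")
  pct <- 100 * curve$drip_mass_g[in_band] / attr(curve, "initial_mass_g")
  fit <- stats::lm.fit(cbind(1, t_min[in_band]), pct)
  slope_g_min <- fit$coefficients[2] / 100 * attr(curve, "initial_mass_g")
  lag <- if (slope_g_min > 0)
    max(t_cross - drop_threshold_g / slope_g_min, t_min[1]) else t_cross
  # the first drop is observed at the threshold crossing; read its
  # temperature there (by then the core sits on the melting plateau)
  onset <- stats::approx(t_min, curve$core_temp_C, xout = t_cross, rule = 2)$y
  temp_at_total <- stats::approx(t_min, curve$core_temp_C, xout = total,
                                 rule = 2)$y
  structure(
    list(total_melting_time_min = total,
         lag_time_min = lag,
         melting_rate_pct_per_min = unname(fit$coefficients[2]),
         onset_temp_C = onset,
         temp_rate_C_per_min = (temp_at_total - curve$core_temp_C[1]) / total),
    class = "melting_parameters"
  )
}

#' @export
print.melting_parameters <- function(x, ...) {
  cat("Melting parameters:\n")
  cat(sprintf("  lag time            %.2f min\n", x$lag_time_min))
  cat(sprintf("  total melting time  %.2f min\n", x$total_melting_time_min))
  cat(sprintf("  melting rate        %.3f %%/min\n", x$melting_rate_pct_per_min))
  cat(sprintf("  onset temperature   %.2f degC\n", x$onset_temp_C))
  cat(sprintf("  temperature rate    %.3f degC/min\n", x$temp_rate_C_per_min))
  invisible(x)
}

#' Construct a penetration trace
#'
#' Force-displacement record of a cylindrical probe penetrating a frozen
#' sample in a texture analyser.
#'
#' @param displacement_mm probe displacement in mm.
#' @param force_N measured force in N.
#' @param probe_diameter_mm probe diameter in mm (default 4).
#' @return A data.frame of class `penetration_trace`.
#' @export
penetration_trace <- function(displacement_mm, force_N,
                              probe_diameter_mm = 4) {
  if (!length(force_N)) validation_error("penetration trace is empty")
  if (length(displacement_mm) != length(force_N))
    validation_error("displacement and force must have equal length")
  if (!is.numeric(probe_diameter_mm) || probe_diameter_mm <= 0)
    validation_error("probe_diameter_mm must be positive")
  structure(
    data.frame(displacement_mm = displacement_mm, force_N = force_N),
    class = c("penetration_trace", "data.frame"),
    probe_diameter_mm = probe_diameter_mm
  )
}

#' Hardness from a penetration trace
#'
#' The hardness of a frozen sample is the stress at the first force peak
#' during penetration: the force at the first local maximum (detected on a
#' 3-point moving average of the force) divided by the probe tip area.
#' With force in N and the probe diameter in mm the stress is directly in
#' MPa (N/mm^2). A monotone trace with no interior peak returns the global
#' maximum stress with a warning.
#'
#' @param trace a [penetration_trace()].
#' @return Hardness in MPa.
#' @examples
#' tr <- penetration_trace(0:10, c(0:5 * 2, 8, 6, 4, 2, 0))
#' hardness_from_penetration(tr) # 10 N on a 4-mm probe -> 0.796 MPa
#' @export
hardness_from_penetration <- function(trace) {
  if (!inherits(trace, "penetration_trace"))
    validation_error("expected a penetration_trace")
  f <- trace$force_N
  area_mm2 <- pi * (attr(trace, "probe_diameter_mm") / 2)^2
  n <- length(f)
  peak_force <- NA_real_
  if (n >= 3L) {
    sm <- stats::filter(f, rep(1 / 3, 3), sides = 2)
    for (i in 2:(n - 1L)) {
      if (anyNA(sm[(i - 1L):(i + 1L)])) next
      if (sm[i] > sm[i - 1L] && sm[i] > sm[i + 1L]) {
        peak_force <- f[i]
        break
      }
    }
  }
  if (is.na(peak_force)) {
    warning("no interior force peak found; using the global maximum",
            call. = FALSE)
    peak_force <- max(f)
  }
  peak_force / area_mm2
}

#' Coefficient of determination of a straight-line fit
#'
#' R-squared of the ordinary least-squares regression `y ~ x`.
#'
#' @param x,y numeric vectors of equal length, n >= 3; `x` must vary.
#' @return R-squared in [0, 1].
#' @export
linear_fit_r2 <- function(x, y) {
  if (length(x) < 3L || length(x) != length(y))
    validation_error("need at least 3 (x, y) pairs of equal length")
  if (stats::var(x) == 0)
    validation_error("x is degenerate (zero variance)")
  fit <- stats::lm(y ~ x)
  1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}
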