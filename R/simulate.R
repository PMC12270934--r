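#' Generator configuration
#'
#' Collects the knobs shared by the synthetic-data generators. Defaults
#' reflect instrument-level repeatability of the emulated measurements:
#' 1 % absolute noise on DSC-derived ice contents (the magnitude of the
#' replicate standard deviations typically reported for such data), three
#' replicates, a 10 s logging cadence for melting tests, 0.05 g balance
#' noise and 0.05 degC thermocouple noise.
#'
#' @param seed integer seed; every generator call is fully reproducible
#'   given the seed.
#' @param noise_sd_ice s.d. of the ice-content noise, % absolute.
#' @param replicates replicate count per cell (>= 1).
#' @param sampling_interval_s melting-test logging cadence, s.
#' @param noise_sd_mass s.d. of the drip-mass noise, g.
#' @param noise_sd_temp s.d. of the core-temperature noise, degC.
#' @param noise_sd_heatflow s.d. of the DSC heat-flow noise, W/g.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, noise_sd_ice = 1, replicates = 3L,
                             sampling_interval_s = 10,
                             noise_sd_mass = 0.05, noise_sd_temp = 0.05,
                             noise_sd_heatflow = 1e-4) {
  cfg <- list(seed = as.integer(seed), noise_sd_ice = noise_sd_ice,
              replicates = as.integer(replicates),
              sampling_interval_s = sampling_interval_s,
              noise_sd_mass = noise_sd_mass, noise_sd_temp = noise_sd_temp,
              noise_sd_heatflow = noise_sd_heatflow)
  if (cfg$replicates < 1L) validation_error("replicates must be >= 1")
  noise <- unlist(cfg[grep("^noise_sd", names(cfg))])
  if (any(!is.finite(noise)) || any(noise < 0))
    validation_error("noise parameters must be finite and >= 0")
  if (cfg$sampling_interval_s <= 0)
    validation_error("sampling_interval_s must be positive")
  class(cfg) <- "generator_config"
  cfg
}

# Resolve an h specification to a function of (concentration_pct, temp_C).
resolve_h_surface <- function(h_surface) {
  if (is.function(h_surface)) return(h_surface)
  if (inherits(h_surface, "hydration_table")) {
    tab <- h_surface
    return(function(conc, temp, solute)
      hydration_lookup(tab, solute, conc, temp, extrapolate = TRUE))
  }
  if (is.numeric(h_surface) && length(h_surface) == 1L)
    return(function(conc, temp, ...) h_surface)
  validation_error("h_surface must be a constant, a function(c, T) or a hydration_table")
}

#' Generate a synthetic ice-content dataset
#'
#' Emulates DSC-derived ice-content tables: for every requested
#' (solute, concentration, temperature) cell the ground-truth ice content
#' is evaluated from the forward model with the hydration number supplied
#' by `h_surface`, Gaussian noise of s.d. `cfg$noise_sd_ice` is added per
#' replicate, and the result is clamped to [0, 100]. Cells whose
#' temperature lies above the sample's melting point are emitted with zero
#' ice and the flag `"above_melting"`.
#'
#' @param solutes character vector of registry names.
#' @param concentrations list mapping each solute to its concentration
#'   vector (% w/w), or a single numeric vector applied to all solutes.
#' @param temperatures temperatures, degC.
#' @param h_surface hydration-number specification: a single number, a
#'   `function(concentration_pct, temperature_C, solute)` or a
#'   [hydration_table()].
#' @param cfg a [generator_config()].
#' @param registry solute registry.
#' @param constants see [thermo_constants()].
#' @return An ice-content dataset data.frame with columns `solute`,
#'   `concentration_pct`, `temperature_C`, `replicate`, `ice_pct`, `flag`.
#' @export
generate_ice_dataset <- function(solutes, concentrations, temperatures,
                                 h_surface, cfg = generator_config(),
                                 registry = default_registry(),
                                 constants = thermo_constants()) {
  hfun <- resolve_h_surface(h_surface)
  if (!is.list(concentrations))
    concentrations <- stats::setNames(
      rep(list(concentrations), length(solutes)), solutes)
  set.seed(cfg$seed)
  rows <- list()
  for (s in solutes) {
    for (conc in concentrations[[s]]) {
      comp <- solution(s, conc, registry = registry)
      for (temp in temperatures) {
        h <- hfun(conc, temp, s)
        pt <- ice_content(comp, h, temp, constants)
        for (r in seq_len(cfg$replicates)) {
          ice <- if (pt$valid)
            min(100, max(0, pt$ice_pct + stats::rnorm(1, 0, cfg$noise_sd_ice)))
          else 0
          rows[[length(rows) + 1L]] <- data.frame(
            solute = s, concentration_pct = conc, temperature_C = temp,
            replicate = r, ice_pct = ice,
            flag = if (pt$valid) "" else "above_melting")
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic melting curve
#'
#' Emulates a thaw test with the classic lag / fast-phase / plateau shape:
#' no drip until `lag_min`, then a linear rise at `rate_pct_per_min` (% of
#' the initial mass per minute) until the melted mass
#' `rate * initial_mass / 100 * (total - lag)` is reached at
#' `total_time_min`, then a plateau. The core temperature climbs linearly
#' from `temp_start_C` to the melting plateau `temp_plateau_C` during the
#' lag, holds there while the sample melts, then rises to `temp_end_C`.
#' Gaussian noise is added to both channels and the cumulative drip mass
#' is forced non-decreasing afterwards.
#'
#' When `total_time_min` is `NULL` the sample melts completely:
#' `total = lag + 100 / rate`. An explicit total time implying more melted
#' mass than the initial mass is rejected.
#'
#' @param lag_min lag time, min.
#' @param rate_pct_per_min fast-phase melting rate, % of initial mass/min.
#' @param total_time_min total melting time, min (default: full melt).
#' @param initial_mass_g initial sample mass, g (default 300; large enough
#'   that the first 0.5 g drips within one logging interval of the lag at
#'   rates of ~1 %/min).
#' @param temp_start_C,temp_plateau_C,temp_end_C core-temperature profile:
#'   start, melting-plateau and end temperatures, degC.
#' @param cfg a [generator_config()].
#' @return A [melting_curve()].
#' @export
generate_melting_curve <- function(lag_min, rate_pct_per_min,
                                   total_time_min = NULL,
                                   initial_mass_g = 300,
                                   temp_start_C = -18, temp_plateau_C = -1,
                                   temp_end_C = 18,
                                   cfg = generator_config()) {
  if (is.null(total_time_min))
    total_time_min <- lag_min + 100 / rate_pct_per_min
  if (lag_min <= 0 || rate_pct_per_min <= 0 || total_time_min <= lag_min)
    validation_error("need 0 < lag < total time and a positive rate")
  slope_g_min <- rate_pct_per_min / 100 * initial_mass_g
  final_mass <- slope_g_min * (total_time_min - lag_min)
  if (final_mass > initial_mass_g * (1 + 1e-9))
    validation_error("infeasible parameters: melted mass would exceed the initial mass")
  set.seed(cfg$seed)
  t_max_s <- (total_time_min + max(5, 0.1 * total_time_min)) * 60
  time_s <- seq(0, t_max_s, by = cfg$sampling_interval_s)
  t_min <- time_s / 60
  drip <- pmin(pmax(t_min - lag_min, 0) * slope_g_min, final_mass)
  temp <- ifelse(
    t_min <= lag_min,
    temp_start_C + (temp_plateau_C - temp_start_C) * t_min / lag_min,
    ifelse(t_min <= total_time_min, temp_plateau_C,
           temp_plateau_C + (temp_end_C - temp_plateau_C) *
             (t_min - total_time_min) / (t_max_s / 60 - total_time_min)))
  drip <- drip + stats::rnorm(length(drip), 0, cfg$noise_sd_mass)
  drip <- cummax(pmax(drip, 0))
  drip <- pmin(drip, initial_mass_g)
  temp <- temp + stats::rnorm(length(temp), 0, cfg$noise_sd_temp)
  melting_curve(time_s, drip, temp, initial_mass_g)
}

#' Generate a synthetic DSC trace
#'
#' Emulates the final 1 degC/min heating ramp of a DSC ice-content
#' measurement: a Gaussian melting endotherm whose analytic area is
#' `ice_pct / 100 * 334` J/g, superimposed on a linear baseline with
#' optional drift, plus Gaussian heat-flow noise.
#'
#' @param ice_pct ground-truth ice content, % of sample mass.
#' @param peak_center_C endotherm peak centre, degC.
#' @param peak_width_C Gaussian s.d. of the peak in degC (> 0).
#' @param drift_slope baseline drift, W/g per second.
#' @param ramp_C_per_min heating rate, degC/min.
#' @param T_range trace temperature span, degC.
#' @param cfg a [generator_config()].
#' @param constants see [thermo_constants()].
#' @return A [dsc_trace()] with an attribute `truth_ice_pct`.
#' @export
generate_dsc_trace <- function(ice_pct, peak_center_C = -2,
                               peak_width_C = 1.5, drift_slope = 0,
                               ramp_C_per_min = 1, T_range = c(-30, 15),
                               cfg = generator_config(),
                               constants = thermo_constants()) {
  if (peak_width_C <= 0) validation_error("peak width must be positive")
  if (peak_center_C < T_range[1] + 3 * peak_width_C ||
      peak_center_C > T_range[2] - 3 * peak_width_C)
    validation_error("peak must lie well inside the trace window")
  set.seed(cfg$seed)
  ramp_C_per_s <- ramp_C_per_min / 60
  time_s <- seq(0, diff(T_range) / ramp_C_per_s, by = 1)
  temp_C <- T_range[1] + ramp_C_per_s * time_s
  area_J_per_g <- ice_pct / 100 * constants$latent_heat_ice
  sigma_s <- peak_width_C / ramp_C_per_s
  center_s <- (peak_center_C - T_range[1]) / ramp_C_per_s
  hf <- drift_slope * time_s +
    area_J_per_g / (sigma_s * sqrt(2 * pi)) *
      exp(-(time_s - center_s)^2 / (2 * sigma_s^2)) +
    stats::rnorm(length(time_s), 0, cfg$noise_sd_heatflow)
  tr <- dsc_trace(time_s, temp_C, hf, sample_mass_mg = 11,
                  annealing_temp_C = NA_real_, sign_convention = "endo_up")
  attr(tr, "truth_ice_pct") <- ice_pct
  tr
}
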