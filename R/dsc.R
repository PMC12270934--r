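#' Construct a DSC heat-flow trace
#'
#' Holds the final heating ramp of a differential scanning calorimetry
#' (DSC) run: time, sample temperature and specific heat flow. The sign
#' convention of the instrument is declared at construction and the trace
#' is normalised internally to endotherm-positive (melting peaks point up).
#'
#' @param time_s time in seconds, strictly increasing, at least 10 samples.
#' @param temp_C sample temperature in degrees Celsius.
#' @param heat_flow specific heat flow in W/g of sample (J s^-1 g^-1).
#' @param sample_mass_mg sample mass in mg (metadata).
#' @param annealing_temp_C annealing temperature of the run, degC (metadata).
#' @param sign_convention `"endo_up"` if endotherms are positive in
#'   `heat_flow`, `"endo_down"` if negative.
#' @return A data.frame of class `dsc_trace` with columns `time_s`,
#'   `temp_C`, `heat_flow` (endotherm-positive) and metadata attributes.
#' @export
dsc_trace <- function(time_s, temp_C, heat_flow, sample_mass_mg = NA_real_,
                      annealing_temp_C = NA_real_,
                      sign_convention = c("endo_up", "endo_down")) {
  sign_convention <- match.arg(sign_convention)
  if (length(time_s) < 10L)
    validation_error("a DSC trace needs at least 10 samples")
  if (any(diff(time_s) <= 0))
    validation_error("time must be strictly increasing")
  if (length(temp_C) != length(time_s) || length(heat_flow) != length(time_s))
    validation_error("time, temperature and heat flow must have equal length")
  if (sign_convention == "endo_down") heat_flow <- -heat_flow
  structure(
    data.frame(time_s = time_s, temp_C = temp_C, heat_flow = heat_flow),
    class = c("dsc_trace", "data.frame"),
    sample_mass_mg = sample_mass_mg,
    annealing_temp_C = annealing_temp_C,
    sign_convention = "endo_up",
    recorded_convention = sign_convention
  )
}

#' Integrate a melting endotherm
#'
#' Trapezoidal integration over time of the heat flow above a straight
#' baseline drawn between the two window endpoints, restricted to the
#' samples whose temperature lies in `window`. Because the heat flow is
#' specific (W/g), the integral is the specific melting enthalpy in J/g of
#' sample.
#'
#' @param trace a [dsc_trace()].
#' @param window numeric length-2, `(T_start, T_end)` in degC; must lie
#'   inside the trace's temperature range.
#' @return Specific enthalpy, J/g.
#' @export
integrate_endotherm <- function(trace, window) {
  if (!inherits(trace, "dsc_trace")) validation_error("expected a dsc_trace")
  if (length(window) != 2L) validation_error("window must be (T_start, T_end)")
  window <- sort(window)
  if (window[1] < min(trace$temp_C) || window[2] > max(trace$temp_C))
    validation_error("integration window lies outside the trace's temperature range")
  idx <- which(trace$temp_C >= window[1] & trace$temp_C <= window[2])
  if (length(idx) < 3L)
    validation_error("fewer than 3 samples inside the integration window")
  t <- trace$time_s[idx]
  hf <- trace$heat_flow[idx]
  n <- length(idx)
  baseline <- hf[1] + (hf[n] - hf[1]) * (t - t[1]) / (t[n] - t[1])
  excess <- hf - baseline
  # count baseline crossings, ignoring sub-5 %-of-peak noise wiggles
  big <- excess[abs(excess) > 0.05 * max(abs(excess), 1e-300)]
  crossings <- sum(diff(sign(big)) != 0)
  if (crossings > 2L)
    warning("baseline crosses the signal more than twice; check the window",
            call. = FALSE)
  sum(diff(t) * (excess[-1] + excess[-n]) / 2)
}

#' Convert a melting enthalpy to an ice content
#'
#' Divides the measured specific melting enthalpy by the enthalpy of fusion
#' of pure ice (334 J/g). Values above 100 % are capped with a warning.
#'
#' @param enthalpy_J_per_g specific melting enthalpy, J per g of sample
#'   (vectorised, >= 0).
#' @param constants see [thermo_constants()].
#' @return Ice content, % of total sample mass.
#' @examples
#' ice_content_from_enthalpy(167) # 50
#' @export
ice_content_from_enthalpy <- function(enthalpy_J_per_g,
                                      constants = thermo_constants()) {
  if (any(!is.finite(enthalpy_J_per_g)) || any(enthalpy_J_per_g < 0))
    validation_error("enthalpy must be finite and >= 0")
  pct <- 100 * enthalpy_J_per_g / constants$latent_heat_ice
  if (any(pct > 100)) {
    warning("ice content above 100 % capped; enthalpy exceeds pure ice",
            call. = FALSE)
    pct <- pmin(pct, 100)
  }
  pct
}
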