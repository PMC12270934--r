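#' Colligative freezing-point depression
#'
#' Ideal (dilute-solution) freezing point of a premix: the cryoscopic
#' constant of water times the total effective molality,
#' `dT_f = -|K_k| * sum_s(i_s * m_s / M_s) / m_water[kg]`. Additive over
#' solutes; 0 for pure water. Real concentrated or strongly non-ideal
#' solutes (notably NaCl) deviate from this ideal line; see
#' [fit_dissociation_degree()] for an effective-i calibration.
#'
#' @param comp a [solution()].
#' @param constants see [thermo_constants()].
#' @return Freezing point in degrees Celsius (<= 0).
#' @examples
#' freezing_point(solution("glucose", 11.5)) # -1.34
#' @export
freezing_point <- function(comp, constants = thermo_constants()) {
  check_solution(comp)
  if (!length(comp$solutes)) return(0)
  i <- vapply(comp$solutes, `[[`, numeric(1), "dissociation_degree")
  molality <- sum(i * solute_moles(comp)) / (water_mass(comp) / 1000)
  -constants$cryoscopic_constant * molality
}

#' Equilibrium solute mole fraction of the serum phase
#'
#' The mole fraction of solute that the unfrozen phase must hold for its
#' freezing point to equal the temperature `T`:
#' `x_s = 1 - exp(a - b / T_K)` with `T_K` the absolute temperature.
#' Increases as the temperature drops below 0 degC. At or above the
#' temperature where `a = b / T_K` the value is <= 0, which callers
#' interpret as "no ice can coexist".
#'
#' @param temperature_C temperature in degrees Celsius (vectorised).
#' @param constants see [thermo_constants()].
#' @return Dimensionless mole fraction (may be <= 0 above the limit).
#' @examples
#' solute_mole_fraction(-18) # ~0.170
#' @export
solute_mole_fraction <- function(temperature_C, constants = thermo_constants()) {
  T_K <- temperature_C + 273.15
  if (any(T_K <= 0)) validation_error("temperature below absolute zero")
  1 - exp(constants$a - constants$b / T_K)
}

# Raw (unclamped) moles of ice per `basis_mass` g of sample.
# Single-solute calls evaluate the literal one-solute expression; mixtures
# extend it with total solute moles in the colligative term and the summed
# bound-water term. Returns -Inf-free finite values only when x_s > 0.
ice_moles_raw <- function(comp, h, temperature_C, constants = thermo_constants()) {
  x_s <- solute_mole_fraction(temperature_C, constants)
  n_w <- water_mass(comp) / constants$mw_water
  n_s <- solute_moles(comp)
  if (!length(n_s)) return(rep(n_w, length(temperature_C)))
  n_w - (1 / x_s - 1) * sum(n_s) - sum(n_s * h)
}

check_h <- function(comp, h) {
  if (!is.numeric(h) || any(!is.finite(h)) || any(h < 0))
    validation_error("hydration numbers must be finite and >= 0")
  n <- length(comp$solutes)
  if (length(h) == 1L && n > 1L) h <- rep(h, n)
  if (length(h) != max(n, 1L))
    validation_error("one hydration number per solute is required")
  h
}

#' Equilibrium ice content of a solution
#'
#' Hydration-corrected ice content as a function of temperature. Total
#' water moles are reduced by the free water that the serum phase must
#' retain (set by the equilibrium solute mole fraction) and by the bound
#' water (`sum(n_s * h_s)` moles held in the solutes' hydration shells);
#' what remains is ice. Expressed as a percentage of the total sample mass:
#' `%ice = 100 * MW_water * n_ice / basis_mass`.
#'
#' Raw negative values (temperature above the melting point, or all water
#' bound) are clamped to 0 and flagged `valid = FALSE`; so are temperatures
#' at or above the equilibrium limit where the mole-fraction expression is
#' non-positive.
#'
#' @param comp a [solution()].
#' @param h effective hydration number(s), mol water per mol solute: a
#'   scalar (recycled over solutes) or one value per solute.
#' @param temperature_C temperature(s) in degrees Celsius.
#' @param constants see [thermo_constants()].
#' @return A data.frame of class `ice_curve` with columns `temperature_C`,
#'   `ice_pct` and `valid`.
#' @examples
#' ice_content(solution("glucose", 15), h = 10.5, temperature_C = -18)
#' @export
ice_content <- function(comp, h, temperature_C,
                        constants = thermo_constants()) {
  check_solution(comp)
  h <- check_h(comp, h)
  x_s <- solute_mole_fraction(temperature_C, constants)
  raw <- vapply(temperature_C, function(Ti)
    ice_moles_raw(comp, h, Ti, constants), numeric(1))
  pct <- 100 * constants$mw_water * raw / comp$basis_mass
  valid <- x_s > 0 & pct >= 0
  pct[x_s <= 0 | pct < 0] <- 0
  structure(
    data.frame(temperature_C = temperature_C, ice_pct = pct, valid = valid),
    class = c("ice_curve", "data.frame")
  )
}

#' Serum-phase concentration after freeze concentration
#'
#' As ice forms, solutes concentrate in the unfrozen (serum) phase. For an
#' ice content expressed as a percentage of the total sample mass, each
#' solute's serum concentration is `100 * m_s / (basis - m_ice)` % w/w of
#' the unfrozen phase.
#'
#' @param comp a [solution()].
#' @param ice_content_pct ice content, % of total sample mass; must be
#'   below the moisture content.
#' @return Named numeric vector of serum concentrations (% w/w), one per
#'   solute.
#' @examples
#' serum_concentration(solution("sucrose", 15), 70) # 50 %
#' @export
serum_concentration <- function(comp, ice_content_pct) {
  check_solution(comp)
  if (!is.numeric(ice_content_pct) || length(ice_content_pct) != 1L ||
      !is.finite(ice_content_pct) || ice_content_pct < 0)
    validation_error("ice_content_pct must be a single non-negative number")
  m_ice <- ice_content_pct / 100 * comp$basis_mass
  if (m_ice >= water_mass(comp))
    validation_error("over-frozen input: ice exceeds the available water")
  out <- 100 * solute_masses(comp) / (comp$basis_mass - m_ice)
  stats::setNames(out, solute_names(comp))
}

#' Unfrozen water content
#'
#' Moisture content minus ice content, both as percentages of the total
#' sample mass.
#'
#' @inheritParams serum_concentration
#' @return Unfrozen water, % of total sample mass (>= 0).
#' @examples
#' unfrozen_water(solution("glucose", 11.5), 73) # 15.5
#' @export
unfrozen_water <- function(comp, ice_content_pct) {
  check_solution(comp)
  moisture <- 100 * water_mass(comp) / comp$basis_mass
  ufw <- moisture - ice_content_pct
  if (any(ufw < -1e-9))
    validation_error("inconsistent inputs: ice content exceeds moisture content")
  pmax(ufw, 0)
}

#' Melting point of a solution with hydration correction
#'
#' The temperature where the ice curve crosses zero ice: the root of the
#' raw (unclamped) ice-moles expression, located by bracketed
#' derivative-free root search on [-40, 0] degC to 1e-6 degC. For `h = 0`
#' and dilute non-electrolytes this agrees with the colligative
#' [freezing_point()] to within a few percent; increasing `h` lowers the
#' melting point because bound water is unavailable for freezing.
#'
#' @inheritParams ice_content
#' @return Melting point in degrees Celsius.
#' @examples
#' melting_point(solution("glucose", 11.5), h = 0) # ~ -1.31
#' @export
melting_point <- function(comp, h, constants = thermo_constants()) {
  check_solution(comp)
  h <- check_h(comp, h)
  if (!length(comp$solutes)) return(0)
  f <- function(T) ice_moles_raw(comp, h, T, constants)
  lo <- -40
  hi <- -1e-7 # x_s -> 0+ just below 0 degC, where f -> -Inf
  f_lo <- f(lo)
  if (!is.finite(f_lo) || f_lo <= 0)
    validation_error("no melting point in [-40, 0] degC (all water bound?)")
  stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
}

#' Effective hydration number from one ice-content measurement
#'
#' Closed-form inversion of the ice-content expression for a single-solute
#' sample: given the temperature and the measured ice content (% of total
#' sample mass), the hydration number is
#' `h = (n_water - n_ice - (1/x_s - 1) * n_s) / n_s`.
#' This is the exact algebraic inverse of [ice_content()]: feeding the
#' result back reproduces the input ice content to machine precision.
#'
#' A negative result means the measured ice content exceeds what even a
#' non-hydrating solute would allow — a physically inconsistent
#' measurement. It is returned as-is with a warning, never clamped.
#'
#' @param comp a single-solute [solution()].
#' @param temperature_C temperature in degrees Celsius, strictly below the
#'   equilibrium limit (where the solute mole fraction is positive).
#' @param ice_content_pct measured ice content, % of total sample mass.
#' @param constants see [thermo_constants()].
#' @return Effective hydration number (mol water / mol solute).
#' @examples
#' comp <- solution("glucose", 15)
#' pt <- ice_content(comp, h = 10.5, temperature_C = -18)
#' hydration_number(comp, -18, pt$ice_pct) # 10.5
#' @export
hydration_number <- function(comp, temperature_C, ice_content_pct,
                             constants = thermo_constants()) {
  check_solution(comp)
  if (length(comp$solutes) != 1L)
    validation_error("hydration_number requires a single-solute composition")
  x_s <- solute_mole_fraction(temperature_C, constants)
  if (x_s <= 0)
    validation_error("temperature at or above the equilibrium limit (no ice possible)")
  n_w <- water_mass(comp) / constants$mw_water
  n_s <- solute_moles(comp)
  n_ice <- (ice_content_pct / 100 * comp$basis_mass) / constants$mw_water
  h <- (n_w - n_ice - (1 / x_s - 1) * n_s) / n_s
  # below -1e-9 is a physical inconsistency, not round-off
  if (h < -1e-9)
    warning("negative hydration number: measured ice content is physically inconsistent",
            call. = FALSE)
  h
}

#' Effective degree of dissociation from freezing-point data
#'
#' Least-squares calibration of the dissociation degree `i` against
#' observed (concentration, freezing point) pairs under the colligative
#' model `dT = |K_k| * i * molality`. Useful for ionic solutes whose
#' measured freezing points fall below the ideal line: the fitted `i` is an
#' effective value absorbing the non-ideality. The package never
#' substitutes it silently for the registry value.
#'
#' The minimiser of `sum((dT_obs - K*i*m)^2)` is the closed-form ratio
#' `i = sum(dT_obs * m) / (K * sum(m^2))`.
#'
#' @param solute a [solute_spec()] (its registry `i` is ignored here).
#' @param concentration_pct concentrations, % w/w of total sample.
#' @param freezing_point_C observed freezing points, degC (<= 0).
#' @param constants see [thermo_constants()].
#' @return Fitted effective dissociation degree.
#' @examples
#' fit_dissociation_degree(solute_spec("NaCl", 58.4),
#'                         c(3, 5, 7, 8), c(-1.54, -2.63, -3.76, -4.36))
#' @export
fit_dissociation_degree <- function(solute, concentration_pct,
                                    freezing_point_C,
                                    constants = thermo_constants()) {
  if (!inherits(solute, "solute_spec"))
    validation_error("expected a solute_spec")
  if (length(concentration_pct) < 1L ||
      length(concentration_pct) != length(freezing_point_C))
    validation_error("need matching, non-empty concentration and freezing-point vectors")
  molality <- (concentration_pct / solute$molecular_weight) /
    ((100 - concentration_pct) / 1000)
  if (all(molality == 0)) validation_error("all molalities are zero")
  depression <- -freezing_point_C
  sum(depression * molality) / (constants$cryoscopic_constant * sum(molality^2))
}
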