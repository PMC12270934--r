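# Independent brute-force oracle for the ice-content model: tabulates the
# equilibrium mole fraction, the free (serum) water and the bound water
# step by step, separately from the package's vectorised implementation.
oracle_ice_pct <- function(mw_solute, conc_pct, h, temp_C, basis = 100,
                           use_printed_a = FALSE) {
  b <- 722.8
  a <- if (use_printed_a) 2.646 else b / 273.15
  mw_w <- 18.015
  m_solute <- conc_pct / 100 * basis
  m_water <- basis - m_solute
  T_K <- temp_C + 273.15
  x_s <- 1 - exp(a - b / T_K)
  if (x_s <= 0) return(NA_real_)
  n_s <- m_solute / mw_solute
  n_water_total <- m_water / mw_w
  n_serum_water <- n_s * (1 - x_s) / x_s   # free water the serum must keep
  n_bound <- n_s * h                       # water locked in hydration shells
  n_ice <- n_water_total - n_serum_water - n_bound
  100 * mw_w * n_ice / basis
}

# Hand-written coefficient of determination (independent of stats::lm).
oracle_r2 <- function(x, y) {
  bhat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ahat <- mean(y) - bhat * mean(x)
  1 - sum((y - ahat - bhat * x)^2) / sum((y - mean(y))^2)
}

# Non-NaCl rows of the model-system overview table: concentration (% w/w),
# molecular weight (g/mol) and the printed freezing point (degC).
freezing_point_fixture <- function() {
  data.frame(
    solute = rep(c("glucose", "sucrose", "ethanol", "xylitol"), each = 4),
    mw = rep(c(180, 342, 46.5, 152), each = 4),
    concentration_pct = c(11.5, 18, 23, 28,   15, 22, 26, 31,
                          5, 7.5, 10, 12.5,   15, 20, 25, 30),
    freezing_point_C = c(-1.34, -2.27, -3.09, -4.02,
                         -0.96, -1.53, -1.91, -2.44,
                         -2.11, -3.24, -4.44, -5.71,
                         -2.16, -3.06, -4.08, -5.24)
  )
}

# Premix concentration, measured ice content at -18 degC, and the printed
# serum-phase concentration (% w/w, integers) for the five model systems.
serum_fixture <- function() {
  data.frame(
    solute = rep(c("glucose", "sucrose", "ethanol", "xylitol", "NaCl"),
                 each = 4),
    concentration_pct = c(11.5, 18, 23, 28,  15, 22, 26, 31,
                          5, 7.5, 10, 12.5,  13, 19, 25, 28,  3, 5, 7, 8),
    ice_pct = c(73, 57, 47, 38,  70, 57, 49, 42,  69, 57, 49, 39,
                70, 59, 51, 41,  73, 62, 50, 42),
    serum_pct = c(43, 42, 43, 45,  50, 51, 51, 53,  16, 17, 20, 20,
                  43, 46, 51, 47,  11, 13, 14, 14)
  )
}

# The four NaCl (concentration, freezing point) observations.
nacl_fixture <- function() {
  data.frame(concentration_pct = c(3, 5, 7, 8),
             freezing_point_C = c(-1.54, -2.63, -3.76, -4.36))
}

round_half_up <- function(x) floor(x + 0.5)

# Noise-free synthetic melting curve (shared across test files).
noiseless_curve <- function(lag = 15, rate = 1.5, seed = 1, ...) {
  generate_melting_curve(lag, rate, ...,
                         cfg = generator_config(seed = seed,
                                                noise_sd_mass = 0,
                                                noise_sd_temp = 0))
}
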