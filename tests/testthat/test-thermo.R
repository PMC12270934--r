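test_that("constants are internally consistent", {
  const <- thermo_constants()
  expect_equal(const$a, const$b / const$T_water)
  expect_equal(round(const$a, 3), 2.646)
  printed <- thermo_constants(use_printed_a = TRUE)
  expect_identical(printed$a, 2.646)
})

test_that("colligative freezing point matches hand-evaluated cases", {
  expect_equal(round(freezing_point(solution("glucose", 11.5)), 2), -1.34)
  # fully dissociated NaCl on the ideal line
  expect_equal(round(freezing_point(solution("NaCl", 3)), 2), -1.97)
  # pure water
  expect_equal(freezing_point(solution(character(0), numeric(0))), 0)
})

test_that("freezing point is additive over solutes", {
  glu <- solute_spec("glucose", 180)
  xyl <- solute_spec("xylitol", 152)
  mix <- solution(list(glu, xyl), c(10, 5))
  # additivity at shared water mass: evaluate each solute alone in the
  # same 85 g of water
  single <- function(sp, pct) {
    molality <- (pct / sp$molecular_weight) / 0.085
    -1.86 * molality
  }
  expect_equal(freezing_point(mix), single(glu, 10) + single(xyl, 5),
               tolerance = 1e-12)
  expect_lt(freezing_point(mix), 0)
})

test_that("equilibrium solute mole fraction behaves as the exponential law", {
  const <- thermo_constants()
  # vanishes exactly where a = b / T_K
  expect_equal(solute_mole_fraction(const$b / const$a - 273.15, const), 0)
  # monotone increase on cooling
  xs <- solute_mole_fraction(c(-18, -8), const)
  expect_gt(xs[1], xs[2])
  expect_gt(xs[2], 0)
  # direct evaluation with the printed rounded constant
  printed <- thermo_constants(use_printed_a = TRUE)
  expect_equal(solute_mole_fraction(-18, printed),
               1 - exp(2.646 - 722.8 / 255.15), tolerance = 1e-12)
  expect_equal(solute_mole_fraction(-18, printed), 0.1705, tolerance = 1e-3)
})

test_that("ice content agrees with the brute-force oracle", {
  pt <- ice_content(solution("glucose", 15), 10.5, -18)
  expect_equal(pt$ice_pct, 61.9, tolerance = 0.1 / 61.9)
  expect_true(pt$valid)
  set.seed(42)
  for (k in 1:50) {
    mw <- runif(1, 46.5, 800)
    conc <- runif(1, 2, 35)
    h <- runif(1, 0, 12)
    temp <- runif(1, -30, -4)
    got <- ice_content(solution(solute_spec("s", mw), conc), h, temp)
    want <- oracle_ice_pct(mw, conc, h, temp)
    if (want >= 0) {
      expect_true(got$valid)
      expect_equal(got$ice_pct, want, tolerance = 1e-11)
    } else {
      expect_false(got$valid)
      expect_identical(got$ice_pct, 0)
    }
  }
})

test_that("ice content clamps non-physical regimes and stays monotone", {
  comp <- solution("glucose", 15)
  # all water bound: n_s * h = total water moles
  h_all <- (85 / 18.015) / (15 / 180) + 10
  pt <- ice_content(comp, h_all, -18)
  expect_identical(pt$ice_pct, 0)
  expect_false(pt$valid)
  # monotone: colder -> more ice; more solute -> less; more hydration -> less
  expect_gt(ice_content(comp, 7, -18)$ice_pct, ice_content(comp, 7, -8)$ice_pct)
  expect_gt(ice_content(comp, 7, -18)$ice_pct,
            ice_content(solution("glucose", 25), 7, -18)$ice_pct)
  expect_gt(ice_content(comp, 5, -18)$ice_pct, ice_content(comp, 9, -18)$ice_pct)
  # bounded by the water fraction
  curve <- ice_content(comp, 7, seq(-30, -2, by = 1))
  expect_true(all(curve$ice_pct[curve$valid] <= 85))
})

test_that("serum concentration reproduces freeze-concentration arithmetic", {
  expect_equal(round_half_up(serum_concentration(solution("sucrose", 15), 70)),
               c(sucrose = 50))
  expect_equal(round_half_up(serum_concentration(solution("glucose", 28), 38)),
               c(glucose = 45))
  # identity at zero ice
  expect_equal(unname(serum_concentration(solution("xylitol", 13), 0)), 13)
  # monotone in ice content, never below the premix concentration
  comp <- solution("glucose", 20)
  serums <- vapply(c(0, 20, 40, 60), function(i)
    serum_concentration(comp, i)[[1]], numeric(1))
  expect_true(all(diff(serums) > 0))
  expect_true(all(serums >= 20))
  expect_error(serum_concentration(comp, 85), "over-frozen")
})

test_that("unfrozen water balances the water mass exactly", {
  comp <- solution("glucose", 11.5)
  expect_equal(unfrozen_water(comp, 73), 15.5)
  expect_equal(unfrozen_water(comp, 0), 88.5)
  expect_equal(unfrozen_water(solution(character(0), numeric(0)), 100), 0)
  expect_error(unfrozen_water(comp, 95), "inconsistent")
  # mass conservation: m_ice + m_unfrozen = m_water for any valid point
  for (ice in c(0, 10.5, 40, 73)) {
    m_ice <- ice / 100 * 100
    m_ufw <- unfrozen_water(comp, ice) / 100 * 100
    expect_equal(m_ice + m_ufw, 88.5)
  }
})

test_that("melting point solves the zero-ice root and responds to hydration", {
  comp <- solution("glucose", 11.5)
  mp0 <- melting_point(comp, 0)
  expect_equal(mp0, freezing_point(comp), tolerance = 0.05)
  # raw expression vanishes at the root
  expect_equal(ice_content(comp, 0, mp0 - 1e-4)$ice_pct, 0, tolerance = 1e-2)
  # increasing h strictly lowers the melting point
  mps <- vapply(c(0, 4, 8, 12), function(h) melting_point(comp, h), numeric(1))
  expect_true(all(diff(mps) < 0))
  # pure water melts at 0 degC
  expect_equal(melting_point(solution(character(0), numeric(0)), 0), 0)
  # all water bound: no root in the bracket
  expect_error(melting_point(solution("glucose", 15), 60), "melting point")
})

test_that("hydration-number inversion is the exact inverse of the forward model", {
  comp <- solution("glucose", 15)
  pt <- ice_content(comp, 7, -18)
  expect_equal(hydration_number(comp, -18, pt$ice_pct), 7, tolerance = 1e-9)
  # the h = 0 prediction inverts to zero
  pt0 <- ice_content(comp, 0, -12)
  expect_equal(hydration_number(comp, -12, pt0$ice_pct), 0, tolerance = 1e-9)
  # worked single-point example
  expect_equal(hydration_number(comp, -18, 61.92), 10.5, tolerance = 1e-3)
  # above the equilibrium limit there is nothing to invert
  expect_error(hydration_number(comp, 2, 10), "equilibrium")
  # inconsistent measurement: negative h is reported, not clamped
  expect_warning(h_neg <- hydration_number(comp, -18, 95), "inconsistent")
  expect_lt(h_neg, 0)
  # mixtures are not invertible from one measurement
  mix <- solution(c("glucose", "sucrose"), c(10, 10))
  expect_error(hydration_number(mix, -18, 50), "single-solute")
})

test_that("dissociation-degree fitting recovers known and printed values", {
  nacl <- solute_spec("NaCl", 58.4)
  # exact recovery when data are generated on the ideal line with i = 2
  conc <- c(2, 4, 6, 8)
  fp <- vapply(conc, function(cc)
    freezing_point(solution(solute_spec("NaCl", 58.4,
                                        dissociation_degree = 2), cc)),
    numeric(1))
  expect_equal(fit_dissociation_degree(nacl, conc, fp), 2, tolerance = 1e-9)
  # single observation reduces to the exact ratio
  m <- (3 / 58.4) / 0.097
  expect_equal(fit_dissociation_degree(nacl, 3, -1.54), 1.54 / (1.86 * m),
               tolerance = 1e-12)
  # the four printed observations give the effective i of ~1.57
  obs <- nacl_fixture()
  expect_equal(fit_dissociation_degree(nacl, obs$concentration_pct,
                                       obs$freezing_point_C),
               1.57, tolerance = 0.02 / 1.57)
  expect_error(fit_dissociation_degree(nacl, numeric(0), numeric(0)))
})

test_that("compositions are validated", {
  expect_error(solution("glucose", 0), "0, 100")
  expect_error(solution("glucose", 101), "0, 100")
  expect_error(solution(c("glucose", "sucrose"), c(60, 45)), "sum below")
  expect_error(solution("unobtainium", 10), "not found")
  expect_error(solute_spec("x", -5), "positive")
  expect_error(solute_spec("x", 100, 0.5), ">= 1")
})
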