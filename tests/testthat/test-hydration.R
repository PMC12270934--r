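noiseless_dataset <- function(h_surface, solutes = "glucose",
                              concentrations = c(15, 20, 25),
                              temperatures = seq(-18, -8, by = 2)) {
  generate_ice_dataset(solutes, concentrations, temperatures, h_surface,
                       cfg = generator_config(seed = 1, noise_sd_ice = 0,
                                              replicates = 1))
}

test_that("noiseless fits recover a constant hydration surface exactly", {
  data <- noiseless_dataset(7)
  tab <- fit_hydration_table(data)
  expect_equal(nrow(tab), 18)
  expect_true(all(abs(tab$h - 7) < 1e-6))
  expect_true(all(tab$flag == ""))
  # both replicate-handling modes agree on noiseless data
  tab2 <- fit_hydration_table(data, method = "invert-then-mean")
  expect_equal(tab$h, tab2$h, tolerance = 1e-12)
})

test_that("a single record reduces to the closed-form inversion", {
  d <- data.frame(solute = "glucose", concentration_pct = 15,
                  temperature_C = -18, replicate = 1, ice_pct = 61.92)
  tab <- fit_hydration_table(d)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$h, 10.5, tolerance = 1e-3)
})

test_that("fits recover a varying surface and preserve its trends", {
  # h decreasing in concentration, increasing on cooling
  h_true <- function(conc, temp, ...) 12 - 0.2 * conc - 0.1 * temp
  data <- noiseless_dataset(h_true)
  tab <- fit_hydration_table(data)
  want <- h_true(tab$concentration_pct, tab$temperature_C)
  expect_equal(tab$h, want, tolerance = 1e-9)
  # no spurious trend: fitted h still decreases with concentration
  for (temp in unique(tab$temperature_C)) {
    sub <- tab[tab$temperature_C == temp, ]
    sub <- sub[order(sub$concentration_pct), ]
    expect_true(all(diff(sub$h) < 0))
  }
})

test_that("inconsistent cells are flagged, bad inputs rejected", {
  d <- data.frame(solute = "glucose", concentration_pct = 15,
                  temperature_C = -18, replicate = 1, ice_pct = 95)
  tab <- fit_hydration_table(d)
  expect_equal(tab$flag, "negative_h")
  expect_lt(tab$h, 0)
  expect_error(fit_hydration_table(d[0, ]), "empty")
  d$solute <- "mystery"
  expect_error(fit_hydration_table(d), "mystery")
  expect_error(as_ice_dataset(data.frame(solute = "glucose", ice_pct = 50)),
               "missing columns")
})

test_that("prediction round-trips the fitted table", {
  data <- noiseless_dataset(function(conc, temp, ...) 9 - 0.15 * conc)
  tab <- fit_hydration_table(data)
  comp <- solution("glucose", 20)
  pred <- predict_ice_curve(comp, tab, seq(-18, -8, by = 2))
  truth <- data[data$solute == "glucose" & data$concentration_pct == 20 &
                  data$replicate == 1, ]
  truth <- truth[order(truth$temperature_C), ]
  pred <- pred[order(pred$temperature_C), ]
  expect_equal(pred$ice_pct, truth$ice_pct, tolerance = 1e-6)
  # a constant-h table predicts identically to direct forward calls
  const_tab <- fit_hydration_table(noiseless_dataset(7))
  direct <- ice_content(comp, 7, c(-17, -11))
  via_table <- predict_ice_curve(comp, const_tab, c(-17, -11))
  expect_equal(via_table$ice_pct, direct$ice_pct, tolerance = 1e-9)
})

test_that("interpolation policies behave as declared", {
  entries <- data.frame(solute = "glucose",
                        concentration_pct = rep(c(15, 25), each = 2),
                        temperature_C = rep(c(-18, -10), 2),
                        h = c(10, 8, 6, 4))
  lin <- hydration_table(entries, interpolation = "linear-in-T")
  comp <- solution("glucose", 15)
  # midpoint temperature -> arithmetic mean of the bracketing cells
  mid <- predict_ice_curve(comp, lin, -14)
  expect_equal(mid$h, 9)
  # nearest policy snaps to the closest cell
  near <- hydration_table(entries, interpolation = "nearest")
  expect_equal(predict_ice_curve(comp, near, -17)$h, 10)
  # bilinear interpolates the concentration axis too
  bil <- hydration_table(entries, interpolation = "bilinear")
  expect_equal(predict_ice_curve(solution("glucose", 20), bil, -14)$h, 7)
  # outside the hull: error unless extrapolation is requested
  expect_error(predict_ice_curve(comp, lin, -25), "hull")
  expect_silent(predict_ice_curve(comp, lin, -25, extrapolate = TRUE))
  # flagged cells never feed interpolation
  entries2 <- entries
  entries2$flag <- c("", "negative_h", "", "")
  near2 <- hydration_table(entries2, interpolation = "nearest")
  expect_equal(predict_ice_curve(comp, near2, -10)$h, 10)
  # duplicate keys are rejected
  expect_error(hydration_table(rbind(entries, entries[1, ])), "duplicate")
})

test_that("noisy fits recover the surface within noise-scaled bounds", {
  h_true <- function(conc, temp, ...) 11 - 0.2 * conc - 0.15 * temp
  data <- generate_ice_dataset("glucose", c(15, 20, 25), seq(-18, -8, 2),
                               h_true,
                               cfg = generator_config(seed = 99,
                                                      noise_sd_ice = 0.5,
                                                      replicates = 3))
  tab <- fit_hydration_table(data)
  want <- h_true(tab$concentration_pct, tab$temperature_C)
  rel <- abs(tab$h - want) / want
  expect_lt(mean(rel), 0.05)
})
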