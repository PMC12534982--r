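test_that("dose-response fit recovers noiseless parameters", {
  I <- c(0, 10^seq(-1, 3, length.out = 8))
  for (truth in list(c(Vmax = 100, IC50 = 10, h = 1),
                     c(Vmax = 50, IC50 = 3.2, h = 1.7),
                     c(Vmax = 7, IC50 = 250, h = 0.8))) {
    V <- truth["Vmax"] / (1 + (I / truth["IC50"])^truth["h"])
    fit <- fit_dose_response(I, V)
    expect_true(fit$converged)
    expect_equal(fit$Vmax, unname(truth["Vmax"]), tolerance = 1e-6)
    expect_equal(fit$IC50, unname(truth["IC50"]), tolerance = 1e-6)
    expect_equal(fit$h, unname(truth["h"]), tolerance = 1e-6)
    # half-maximal activity at the fitted IC50, by construction
    expect_equal(predict(fit, fit$IC50), fit$Vmax / 2, tolerance = 1e-9)
  }
})

test_that("dose-response fit flags unusable designs instead of guessing", {
  # too few concentrations
  fit <- fit_dose_response(c(0, 1, 10), c(100, 90, 50))
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "5 distinct")
  # flat data
  I <- 10^seq(-1, 3, length.out = 8)
  flat <- fit_dose_response(I, rep(100, 8))
  expect_false(flat$converged)
  expect_match(flat$diagnostic, "flat")
  # negative concentrations are a hard error
  expect_error(fit_dose_response(c(-1, 1, 10, 100, 1000), rep(1, 5)), ">= 0")
})

test_that("IC50 recovery under multiplicative noise is accurate in median", {
  errs <- vapply(1:100, function(s) {
    tab <- simulate_inhibition_assay("competitive", Ki = 5, Km = 100,
                                     Vmax = 100, S = 100,
                                     I = 10^seq(-1, 3, length.out = 10),
                                     noise_cv = 0.02, seed = 9000 + s)
    fit <- fit_dose_response(tab$inhibitor_uM, tab$activity)
    true_ic50 <- 5 * (1 + 100 / 100)
    abs(fit$IC50 - true_ic50) / true_ic50
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("Cheng-Prusoff arithmetic and its algebraic inverse", {
  expect_equal(cheng_prusoff_ki(20, S = 0, Km = 100), 20)
  expect_equal(cheng_prusoff_ki(20, S = 100, Km = 100), 10)
  set.seed(3)
  for (i in 1:25) {
    ic50 <- runif(1, 0.1, 100); S <- runif(1, 0, 1000); Km <- runif(1, 1, 500)
    expect_equal(cheng_prusoff_ki(ic50, S, Km) * (1 + S / Km), ic50,
                 tolerance = 1e-12)
  }
  expect_error(cheng_prusoff_ki(-1, 10, 10), "positive")
  expect_error(cheng_prusoff_ki(10, 10, 0), "positive")
})

test_that("predicted IC50 curves are monotone in the mode's direction", {
  S <- c(100, 200, 500, 1000)
  comp <- predicted_ic50_curve(Ki = 2, Km = 100, "competitive", S)
  expect_equal(comp$IC50[comp$S == 100], 2 * (1 + 1))
  expect_equal(comp$IC50[comp$S == 1000] / comp$IC50[comp$S == 100],
               (1 + 10) / (1 + 1))
  expect_true(all(diff(comp$IC50) > 0))
  unc <- predicted_ic50_curve(Ki = 2, Km = 100, "uncompetitive", S)
  expect_true(all(diff(unc$IC50) < 0))
  expect_error(predicted_ic50_curve(2, 100, "mixed", S), "arg")
  # round trip: Cheng-Prusoff recovers the generating Ki from the curve
  ki_back <- cheng_prusoff_ki(comp$IC50, comp$S, Km = 100)
  expect_equal(ki_back, rep(2, 4), tolerance = 1e-12)
})

test_that("mode classification follows the IC50-substrate trend", {
  # a 3.4-fold IC50 increase from low to high substrate reads competitive
  call <- classify_inhibition_mode(S = c(100, 1000), ic50 = c(7, 7 * 3.4),
                                   Km = 100)
  expect_equal(call$mode, "competitive")
  expect_equal(call$fold_shift, 3.4)
  expect_equal(call$Ki,
               mean(c(7 / (1 + 1), 7 * 3.4 / (1 + 10))), tolerance = 1e-12)
  # decreasing IC50 reads uncompetitive; no Ki is derived
  dec <- classify_inhibition_mode(S = c(100, 1000), ic50 = c(10, 4))
  expect_equal(dec$mode, "uncompetitive")
  expect_true(is.na(dec$Ki))
  # shifts inside the dead band are indeterminate
  flat <- classify_inhibition_mode(S = c(100, 1000), ic50 = c(10, 11))
  expect_equal(flat$mode, "indeterminate")
  expect_error(classify_inhibition_mode(S = c(100, 100), ic50 = c(1, 2)),
               "duplicated")
})

test_that("simulated competitive/uncompetitive assays classify correctly", {
  set.seed(21)
  for (draw in 1:20) {
    Ki <- runif(1, 0.5, 20); Km <- runif(1, 50, 500)
    for (mode in c("competitive", "uncompetitive")) {
      ic50s <- vapply(c(100, 1000), function(S) {
        tab <- simulate_inhibition_assay(mode, Ki, Km, Vmax = 100, S = S,
                                         I = 10^seq(-2, 4, length.out = 12),
                                         noise_cv = 0)
        fit_dose_response(tab$inhibitor_uM, tab$activity)$IC50
      }, numeric(1))
      call <- classify_inhibition_mode(c(100, 1000), ic50s)
      expect_equal(call$mode, mode)
    }
  }
})

test_that("fitted apparent IC50 matches the closed form Ki(1 + S/Km)", {
  for (pars in list(c(Ki = 1.5, Km = 80, S = 100),
                    c(Ki = 3.9, Km = 200, S = 1000),
                    c(Ki = 10, Km = 500, S = 250))) {
    tab <- simulate_inhibition_assay("competitive", pars["Ki"], pars["Km"],
                                     Vmax = 100, S = pars["S"],
                                     I = 10^seq(-2, 4, length.out = 12),
                                     noise_cv = 0)
    fit <- fit_dose_response(tab$inhibitor_uM, tab$activity)
    expected <- unname(pars["Ki"] * (1 + pars["S"] / pars["Km"]))
    expect_equal(fit$IC50, expected, tolerance = 0.01)
  }
})

test_that("Tm extraction recovers sigmoid midpoints by both methods", {
  curve <- simulate_melt_curve(Tm = 55.7, slope = 1.5)
  tm_d <- fit_melting_temperature(curve$temperature_C, curve$ratio_350_330,
                                  "derivative")
  tm_b <- fit_melting_temperature(curve$temperature_C, curve$ratio_350_330,
                                  "boltzmann")
  expect_equal(tm_d, 55.7, tolerance = 0.1)
  expect_equal(tm_b, 55.7, tolerance = 0.1)
  expect_lt(abs(tm_d - tm_b), 0.2)

  # with baseline drifts the midpoint still comes back
  drifty <- simulate_melt_curve(Tm = 59.2, slope = 2,
                                drifts = c(0.0005, 0.001))
  tm2 <- fit_melting_temperature(drifty$temperature_C, drifty$ratio_350_330)
  expect_equal(tm2, 59.2, tolerance = 0.15)

  # flat and featureless inputs are refused
  Tgrid <- seq(35, 80, by = 0.5)
  expect_error(fit_melting_temperature(Tgrid, rep(0.8, length(Tgrid))),
               "no transition")
  expect_error(fit_melting_temperature(Tgrid, 0.8 + 0.001 * (Tgrid - 35),
                                       "derivative"), "no transition")
  expect_error(fit_melting_temperature(seq(1, 9), seq(1, 9)), ">= 10")
})

test_that("thermal shift is a signed antisymmetric difference", {
  expect_equal(delta_tm(55.7, 55.7), 0)
  expect_equal(delta_tm(59.2, 55.7), 3.5)
  expect_equal(delta_tm(55.7, 59.2), -delta_tm(59.2, 55.7))
})
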