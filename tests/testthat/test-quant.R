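test_that("gravimetric unit conversion matches the benzoate-salt arithmetic", {
  salt <- benzoate_salt()
  expect_equal(average_mw(salt), 446.59, tolerance = 0.01)
  expect_equal(signif(ng_to_pmol(0.68, salt), 3), 1.52)
  expect_equal(ng_to_pmol(0, salt), 0)
  expect_equal(ng_to_pmol(446.58, salt), 1000, tolerance = 1)
  # round trip
  expect_equal(pmol_to_ng(ng_to_pmol(7.3, salt), salt), 7.3, tolerance = 1e-12)
})

test_that("preparation arithmetic chains concentrations and volumes", {
  sc <- prep_scheme()
  # 2 uL x 0.5 mg/mL standard = 1000 ng in a 145 uL vial
  a <- prep_amounts(sc, 0)
  expect_equal(a$standard_ng_vial, 1000)
  expect_equal(a$final_volume_uL, 145)
  expect_equal(a$standard_ng, 1000 * sc$injection_volume_uL / 145)
  expect_equal(a$analyte_ng, 0)

  # 1300 uL sample at 10 ug/mL -> 13 ug residue; 20/200 aliquot -> 1.3 ug
  b <- prep_amounts(sc, 10)
  expect_equal(b$analyte_ng_vial, 1300, tolerance = 1e-9)

  expect_error(prep_scheme(aliquot_uL = 300), "aliquot")
  expect_error(prep_scheme(diluent_uL = 0), "> 0")
})

test_that("calibration fitting reports OLS slope, R-squared and residual sd", {
  x <- c(1, 2, 4, 8, 16)
  # exactly collinear points: lm warns about the perfect fit, which is the point
  cal <- suppressWarnings(fit_calibration(x, 3 * x + 2))
  expect_equal(cal$slope, 3, tolerance = 1e-12)
  expect_equal(cal$intercept, 2, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_equal(cal$residual_sd, 0, tolerance = 1e-9)
  expect_error(fit_calibration(c(2, 2, 2), c(1, 2, 3)), "degenerate")
  expect_error(fit_calibration(c(1, 2), c(1, 2)), "3 points")
})

test_that("LOD follows the 3.3 sigma / slope rule and scales with noise", {
  cal <- fit_calibration(c(1, 2, 4, 8), c(1.1, 1.9, 4.2, 7.9))
  cal <- estimate_lod(cal)
  expect_equal(cal$lod_ng, 3.3 * cal$residual_sd / cal$slope, tolerance = 1e-12)
  expect_equal(cal$lod_pmol, ng_to_pmol(cal$lod_ng), tolerance = 1e-12)
  expect_false(cal$lod_below_floor)

  # doubling the residuals doubles the LOD
  resp <- c(1.1, 1.9, 4.2, 7.9)
  fitted <- fit_calibration(c(1, 2, 4, 8), resp)
  pred <- fitted$intercept + fitted$slope * c(1, 2, 4, 8)
  cal2 <- estimate_lod(fit_calibration(c(1, 2, 4, 8), pred + 2 * (resp - pred)))
  expect_equal(cal2$lod_ng, 2 * cal$lod_ng, tolerance = 1e-9)

  perfect <- estimate_lod(suppressWarnings(fit_calibration(c(1, 2, 4),
                                                           c(2, 4, 8))))
  expect_equal(perfect$lod_ng, 0, tolerance = 1e-9)
  expect_true(perfect$lod_below_floor)

  # a calibration whose 3.3 sigma/slope is exactly 0.68 ng reports 1.52 pmol
  tuned <- cal
  tuned$residual_sd <- 0.68 * tuned$slope / 3.3
  tuned <- estimate_lod(tuned)
  expect_equal(signif(tuned$lod_pmol, 3), 1.52)
})

test_that("noiseless quantification is an exact round trip", {
  st <- full_d2()
  b <- build_basis(denatonium(), st)
  run <- simulate_run(10, 10, st, model = noiseless_model())
  qr <- quantify_run(run, b, 10)
  expect_true(qr$detected)
  expect_equal(qr$analyte_pmol, 10, tolerance = 1e-9)
  # unit consistency: pmol path and ng path agree to 1e-9 relative
  expect_equal(qr$analyte_ng, pmol_to_ng(10), tolerance = 1e-9 * qr$analyte_ng)
})

test_that("a blank run is reported as a non-detect", {
  st <- full_d2()
  b <- build_basis(denatonium(), st)
  blank <- structure(list(scans = lapply(seq(17.5, 20, 1 / 60), function(rt) {
    list(rt = rt, peaks = data.frame(mz = numeric(0), intensity = numeric(0)))
  })), class = "centroid_run")
  qr <- quantify_run(blank, b, 10)
  expect_false(qr$detected)
  expect_equal(qr$analyte_pmol, 0)
})

test_that("back-calculation through the prep scheme inverts the forward chain", {
  st <- full_d2()
  b <- build_basis(denatonium(), st)
  sc <- prep_scheme()
  conc_truth <- 10  # ug/mL in the original sample
  fwd <- prep_amounts(sc, conc_truth)
  analyte_pmol <- ng_to_pmol(fwd$analyte_ng)
  standard_pmol <- ng_to_pmol(fwd$standard_ng)
  run <- simulate_run(analyte_pmol, standard_pmol, st,
                      model = noiseless_model())
  qr <- quantify_run(run, b, standard_pmol, scheme = sc)
  expect_equal(qr$sample_conc_ug_per_mL, conc_truth,
               tolerance = 1e-6 * conc_truth)
})

test_that("calibration through the full chain is linear in amount", {
  st <- full_d2()
  b <- build_basis(denatonium(), st)
  amounts_ng <- exp(seq(log(0.68), log(47.5), length.out = 5))
  amounts_pmol <- ng_to_pmol(amounts_ng)
  runs <- simulate_calibration_series(amounts_pmol, 20, st,
                                      model = acquisition_model(noise_cv = 0.005,
                                                                seed = 21))
  resp <- vapply(runs, function(r) quantify_run(r, b, 20)$response, numeric(1))
  cal <- fit_calibration(amounts_ng, resp)
  expect_gt(cal$r_squared, 0.999)
  # response is the internal-standard-normalized ratio: slope in 1/ng tracks
  # the molar ratio, independent of the absolute response factor
  m2 <- acquisition_model(noise_cv = 0.005, seed = 21,
                          intensity_per_pmol = 5e4)
  runs2 <- simulate_calibration_series(amounts_pmol, 20, st, model = m2)
  resp2 <- vapply(runs2, function(r) quantify_run(r, b, 20)$response, numeric(1))
  cal2 <- fit_calibration(amounts_ng, resp2)
  expect_equal(cal2$slope, cal$slope, tolerance = 0.02 * cal$slope)
})
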