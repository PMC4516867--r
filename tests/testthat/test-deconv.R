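test_that("basis columns are normalized and share the overlap grid position", {
  b <- build_basis(denatonium(), full_d2())
  expect_equal(sum(b$light), 1, tolerance = 1e-9)
  expect_equal(sum(b$heavy), 1, tolerance = 1e-9)
  expect_true(all(diff(b$mz_grid) > 0))
  # the light M+2 and heavy M+0 centroids (~6 mDa apart) occupy one grid
  # position: exactly one grid point near 327.23 carries weight in BOTH columns
  near <- which(b$mz_grid > 327.1 & b$mz_grid < 327.4)
  expect_equal(length(near), 1)
  expect_gt(b$light[near], 0)
  expect_gt(b$heavy[near], 0)
})

test_that("partially labeled standards give a state-weighted heavy column", {
  st <- state_distribution(0.95, FALSE, 2)
  b <- build_basis(denatonium(), st)
  # d0/d1/d2 alpha states put heavy weight on the light monoisotopic position
  expect_gt(b$heavy[1], 0.0015)  # ~ (1-0.95)^2 * base abundance
  expect_lt(b$heavy[1], 0.005)
  full <- build_basis(denatonium(), full_d2())
  expect_equal(full$heavy[1], 0)
})

test_that("an unlabeled standard is rejected as collinear", {
  st0 <- state_distribution(0, FALSE, 2)
  b <- build_basis(denatonium(), st0)
  obs <- b$light * 100
  expect_error(estimate_fractions(obs, b), "collinear")
})

test_that("envelope matching sums in-tolerance peaks and flags foreign intensity", {
  b <- build_basis(denatonium(), full_d2())
  sp <- render_spectrum(list(list(pattern = isotope_pattern(denatonium()),
                                  weight = 1000)), noiseless_model())
  mt <- match_envelope(sp, b)
  expect_equal(mt$observed / sum(mt$observed), b$light, tolerance = 1e-9)
  expect_equal(mt$foreign_intensity, 0)

  sp2 <- rbind(sp, data.frame(mz = max(b$mz_grid) + 0.8, intensity = 50))
  mt2 <- match_envelope(sp2, b)
  expect_equal(mt2$observed, mt$observed, tolerance = 1e-12)
  expect_equal(mt2$foreign_intensity, 50)

  far <- data.frame(mz = c(100, 200), intensity = c(1, 1))
  expect_warning(mt3 <- match_envelope(far, b), "no observed peaks")
  expect_true(all(mt3$observed == 0))
})

test_that("fractions are recovered exactly from noiseless mixtures", {
  b <- build_basis(denatonium(), full_d2())
  light <- isotope_pattern(denatonium())
  heavy <- isotope_pattern(parse_formula("C21H27D2N2O", 1))
  for (w in list(c(1, 1), c(2, 1), c(1, 2), c(97, 3))) {
    sp <- render_spectrum(list(list(pattern = light, weight = w[1]),
                               list(pattern = heavy, weight = w[2])),
                          noiseless_model())
    est <- estimate_fractions(match_envelope(sp, b)$observed, b)
    expect_equal(est$light_fraction, w[1] / sum(w), tolerance = 1e-9)
    expect_equal(est$light_fraction + est$heavy_fraction, 1, tolerance = 1e-12)
    expect_lt(est$residual_norm, 1e-9)
  }
  # pure heavy: light fraction exactly zero under the NNLS constraint
  sph <- render_spectrum(list(list(pattern = heavy, weight = 5)),
                         noiseless_model())
  esth <- estimate_fractions(match_envelope(sph, b)$observed, b)
  expect_equal(esth$light_fraction, 0)
  expect_error(estimate_fractions(rep(0, length(b$mz_grid)), b), "all zero")
})

test_that("NNLS equals an exhaustive grid search over fractions", {
  b <- build_basis(denatonium(), full_d2())
  A <- cbind(b$light, b$heavy)
  grid_fracs <- seq(0, 1, by = 1e-4)
  withr::with_seed(5, {
    for (rep in 1:20) {
      truth <- runif(1, 0.02, 0.98)
      obs <- 1000 * (truth * b$light + (1 - truth) * b$heavy) *
        exp(rnorm(length(b$light), sd = 0.02))
      est <- estimate_fractions(obs, b)
      # oracle: scan the fraction simplex, optimal scale in closed form
      sse <- vapply(grid_fracs, function(f) {
        v <- A %*% c(f, 1 - f)
        s <- sum(v * obs) / sum(v * v)
        sum((obs - s * v)^2)
      }, numeric(1))
      best <- grid_fracs[which.min(sse)]
      expect_lt(abs(est$light_fraction - best), 2e-4)
    }
  })
})

test_that("modelling the shared M+2/M+0 centroid beats the naive two-peak ratio", {
  b <- build_basis(denatonium(), full_d2())
  light <- isotope_pattern(denatonium())
  heavy <- isotope_pattern(parse_formula("C21H27D2N2O", 1))
  sp <- render_spectrum(list(list(pattern = light, weight = 1),
                             list(pattern = heavy, weight = 1)),
                        noiseless_model())
  est <- estimate_fractions(match_envelope(sp, b)$observed, b)
  bias_full <- abs(est$light_fraction - 0.5)
  # naive estimate: ratio of the two monoisotopic peaks, ignoring that the
  # heavy M+0 position also carries the light M+2 contribution
  i_light <- sp$intensity[which.min(abs(sp$mz - light$mz[1]))]
  i_heavy <- sp$intensity[which.min(abs(sp$mz - heavy$mz[1]))]
  bias_naive <- abs(i_light / (i_light + i_heavy) - 0.5)
  expect_gt(bias_naive, 0.005)
  expect_lt(bias_full, bias_naive)
})

test_that("isotope dilution arithmetic converts fractions to amounts", {
  est <- structure(list(light_fraction = 0.5, heavy_fraction = 0.5,
                        residual_norm = 0), class = "fraction_estimate")
  expect_equal(ratio_and_amount(est, 10), 10)
  est2 <- structure(list(light_fraction = 2 / 3, heavy_fraction = 1 / 3,
                         residual_norm = 0), class = "fraction_estimate")
  expect_equal(ratio_and_amount(est2, 3), 6, tolerance = 1e-12)
  blank <- structure(list(light_fraction = 0, heavy_fraction = 1,
                          residual_norm = 0), class = "fraction_estimate")
  expect_equal(ratio_and_amount(blank, 42), 0)
  none <- structure(list(light_fraction = 1, heavy_fraction = 0,
                         residual_norm = 0), class = "fraction_estimate")
  expect_error(ratio_and_amount(none, 10), "no internal standard")
})
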