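test_that("scaled subtraction is exact, linear and restricted to the overlap", {
  v <- seq(1000, 2000, by = 2)
  s <- spectrum(v, 0.5 + 1e-4 * v + 0.3 * exp(-((v - 1545) / 40)^2))
  expect_equal(subtract_scaled(s, s, 1)$absorbance, rep(0, length(v)))
  expect_equal(subtract_scaled(s, s, 0)$absorbance, s$absorbance)
  r <- spectrum(seq(900, 2100, by = 5), 0.2 + 5e-5 * seq(900, 2100, by = 5))
  one <- subtract_scaled(subtract_scaled(s, r, 0.3), r, 0.4)
  two <- subtract_scaled(s, r, 0.7)
  expect_equal(one$absorbance, two$absorbance, tolerance = 1e-12)
  expect_error(subtract_scaled(s, spectrum(c(4000, 4100), c(1, 1)), 1),
               "disjoint")
  expect_equal(difference_spectrum(s, r)$absorbance,
               subtract_scaled(s, r, 1)$absorbance)
})

test_that("under-weighted water subtraction leaves the high-wavenumber hydration residual", {
  # emulate an amide solution spectrum: a weighted bulk-water band at 3400
  # cm^-1 plus a blue-shifted hydration-shell band at 3450 cm^-1
  v <- seq(2800, 3800, by = 2)
  water <- spectrum(v, exp(-((v - 3400) / (2 * 150))^2))
  sample <- spectrum(v, 0.88 * water$absorbance +
                        0.10 * exp(-((v - 3450) / (2 * 60))^2))
  at3410 <- function(sp) sp$absorbance[which.min(abs(sp$wavenumber - 3410))]
  res <- vapply(c(0.77, 0.88, 0.92),
                function(w) at3410(subtract_scaled(sample, water, w)),
                numeric(1))
  # residual absorbance near 3410 stays positive at every plausible weight,
  # shrinking as the subtraction weight grows
  expect_true(all(res > 0))
  expect_true(all(diff(res) < 0))
})

test_that("the band model evaluates exactly as written (2*Delta inside the square)", {
  comp <- data.frame(amplitude = 0.4, center = 1545, width = 11)
  m <- peak_model(0.02, 1e-5, comp, window = c(1450, 1750))
  # zero-component model is the straight baseline
  m0 <- peak_model(0.02, 1e-5, comp[0, ], window = c(1450, 1750))
  v <- seq(1450, 1750, by = 1)
  expect_equal(evaluate_peak_model(m0, v)$absorbance, 0.02 + 1e-5 * v)
  # value at the center is baseline + amplitude
  expect_equal(evaluate_peak_model(m, 1545)$absorbance,
               0.02 + 1e-5 * 1545 + 0.4)
  # value at center +- 2*Delta is baseline + A/e
  for (v2 in 1545 + c(-22, 22))
    expect_equal(evaluate_peak_model(m, v2)$absorbance,
                 0.02 + 1e-5 * v2 + 0.4 * exp(-1), tolerance = 1e-12)
})

test_that("band fitting round-trips noiseless two-Gaussian spectra to 1e-4", {
  v <- seq(1450, 1750, by = 1)
  truth <- peak_model(0.02, 2e-5,
                      data.frame(amplitude = c(0.35, 0.5),
                                 center = c(1545, 1640), width = c(11, 13)),
                      window = c(1450, 1750))
  fit <- fit_peak_model(evaluate_peak_model(truth, v))
  expect_true(fit$converged)
  expect_equal(fit$components$center, c(1545, 1640), tolerance = 1e-4)
  expect_equal(fit$components$amplitude, c(0.35, 0.5), tolerance = 1e-4)
  expect_equal(fit$components$width, c(11, 13), tolerance = 1e-4)
  expect_equal(fit$baseline_intercept, 0.02, tolerance = 1e-3)
  # far too few points for the parameter count
  expect_error(fit_peak_model(spectrum(v[1:20], rep(1, 20)),
                              window = c(1450, 1470)), "points")
})

test_that("fitted centers are reproducible across restarts and offset-invariant", {
  spec <- gen_ir_series(temperatures = 50, seed = 31)[[1]]
  f1 <- fit_peak_model(spec)
  # restart from a deliberately shifted warm start: centers agree to 0.1 cm^-1
  shifted <- peak_model(f1$baseline_intercept, f1$baseline_slope,
                        transform(f1$components, center = center + 4),
                        window = f1$window)
  f2 <- fit_peak_model(spec, init = shifted)
  expect_lt(max(abs(f1$components$center - f2$components$center)), 0.1)
  # adding a constant moves only the baseline intercept
  spec2 <- spectrum(spec$wavenumber, spec$absorbance + 0.37,
                    temperature = spec$temperature)
  f3 <- fit_peak_model(spec2)
  expect_lt(max(abs(f1$components$center - f3$components$center)), 0.01)
  expect_equal(f3$baseline_intercept - f1$baseline_intercept, 0.37,
               tolerance = 1e-3)
})

test_that("band tracking recovers the amide II drift and is hysteresis-free", {
  spectra <- gen_ir_series(seed = 11)
  series <- band_position_series(spectra)
  expect_false(anyNA(series$center))
  drift <- series$center[nrow(series)] - series$center[1]
  expect_equal(drift, -5, tolerance = 0.2)
  # flat series stays flat within fit noise
  flat <- gen_ir_series(drift = c(1545, 1545), seed = 12)
  fs <- band_position_series(flat)
  expect_lt(diff(range(fs$center)), 0.2)
  # cooling (reversed) series returns to the starting position
  cool <- gen_ir_series(temperatures = seq(81, 27, by = -6), seed = 13)
  cs <- band_position_series(cool)
  expect_equal(cs$center[nrow(cs)], series$center[1], tolerance = 0.1)
})

test_that("per-spectrum failures become gaps, not aborts", {
  spectra <- gen_ir_series(temperatures = c(27, 45, 63), seed = 14)
  # make the middle spectrum unusable within the window
  bad <- spectrum(seq(1740, 1760, by = 1), rep(1, 21), temperature = 45)
  out <- band_position_series(list(spectra[[1]], bad, spectra[[3]]))
  expect_identical(is.na(out$center), c(FALSE, TRUE, FALSE))
})
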