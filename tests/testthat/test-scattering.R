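test_that("scattering vector from angle matches the closed form", {
  expect_equal(q_from_angle(0, 0.154), 0)
  expect_equal(q_from_angle(180, 1), 4 * pi)
  expect_equal(q_from_angle(2, 0.154), 1.42411, tolerance = 1e-5)
  expect_error(q_from_angle(2, 0), "> 0")
  expect_error(q_from_angle(-1, 0.154), "degrees")
})

test_that("Debye intensity has the right limits, monotonicity and asymptote", {
  expect_equal(debye_intensity(0, 7, 12), 7)
  # x = 1: 2 I0 / e
  expect_equal(debye_intensity(1 / 12, 1, 12), 2 * exp(-1), tolerance = 1e-10)
  # q^-2 regime: I q^2 -> 2 I0 / rg^2 at large x (x = 400)
  rg <- 12; q <- 20 / rg
  expect_equal(debye_intensity(q, 1, rg) * q^2, 2 / rg^2, tolerance = 5e-3)
  # normalised intensity in (0, 1], equal to 1 only at q = 0, decreasing
  qq <- seq(0, 5, length.out = 400)
  y <- debye_intensity(qq, 1, 12)
  expect_true(all(y > 0 & y <= 1))
  expect_identical(which(y == 1), 1L)
  expect_true(all(diff(y) < 0))
  # Guinier consistency at low q: |D/I0 - (1 - x/3)| <= 0.01 for q rg <= 0.3
  qs <- seq(1e-4, 0.3 / 12, length.out = 50)
  expect_true(all(abs(debye_intensity(qs, 1, 12) - (1 - (qs * 12)^2 / 3)) <= 0.01))
})

test_that("Guinier analysis recovers Rg and rejects curves without a Guinier regime", {
  q <- seq(0.01, 1, length.out = 150)
  cur <- scattering_curve(q, debye_intensity(q, 50, 12))
  gf <- guinier_fit(cur)
  expect_equal(gf$rg, 12, tolerance = 0.02)
  # exactly log-linear curve with slope -48 nm^2 gives rg = sqrt(144)
  cur2 <- scattering_curve(q, 10 * exp(-48 * q^2))
  expect_equal(guinier_fit(cur2)$rg, 12, tolerance = 1e-8)
  expect_error(guinier_fit(scattering_curve(q, rep(3, length(q)))),
               "no Guinier regime")
})

test_that("Debye fits recover exact parameters on noiseless curves for rg 2-30 nm", {
  q <- seq(0.01, 1, length.out = 150)
  for (rg in c(2, 5, 12.5, 20, 30)) {
    fit <- fit_debye(scattering_curve(q, debye_intensity(q, 100, rg)))
    expect_true(fit$converged)
    expect_equal(fit$rg, rg, tolerance = 1e-6)
    expect_equal(fit$I0, 100, tolerance = 1e-6)
    # Guinier and Debye agree within 3% (noiseless)
    expect_equal(guinier_fit(scattering_curve(q, debye_intensity(q, 100, rg)))$rg,
                 rg, tolerance = 0.03)
  }
})

test_that("Debye fits tolerate 5% noise and flag aggregated curves", {
  q <- seq(0.05, 2, length.out = 120)
  I <- debye_intensity(q, 100, 12.5)
  set.seed(91)
  noisy <- scattering_curve(q, I * (1 + rnorm(length(q), 0, 0.05)),
                            sigma = 0.05 * I)
  fit <- fit_debye(noisy)
  expect_true(fit$converged)
  expect_equal(fit$rg, 12.5, tolerance = 0.05)
  # strong low-q power-law component from an aggregated state
  agg <- scattering_curve(q, I + 5 * q^-2)
  fa <- fit_debye(agg)
  expect_true(!fa$converged || fa$rg > 3 * 12.5)
})

test_that("power-law exponent recovers exact slopes", {
  q <- seq(0.05, 2, length.out = 200)
  expect_equal(power_law_exponent(scattering_curve(q, 3 * q^-2), range(q)),
               -2, tolerance = 1e-10)
  expect_equal(power_law_exponent(scattering_curve(q, rep(4, length(q))),
                                  range(q)), 0, tolerance = 1e-10)
  # pure Debye in the window q rg in [5, 20] sits in the q^-2 regime
  rg <- 12.5
  cur <- scattering_curve(q, debye_intensity(q, 100, rg))
  slope <- power_law_exponent(cur, c(5 / rg, 20 / rg))
  expect_gt(slope, -2.1); expect_lt(slope, -1.9)
  expect_error(power_law_exponent(scattering_curve(q, q - 1), range(q)),
               "nonpositive")
})

test_that("background subtraction interpolates, combines uncertainties and rejects disjoint grids", {
  q <- seq(0.1, 1, by = 0.1)
  cur <- scattering_curve(q, q * 2, sigma = rep(0.3, length(q)))
  zero <- background_subtract(cur, cur, scale = 1)
  expect_equal(zero$intensity, rep(0, length(q)))
  expect_equal(zero$sigma, rep(sqrt(2) * 0.3, length(q)))
  expect_equal(background_subtract(cur, cur, scale = 0)$intensity, cur$intensity)
  # piecewise-linear background on a shifted grid: hand-computed at 3 probes
  bg <- scattering_curve(c(0.05, 0.45, 0.95, 1.5), c(1, 5, 2, 2))
  out <- background_subtract(cur, bg)
  hand <- function(x) approx(c(0.05, 0.45, 0.95, 1.5), c(1, 5, 2, 2), x)$y
  for (probe in c(0.1, 0.5, 0.9)) {
    i <- which(abs(out$q - probe) < 1e-9)
    expect_equal(out$intensity[i], 2 * probe - hand(probe))
  }
  far <- scattering_curve(c(5, 6), c(1, 1))
  expect_error(background_subtract(cur, far), "disjoint")
})

test_that("aggregation onset triggers on fit failure or a 50% jump over the prior median", {
  mk <- function(rg, conv = TRUE)
    structure(list(rg = rg, converged = conv), class = "debye_fit")
  temps <- c(25, 35, 45, 55, 60, 65, 70, 75)
  flat <- lapply(rep(12, 8), mk)
  expect_null(aggregation_onset(flat, temps))
  series <- c(lapply(c(12, 12.3, 11.8, 12.1, 12), mk),
              list(mk(25), mk(60), mk(NA, conv = FALSE)))
  expect_equal(aggregation_onset(series, temps), 65)
  # failure at the first point: no baseline below the candidate
  early <- c(list(mk(NA, conv = FALSE)), lapply(rep(12, 7), mk))
  expect_error(aggregation_onset(early, temps), "baseline")
  expect_error(aggregation_onset(lapply(rep(12, 3), mk), temps[1:3]),
               "at least 4")
})
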