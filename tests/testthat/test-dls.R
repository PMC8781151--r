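test_that("DLS scattering vector and water viscosity anchors are right", {
  expect_equal(dls_q(180, 4 * pi, 1), 1)
  expect_equal(dls_q(173, 633, 1.33), 0.0263540, tolerance = 1e-5)
  expect_lt(dls_q(0.001, 633, 1.33), 1e-6)
  expect_equal(water_viscosity(20), 1.002)
  expect_error(water_viscosity(120), "range")
})

test_that("simulated g2 matches the closed-form field correlation", {
  lag <- 10^seq(-7, -2, length.out = 80)
  ac <- simulate_g2(12.5, 1, lag = lag, beta = 0.8, noise_sd = 0)
  g <- oracle_gamma(12.5)
  expect_equal(ac$g2, 1 + 0.8 * exp(-2 * g * lag), tolerance = 1e-9)
  # intercept: g2 -> 1 + beta as lag -> 0
  expect_lt(abs(ac$g2[1] - (1 + 0.8)), 0.005)
  expect_error(simulate_g2(c(12.5, 90), c(0, 0)), "positive sum")
})

test_that("cumulant analysis is the inverse of monodisperse simulation", {
  ac <- simulate_g2(12.5, 1, noise_sd = 0)
  cf <- cumulant_fit(ac)
  expect_equal(cf$z_average_rh, 12.5, tolerance = 1e-6)
  expect_lt(cf$pdi, 1e-6)
  expect_equal(cf$intercept_beta, 0.9, tolerance = 1e-6)
})

test_that("bimodal mixtures give the analytic cumulants and an intermediate Z-average", {
  ac <- simulate_g2(c(12.5, 90), c(0.5, 0.5), noise_sd = 0)
  # analytic two-exponential cumulants (brute force from the definition)
  or <- mixture_cumulants(c(0.5, 0.5), oracle_gamma(c(12.5, 90)))
  # short-lag window: fitted cumulants approach the analytic values
  cf0 <- cumulant_fit(ac, amplitude_cut = 0.7)
  expect_equal(cf0$decay_rate, or$gamma, tolerance = 0.01)
  expect_equal(cf0$pdi, or$mu2 / or$gamma^2, tolerance = 0.05)
  # Z-average equals the intensity-weighted harmonic mean of the radii
  expect_equal(cf0$z_average_rh, 1 / (0.5 / 12.5 + 0.5 / 90), tolerance = 0.01)
  # default window: polydisperse, Z-average between the modes
  cf <- cumulant_fit(ac)
  expect_gt(cf$pdi, 0.1)
  expect_gt(cf$z_average_rh, 12.5); expect_lt(cf$z_average_rh, 90)
})

test_that("cumulant analysis rejects pure-noise records", {
  set.seed(5)
  lag <- 10^seq(-7, -2, length.out = 60)
  noise <- autocorrelation(lag, 1 + rnorm(60, 0, 1e-4))
  expect_error(cumulant_fit(noise), "no ")
})

test_that("decay rate scales with q^2 and the Z-average ignores weight scaling", {
  g90 <- cumulant_fit(simulate_g2(12.5, 1, angle = 90, noise_sd = 0))
  g173 <- cumulant_fit(simulate_g2(12.5, 1, angle = 173, noise_sd = 0))
  ratio <- (dls_q(173, 633, 1.33) / dls_q(90, 633, 1.33))^2
  expect_equal(g173$decay_rate / g90$decay_rate, ratio, tolerance = 1e-6)
  a <- cumulant_fit(simulate_g2(c(12.5, 90), c(0.25, 0.75), noise_sd = 0))
  b <- cumulant_fit(simulate_g2(c(12.5, 90), 40 * c(0.25, 0.75), noise_sd = 0))
  expect_equal(a$z_average_rh, b$z_average_rh, tolerance = 1e-12)
})

test_that("Rh onset follows the shared 50%-jump rule", {
  mk <- function(rh) structure(list(z_average_rh = rh, converged = TRUE),
                               class = "cumulant_fit")
  temps <- seq(25, 80, by = 5)
  expect_null(rh_onset(lapply(rep(12.5, 12), mk), temps))
  stepped <- lapply(c(rep(12.5, 8), rep(90, 4)), mk)
  expect_equal(rh_onset(stepped, temps), 65)
  drift <- lapply(12 * 1.02^(0:11), mk)
  expect_null(rh_onset(drift, temps))
})
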