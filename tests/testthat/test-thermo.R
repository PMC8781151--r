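fitted_shell <- hydration_params(-69.7, 0.2, 57.9)

test_that("ice and water chemical-potential quadratics evaluate as printed", {
  expect_equal(mu_ice(0), 10.286)
  expect_equal(mu_water(0), 8.038)
  expect_equal(mu_water(25), -84.5045, tolerance = 1e-6)
  expect_equal(mu_ice(-6), -125.4112, tolerance = 1e-6)
  expect_warning(mu_water(110), "validity")
})

test_that("quadratic curves refit exactly and regenerate from the packaged reference table", {
  T_C <- c(-5, 10, 30, 60, 90)
  mu <- 8.038 - 0.7842 * T_C - 0.1167 * T_C^2
  cv <- suppressWarnings(fit_quadratic_mu(T_C, mu))
  expect_equal(c(cv$c0, cv$c1, cv$c2), c(8.038, -0.7842, -0.1167),
               tolerance = 1e-9)
  expect_error(fit_quadratic_mu(T_C[1:3], mu[1:3]), "4 points")
  expect_error(fit_quadratic_mu(rep(5, 5), rep(1, 5)), "rank")
  ref <- read.csv(system.file("extdata", "mu_reference_synthetic.csv",
                              package = "silksol"), comment.char = "#")
  w <- ref[ref$phase == "water", ]
  cw <- fit_quadratic_mu(w$temperature_C, w$mu_J_per_mol, "water")
  expect_lt(abs(cw$c0 - 8.038) / 8.038, 0.02)
  expect_lt(abs(cw$c2 + 0.1167) / 0.1167, 0.02)
  i <- ref[ref$phase == "ice", ]
  ci <- suppressWarnings(fit_quadratic_mu(i$temperature_C, i$mu_J_per_mol, "ice"))
  expect_lt(abs(ci$c1 - 22.186) / 22.186, 0.02)
})

test_that("solution potential lowers with water activity as R T ln(a)", {
  expect_equal(mu_solution(25, 1), mu_water(25))
  expect_equal(mu_solution(25, 0.9), -345.674, tolerance = 1e-3)
  a <- seq(1, 0.8, by = -0.02)
  expect_true(all(diff(mu_solution(25, a)) < 0))
  expect_error(mu_solution(25, 0), "0, 1")
})

test_that("the shell potential evaluates Eq-style with Kelvin increments and log ratios", {
  # at T0 the potential reduces to dH0 - T0 dS0
  expect_equal(mu_hydration(0, fitted_shell), -69.7 - 273.15 * 0.2,
               tolerance = 1e-9)
  expect_equal(mu_hydration(-6, fitted_shell), -126.978, tolerance = 1e-3)
  # zero heat capacity: linear in absolute temperature
  p0 <- hydration_params(-100, -0.5, 1e-9)
  T_C <- c(0, 20, 40, 60)
  expect_equal(mu_hydration(T_C, p0), -100 + (T_C + 273.15) * 0.5,
               tolerance = 1e-4)
  # heat-capacity consistency: d(dH_hyd)/dT equals cp_shell
  h <- function(T_C) fitted_shell$dH0 +
    fitted_shell$cp_shell * (T_C + 273.15 - 273.15)
  num <- (h(25 + 0.005) - h(25 - 0.005)) / 0.01
  expect_equal(num, fitted_shell$cp_shell, tolerance = 1e-9)
  # continuity / differentiability probe over the working range
  grid <- seq(-29, 99, by = 0.5)
  mu <- mu_hydration(grid, fitted_shell)
  expect_true(all(is.finite(mu)))
  # second differences bounded by the smooth curvature -cp/T (no kinks)
  expect_lt(max(abs(diff(diff(mu)))), 0.06)
})

test_that("shell-minus-water differences show enthalpy-entropy compensation", {
  d0 <- delta_thermo(0, fitted_shell)
  expect_equal(d0$dG, -69.7 - 273.15 * 0.2, tolerance = 1e-9)
  d <- delta_thermo(seq(10, 60, by = 5), fitted_shell)
  expect_true(all(d$dH_rel < 0))
  expect_true(all(d$TdS_rel < 0))
  # nearly parallel: local slopes of dH and T dS agree within 20%
  sH <- diff(d$dH_rel) / 5; sTS <- diff(d$TdS_rel) / 5
  expect_true(all(abs(sH - sTS) / abs(sH) < 0.2))
  # dCp = 0 makes dG linear in absolute temperature
  pl <- hydration_params(-100, -0.5, 75.7, cp_water_ref = 75.7)
  dg <- delta_thermo(c(0, 25, 50, 75), pl)$dG
  expect_lt(max(abs(diff(diff(dg)))), 1e-9)
})

test_that("gelation roots match a 0.01-degC grid-scan oracle", {
  Tg <- gelation_temperature_heating(fitted_shell)
  oracle <- grid_scan_root(function(T_C) delta_thermo(T_C, fitted_shell)$dG,
                           0, 100, by = 0.01)
  expect_lte(abs(Tg - oracle), 0.02)
  expect_equal(Tg, 67.58, tolerance = 0.01)
  Tf <- gelation_temperature_freezing(fitted_shell)
  oracle_f <- grid_scan_root(function(T_C)
    mu_hydration(T_C, fitted_shell) - mu_ice(T_C), -25, -0.01, by = 0.01)
  expect_lte(abs(Tf - oracle_f), 0.02)
  expect_equal(Tf, -6.07, tolerance = 0.01)
})

test_that("degenerate shell states yield no root or flag multiple crossings", {
  # dCp = 0, nonpositive entropy penalty, negative enthalpy: always stable
  stable <- hydration_params(-100, 0.1, 75.7, cp_water_ref = 75.7)
  expect_null(gelation_temperature_heating(stable))
  # ice curve far below the shell curve everywhere: no freezing crossing
  low_ice <- quadratic_mu(-5000, 0, 0, "ice")
  expect_null(gelation_temperature_freezing(fitted_shell, ice = low_ice))
  # a strongly curved ice stand-in crossing the shell twice is flagged
  wavy_ice <- quadratic_mu(-370, -36, -1.2, "ice")
  expect_error(gelation_temperature_freezing(fitted_shell, ice = wavy_ice),
               "multiple sign changes")
})

test_that("the enthalpy penalty at gelation is consistent with the root", {
  expect_equal(enthalpy_penalty_at_gelation(fitted_shell), 1.273,
               tolerance = 1e-3)
  # dCp = 0 case: penalty is |dH0| at any root
  p <- hydration_params(-500, -1.7, 75.7, cp_water_ref = 75.7)
  expect_equal(enthalpy_penalty_at_gelation(p), 0.5, tolerance = 1e-6)
  # at the root, dH_rel = T_K dS_rel by definition
  Tg <- gelation_temperature_heating(fitted_shell, tol = 1e-8)
  d <- delta_thermo(Tg, fitted_shell)
  expect_equal(d$dH_rel, d$TdS_rel, tolerance = 1e-6)
  expect_error(enthalpy_penalty_at_gelation(
    hydration_params(-100, 0.1, 75.7, cp_water_ref = 75.7)), "no heating")
})

test_that("the heating root moves earlier as the shell heat-capacity deficit grows", {
  cps <- c(57.9, 60, 63, 65)   # increasing cp_shell = decreasing dCp
  roots <- vapply(cps, function(cp)
    gelation_temperature_heating(hydration_params(-69.7, 0.2, cp)), numeric(1))
  expect_true(all(diff(roots) > 0))
})

test_that("heat-capacity deficit and amide hydrogen-bond arithmetic reproduce the derived values", {
  expect_equal(shell_cp_deficit(fitted_shell), 17.8, tolerance = 1e-9)
  expect_equal(shell_cp_deficit(fitted_shell, 2), 35.6, tolerance = 1e-9)
  est <- peptide_hbond_enthalpy()
  expect_equal(est$per_peptide, 5.775, tolerance = 1e-6)
  expect_equal(est$per_water, 5.775 / 2, tolerance = 1e-6)
  # robust across the full 1.6-1.9 acceptor/donor strength range
  for (r in seq(1.6, 1.9, by = 0.05))
    expect_equal(peptide_hbond_enthalpy(acceptor_donor_ratio = r)$per_peptide,
                 5.8, tolerance = 0.1)
})

test_that("salt water-activity interpolation is monotone, anchored and bounded", {
  expect_equal(water_activity("NaCl", 0), 1)
  expect_equal(water_activity("NaCl", 6), 0.767, tolerance = 0.01)
  tab <- salt_activity_table("KCl")
  # midpoint of a tabulated interval is the mean of its neighbours
  m <- (tab$molality[5] + tab$molality[6]) / 2
  expect_equal(water_activity(tab, m),
               mean(tab$water_activity[5:6]), tolerance = 1e-12)
  ms <- seq(0, 4.5, by = 0.25)
  expect_true(all(diff(water_activity(tab, ms)) < 0))
  expect_error(water_activity("NaCl", 7), "range")
})
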