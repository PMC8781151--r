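test_that("freely jointed chain Rg follows b*sqrt(N/6) and the fibroin chain gives 12.1 nm", {
  expect_equal(rg_random_coil(bmori_fibroin()), 12.13809, tolerance = 1e-6)
  expect_equal(rg_random_coil(chain_spec(6, 1, 110)), 1.0)
  # sqrt scaling: quadrupling N doubles Rg
  expect_equal(rg_random_coil(chain_spec(24, 0.5, 110)),
               2 * rg_random_coil(chain_spec(6, 0.5, 110)))
  # closed form holds across a parameter sweep
  for (N in c(10, 100, 5525)) for (b in c(0.2, 0.4, 1.5))
    expect_equal(rg_random_coil(chain_spec(N, b, 100)), b * sqrt(N / 6))
})

test_that("power-law coil-size relation behaves and brackets the literature size classes", {
  expect_equal(rg_power_law(1, 3.7, 0.29), 3.7)
  # exponent 0.5 with prefactor b/sqrt(6) reproduces the random-coil formula
  expect_equal(rg_power_law(5525, 0.4 / sqrt(6), 0.5),
               rg_random_coil(bmori_fibroin()))
  # monotone in the exponent at fixed n > 1: folded < denatured < disordered
  ex <- c(0.29, 0.50, 0.59)
  vals <- vapply(ex, function(e) rg_power_law(5525, 0.35, e), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("single-coil density uses the uniform sphere of equal Rg and round-trips the mass", {
  expect_equal(coil_mass_density(419600, 12), 0.04474, tolerance = 1e-4)
  # one chain weighing 1 g in a 1 cm^3 sphere has density 1
  rg1 <- (3 / (4 * pi))^(1 / 3) / sqrt(5 / 3) * 1e7   # nm
  expect_equal(coil_mass_density(6.02214076e23, rg1), 1.0, tolerance = 1e-12)
  # cubic scaling
  expect_equal(coil_mass_density(419600, 24),
               coil_mass_density(419600, 12) / 8, tolerance = 1e-12)
  # mass round trip: rho * V_sphere * N_A = M
  for (rg in c(5, 12, 30)) {
    rho <- coil_mass_density(419600, rg)
    V <- (4 / 3) * pi * (sqrt(5 / 3) * rg * 1e-7)^3
    expect_equal(rho * V * 6.02214076e23, 419600, tolerance = 1e-12)
  }
})

test_that("water-to-residue ratios reproduce the feedstock stoichiometry", {
  expect_equal(water_to_residue_ratio(solution_composition(0.23, 75.9)),
               14.10, tolerance = 1e-3)
  expect_equal(
    water_to_residue_ratio(solution_composition(NA, 75.9,
                                                solute_concentration = 0.25)),
    12.639, tolerance = 1e-3)
  # equal moles at 50% w/w when residue mass equals the water molar mass
  expect_equal(water_to_residue_ratio(solution_composition(0.5, 18.015)), 1.0)
  # strictly decreasing in the solute mass fraction
  fr <- seq(0.05, 0.95, by = 0.05)
  ratios <- vapply(fr, function(f)
    water_to_residue_ratio(solution_composition(f, 75.9)), numeric(1))
  expect_true(all(diff(ratios) < 0))
  # solute concentration must stay below the solution density
  expect_error(solution_composition(NA, 75.9, solute_concentration = 1.1),
               "below the total")
})

test_that("chain specifications validate mass consistency and read from config blocks", {
  expect_error(chain_spec(5525, 0.4, 75.9, chain_molar_mass = 350000),
               "inconsistent")
  expect_error(chain_spec(0, 0.4, 75.9), ">= 1")
  cfg <- list(n_residues = 5525, monomer_length_nm = 0.4,
              avg_residue_mass = 75.9, chain_molar_mass = 419600)
  ch <- spec_from_config(cfg)
  expect_s3_class(ch, "chain_spec")
  expect_equal(rg_random_coil(ch), rg_random_coil(bmori_fibroin()))
  comp <- spec_from_config(list(mass_fraction = 0.23, residue_mass = 75.9))
  expect_s3_class(comp, "solution_composition")
  yml <- tempfile(fileext = ".yaml")
  writeLines("n_residues: 100\nmonomer_length_nm: 0.4\navg_residue_mass: 75.9", yml)
  expect_equal(spec_from_config(yml)$n_residues, 100)
})
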