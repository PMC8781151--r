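## Closed-form coil-size, density and hydration-stoichiometry calculations for
## a polypeptide chain characterised only by residue count, monomer length and
## masses (no sequence information).

#' Polypeptide chain specification
#'
#' Bundles the quantities needed for random-coil size and density predictions:
#' the number of residues `N`, the monomer (statistical segment) length `b`,
#' and the masses. If the molar mass of the whole chain is supplied it must be
#' consistent with `N * avg_residue_mass` to within 2%.
#'
#' @param n_residues number of amino-acid residues (>= 1).
#' @param monomer_length monomer length b in nm (> 0).
#' @param avg_residue_mass average residue formula weight in g/mol (> 0).
#' @param chain_molar_mass optional molar mass of the complete chain in g/mol.
#' @return an object of class `"chain_spec"`.
#' @examples
#' chain_spec(5525, 0.4, 75.9, 419600)
#' @export
chain_spec <- function(n_residues, monomer_length, avg_residue_mass,
                       chain_molar_mass = NULL) {
  .stopifnot_num(n_residues, "n_residues")
  if (n_residues < 1) stop("'n_residues' must be >= 1")
  .stopifnot_num(monomer_length, "monomer_length", positive = TRUE)
  .stopifnot_num(avg_residue_mass, "avg_residue_mass", positive = TRUE)
  if (!is.null(chain_molar_mass)) {
    .stopifnot_num(chain_molar_mass, "chain_molar_mass", positive = TRUE)
    rel <- abs(chain_molar_mass - n_residues * avg_residue_mass) / chain_molar_mass
    if (rel > 0.02)
      stop("'chain_molar_mass' inconsistent with n_residues * avg_residue_mass ",
           sprintf("(relative difference %.3f > 0.02)", rel))
  }
  structure(list(n_residues = n_residues, monomer_length = monomer_length,
                 avg_residue_mass = avg_residue_mass,
                 chain_molar_mass = chain_molar_mass),
            class = "chain_spec")
}

#' @export
print.chain_spec <- function(x, ...) {
  cat("Polypeptide chain: N =", x$n_residues,
      "residues, b =", x$monomer_length, "nm,",
      "<m> =", x$avg_residue_mass, "g/mol")
  if (!is.null(x$chain_molar_mass))
    cat(", M =", format(x$chain_molar_mass, big.mark = ","), "g/mol")
  cat("\n")
  invisible(x)
}

#' The B. mori fibroin chain
#'
#' Convenience constructor for the conjoined heavy + light fibroin chain of
#' *Bombyx mori*: 5525 residues, 0.4 nm monomer length, 75.9 g/mol average
#' residue mass and a 419.6 kDa chain molar mass (sequence-derived values).
#'
#' @return a [chain_spec()].
#' @export
bmori_fibroin <- function() chain_spec(5525, 0.4, 75.9, 419600)

#' Solution composition of an amide/peptide solute in water
#'
#' Describes a binary solute-water mixture either by mass fraction or by
#' solute concentration in g/cm^3 (which, together with the total solution
#' density, overrides the mass fraction).
#'
#' @param solute_mass_fraction solute mass fraction in `[0, 1]`.
#' @param solute_residue_mass molar mass of the solute repeat unit (g/mol).
#' @param water_molar_mass molar mass of water (g/mol), default 18.015.
#' @param total_density total solution density in g/cm^3, default 1.0.
#' @param solute_concentration optional solute concentration in g/cm^3.
#' @return an object of class `"solution_composition"`.
#' @examples
#' solution_composition(0.23, 75.9)                          # 23% w/w fibroin
#' solution_composition(NA, 75.9, solute_concentration = 0.25) # undiluted NSF
#' @export
solution_composition <- function(solute_mass_fraction, solute_residue_mass,
                                 water_molar_mass = 18.015, total_density = 1.0,
                                 solute_concentration = NULL) {
  if (is.null(solute_concentration)) {
    .stopifnot_num(solute_mass_fraction, "solute_mass_fraction")
    if (solute_mass_fraction < 0 || solute_mass_fraction > 1)
      stop("'solute_mass_fraction' must lie in [0, 1]")
  }
  .stopifnot_num(solute_residue_mass, "solute_residue_mass", positive = TRUE)
  .stopifnot_num(total_density, "total_density", positive = TRUE)
  if (!is.null(solute_concentration)) {
    .stopifnot_num(solute_concentration, "solute_concentration", positive = TRUE)
    if (solute_concentration >= total_density)
      stop("'solute_concentration' must be below the total solution density")
  }
  structure(list(solute_mass_fraction = solute_mass_fraction,
                 solute_residue_mass = solute_residue_mass,
                 water_molar_mass = water_molar_mass,
                 total_density = total_density,
                 solute_concentration = solute_concentration),
            class = "solution_composition")
}

#' Radius of gyration of a freely jointed chain
#'
#' Random-coil (theta-condition) prediction `R_G = sqrt(N b^2 / 6)` for a
#' freely jointed chain of `N` monomers of length `b`. For the B. mori
#' fibroin chain (N = 5525, b = 0.4 nm) this gives 12.1 nm.
#'
#' @param chain a [chain_spec()].
#' @return radius of gyration in nm.
#' @examples
#' rg_random_coil(bmori_fibroin())
#' @export
rg_random_coil <- function(chain) {
  stopifnot(inherits(chain, "chain_spec"))
  chain$monomer_length * sqrt(chain$n_residues / 6)
}

#' Power-law coil-size relation
#'
#' Evaluates `R_G = prefactor * n^exponent`, the generic chain-length scaling
#' used to compare folded-globule, denatured-globule and disordered-protein
#' size classes. Coefficients are caller-supplied.
#'
#' @param n_residues chain length (number of residues).
#' @param prefactor prefactor in nm (> 0).
#' @param exponent scaling exponent.
#' @return predicted radius of gyration in nm.
#' @export
rg_power_law <- function(n_residues, prefactor, exponent) {
  .stopifnot_num(n_residues, "n_residues", positive = TRUE)
  .stopifnot_num(prefactor, "prefactor", positive = TRUE)
  .stopifnot_num(exponent, "exponent")
  prefactor * n_residues^exponent
}

#' Mass density of a single coil
#'
#' Mass of one chain (`M / N_A`) divided by the volume of the uniform sphere
#' with the same radius of gyration, i.e. a sphere of radius
#' `R = sqrt(5/3) * R_G`. For the 419.6 kDa fibroin chain at R_G = 12 nm this
#' gives about 0.045 g/cm^3, illustrating how dilute the protein is within
#' its own coil.
#'
#' @param chain_molar_mass molar mass of the chain (g/mol).
#' @param rg radius of gyration in nm.
#' @return coil density in g/cm^3.
#' @examples
#' coil_mass_density(419600, 12)
#' @export
coil_mass_density <- function(chain_molar_mass, rg) {
  .stopifnot_num(chain_molar_mass, "chain_molar_mass", positive = TRUE)
  .stopifnot_num(rg, "rg", positive = TRUE)
  r_cm <- sqrt(5 / 3) * rg * 1e-7
  (chain_molar_mass / .const$N_A) / ((4 / 3) * pi * r_cm^3)
}

#' Molar ratio of water to solute residues
#'
#' Moles of water per mole of solute repeat unit. From a mass fraction,
#' `((1 - f)/M_w) / (f/m_res)`; from a g/cm^3 concentration, the water mass
#' per cm^3 is `total_density - solute_concentration`. Native silk feedstock
#' at 23% w/w gives about 14:1; undiluted feedstock at 0.25 g/cm^3 gives
#' about 12.6:1.
#'
#' @param comp a [solution_composition()].
#' @return dimensionless molar ratio (water : residue).
#' @examples
#' water_to_residue_ratio(solution_composition(0.23, 75.9))
#' @export
water_to_residue_ratio <- function(comp) {
  stopifnot(inherits(comp, "solution_composition"))
  if (!is.null(comp$solute_concentration)) {
    water_mass <- comp$total_density - comp$solute_concentration
    solute_mass <- comp$solute_concentration
  } else {
    f <- comp$solute_mass_fraction
    if (f >= 1) stop("solute mass fraction must be < 1 for a water ratio")
    water_mass <- 1 - f
    solute_mass <- f
  }
  (water_mass / comp$water_molar_mass) / (solute_mass / comp$solute_residue_mass)
}

#' Read a chain or composition specification from a config block
#'
#' Accepts a named list (e.g. parsed from YAML or JSON) with keys
#' `n_residues`, `monomer_length_nm`, `avg_residue_mass` and optionally
#' `chain_molar_mass`, or with `mass_fraction`, `residue_mass` and optionally
#' `density` / `concentration` for a composition.
#'
#' @param config named list, or path to a YAML/JSON file containing one.
#' @return a [chain_spec()] or [solution_composition()] depending on the keys.
#' @export
spec_from_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.null(config$n_residues)) {
    chain_spec(config$n_residues, config$monomer_length_nm,
               config$avg_residue_mass, config$chain_molar_mass)
  } else if (!is.null(config$mass_fraction) || !is.null(config$concentration)) {
    solution_composition(
      solute_mass_fraction = if (is.null(config$mass_fraction)) NA else config$mass_fraction,
      solute_residue_mass  = config$residue_mass,
      total_density        = if (is.null(config$density)) 1.0 else config$density,
      solute_concentration = config$concentration)
  } else stop("config block has neither chain nor composition keys")
}
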