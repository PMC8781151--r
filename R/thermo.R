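## Chemical-potential curves for ice, water and salt solutions, and the
## three-parameter thermodynamic model of the protein hydration shell.
##
## Temperature-unit convention: the empirical quadratics for ice and water
## take temperature in deg C (as they are printed); the hydration-shell
## expressions use the absolute scale (Kelvin) inside the enthalpy increment
## and the log ratio, with reference temperature T0 = 273.15 K. A Celsius
## log ratio would be undefined at 0 degC; enthalpy differences are
## unit-invariant, so the two conventions meet consistently.

#' Quadratic chemical-potential curve
#'
#' `mu(T) = c0 + c1 T + c2 T^2` with `T` in deg C and `mu` in J/mol, the
#' empirical form used for the ice and liquid-water curves referenced to the
#' triple point of water.
#'
#' @param c0,c1,c2 polynomial coefficients.
#' @param phase `"ice"` or `"water"` (or any label).
#' @return object of class `"quadratic_mu"`.
#' @export
quadratic_mu <- function(c0, c1, c2, phase = "") {
  .stopifnot_num(c(c0, c1, c2), "coefficients")
  structure(list(c0 = c0, c1 = c1, c2 = c2, phase = phase),
            class = "quadratic_mu")
}

#' @export
print.quadratic_mu <- function(x, ...) {
  cat(sprintf("mu_%s(T) = %g %+g*T %+g*T^2  (T in degC, mu in J/mol)\n",
              if (nzchar(x$phase)) x$phase else "phase", x$c0, x$c1, x$c2))
  invisible(x)
}

#' @export
predict.quadratic_mu <- function(object, newdata, ...) {
  T_C <- if (is.list(newdata)) newdata$temperature else newdata
  object$c0 + object$c1 * T_C + object$c2 * T_C^2
}

## Published-curve coefficients (J/mol, T in degC, relative to the triple
## point 273.16 K / 611.657 Pa).
.mu_ice_default   <- quadratic_mu(10.286, 22.186, -0.0717, "ice")
.mu_water_default <- quadratic_mu(8.038, -0.7842, -0.1167, "water")

#' Default ice / water chemical-potential curves
#'
#' The empirical quadratics used for the chemical potential of ice and of
#' liquid water (J/mol, temperature in deg C, referenced to the triple
#' point).
#'
#' @return a [quadratic_mu()].
#' @export
mu_ice_curve <- function() .mu_ice_default

#' @rdname mu_ice_curve
#' @export
mu_water_curve <- function() .mu_water_default

.mu_eval <- function(T_C, curve) {
  .stopifnot_num(T_C, "T")
  if (any(T_C < -30 | T_C > 100))
    warning("temperature outside the validity range [-30, 100] degC")
  curve$c0 + curve$c1 * T_C + curve$c2 * T_C^2
}

#' Chemical potential of ice
#'
#' @param T_C temperature in deg C (validity range -30 to 100 deg C; a
#'   warning is issued outside it).
#' @param curve a [quadratic_mu()]; defaults to the published-curve
#'   coefficients.
#' @return chemical potential in J/mol.
#' @examples
#' mu_ice(0)    # 10.286
#' mu_water(25) # -84.50
#' @export
mu_ice <- function(T_C, curve = mu_ice_curve()) .mu_eval(T_C, curve)

#' Chemical potential of liquid water
#'
#' @inheritParams mu_ice
#' @return chemical potential in J/mol.
#' @export
mu_water <- function(T_C, curve = mu_water_curve()) .mu_eval(T_C, curve)

#' Fit a quadratic chemical-potential curve
#'
#' Least-squares quadratic in temperature, for regenerating ice/water curves
#' from tabulated reference data.
#'
#' @param T_C temperatures in deg C (at least 4 points).
#' @param mu chemical potentials in J/mol.
#' @param phase label for the fitted curve.
#' @return a [quadratic_mu()].
#' @export
fit_quadratic_mu <- function(T_C, mu, phase = "") {
  .stopifnot_num(T_C, "T_C"); .stopifnot_num(mu, "mu")
  if (length(T_C) != length(mu)) stop("'T_C' and 'mu' lengths differ")
  if (length(T_C) < 4) stop("at least 4 points are required")
  f <- stats::lm(mu ~ T_C + I(T_C^2))
  cf <- stats::coef(f)
  if (any(is.na(cf))) stop("rank-deficient design: temperatures not distinct enough")
  quadratic_mu(unname(cf[1]), unname(cf[2]), unname(cf[3]), phase)
}

#' Chemical potential of water in a solution
#'
#' `mu_w = mu_w(T) + R T_K ln(a_w)` where the water activity `a_w = p/p#`
#' is the vapour-pressure ratio against pure water. Dissolved salts lower
#' the activity and hence the chemical potential of the bulk water.
#'
#' @param T_C temperature in deg C.
#' @param water_activity water activity in `(0, 1]`.
#' @param curve water-curve [quadratic_mu()].
#' @return chemical potential in J/mol.
#' @examples
#' mu_solution(25, 0.9)
#' @export
mu_solution <- function(T_C, water_activity, curve = mu_water_curve()) {
  .stopifnot_num(water_activity, "water_activity")
  if (any(water_activity <= 0 | water_activity > 1))
    stop("'water_activity' must lie in (0, 1]")
  mu_water(T_C, curve) + .const$R * (T_C + .const$T_zero_C) * log(water_activity)
}

#' Hydration-shell model parameters
#'
#' The three-parameter thermodynamic state of the peptide hydration shell:
#' the enthalpy and entropy offsets from pure water at the reference
#' temperature `T0` (0 deg C), and the constant molar heat capacity of
#' shell water. `cp_water_ref` is the molar heat capacity of bulk liquid
#' water used when forming shell-minus-water differences.
#'
#' @param dH0 enthalpy offset at `T0`, J/mol.
#' @param dS0 entropy offset at `T0`, J/mol/K.
#' @param cp_shell heat capacity of shell water, J/mol/K (> 0).
#' @param T0 reference temperature in K (default 273.15).
#' @param cp_water_ref molar heat capacity of bulk water, J/mol/K
#'   (default 75.7).
#' @return object of class `"hydration_params"`.
#' @examples
#' hydration_params(-69.7, 0.2, 57.9)  # the fitted shell state
#' @export
hydration_params <- function(dH0, dS0, cp_shell, T0 = 273.15,
                             cp_water_ref = 75.7) {
  .stopifnot_num(dH0, "dH0"); .stopifnot_num(dS0, "dS0")
  .stopifnot_num(cp_shell, "cp_shell", positive = TRUE)
  .stopifnot_num(T0, "T0", positive = TRUE)
  structure(list(dH0 = dH0, dS0 = dS0, cp_shell = cp_shell, T0 = T0,
                 cp_water_ref = cp_water_ref),
            class = "hydration_params")
}

#' @export
print.hydration_params <- function(x, ...) {
  cat(sprintf(paste0("Hydration-shell parameters: dH0 = %.4g J/mol, ",
                     "dS0 = %.4g J/mol/K, Cp(shell) = %.4g J/mol/K ",
                     "(T0 = %.2f K)\n"),
              x$dH0, x$dS0, x$cp_shell, x$T0))
  cat(sprintf("  dCp = Cp(water) - Cp(shell) = %.4g - %.4g = %.4g J/mol/K\n",
              x$cp_water_ref, x$cp_shell, x$cp_water_ref - x$cp_shell))
  invisible(x)
}

#' Chemical potential of the hydration shell
#'
#' `mu_hyd(T) = dH(T) - T_K dS(T)` with
#' `dH(T) = dH0 + Cp (T_K - T0)` and `dS(T) = dS0 + Cp ln(T_K / T0)`,
#' all on the absolute temperature scale.
#'
#' @param T_C temperature in deg C.
#' @param params a [hydration_params()].
#' @return chemical potential in J/mol.
#' @export
mu_hydration <- function(T_C, params) {
  stopifnot(inherits(params, "hydration_params"))
  T_K <- T_C + .const$T_zero_C
  if (any(T_K <= 0)) stop("absolute temperature must be positive")
  dH <- params$dH0 + params$cp_shell * (T_K - params$T0)
  dS <- params$dS0 + params$cp_shell * log(T_K / params$T0)
  dH - T_K * dS
}

#' Shell thermodynamics relative to bulk water
#'
#' Differences between the hydration shell and pure liquid water, using the
#' constant bulk heat capacity `cp_water_ref`: with
#' `dCp = cp_water_ref - cp_shell`,
#' `dH_rel = dH0 - dCp (T_K - T0)`, `dS_rel = dS0 - dCp ln(T_K / T0)` and
#' `dG = dH_rel - T_K dS_rel`. Both `dH_rel` and `T dS_rel` are negative and
#' nearly parallel across 10-60 deg C (enthalpy-entropy compensation); `dG`
#' changes sign at the heating gelation temperature.
#'
#' @param T_C temperature(s) in deg C.
#' @param params a [hydration_params()].
#' @return data frame with columns `temperature`, `dH_rel` (J/mol),
#'   `dS_rel` (J/mol/K), `TdS_rel` (J/mol) and `dG` (J/mol).
#' @export
delta_thermo <- function(T_C, params) {
  stopifnot(inherits(params, "hydration_params"))
  T_K <- T_C + .const$T_zero_C
  dCp <- params$cp_water_ref - params$cp_shell
  dH <- params$dH0 - dCp * (T_K - params$T0)
  dS <- params$dS0 - dCp * log(T_K / params$T0)
  data.frame(temperature = T_C, dH_rel = dH, dS_rel = dS,
             TdS_rel = T_K * dS, dG = dH - T_K * dS)
}

## bracketed root of f on (lo, hi): pre-scan on a grid for sign changes;
## 0 -> NULL, >1 -> error, 1 -> uniroot refined to `tol` degC
.bracketed_root <- function(f, lo, hi, tol = 0.01, scan_by = 0.5) {
  grid <- seq(lo, hi, by = scan_by)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  vals <- vapply(grid, f, 1)
  sgn <- sign(vals)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(flips) == 0) {
    zero <- which(sgn == 0)
    if (length(zero) == 1) return(grid[zero])
    return(NULL)
  }
  if (length(flips) > 1)
    stop("multiple sign changes in the search interval")
  stats::uniroot(f, c(grid[flips], grid[flips + 1]), tol = tol)$root
}

#' Gelation temperature on heating
#'
#' Temperature at which the Gibbs free energy of the hydration shell
#' relative to bulk water changes sign (`dG = 0`), found by bracketed
#' root-finding on `(0, 100)` deg C with 0.01 deg C tolerance. Above this
#' temperature the shell is unstable and peptide-peptide hydrogen bonds
#' (gelation) are favoured. The fitted shell state gives about 67.6 deg C.
#'
#' @param params a [hydration_params()].
#' @param interval search interval in deg C (default `c(0, 100)`).
#' @param tol root tolerance in deg C (default 0.01).
#' @return root temperature in deg C, or `NULL` if `dG` never changes sign.
#' @examples
#' gelation_temperature_heating(hydration_params(-69.7, 0.2, 57.9))
#' @export
gelation_temperature_heating <- function(params, interval = c(0, 100),
                                         tol = 0.01) {
  stopifnot(inherits(params, "hydration_params"))
  .bracketed_root(function(T_C) delta_thermo(T_C, params)$dG,
                  interval[1], interval[2], tol = tol)
}

#' Gelation temperature on freezing
#'
#' Temperature below 0 deg C at which the chemical potential of the
#' hydration shell equals that of ice, i.e. where freezing starts to strip
#' the shell. The fitted shell state with the published ice curve gives
#' about -6.1 deg C.
#'
#' @param params a [hydration_params()].
#' @param ice ice-curve [quadratic_mu()].
#' @param interval search interval in deg C (default `c(-25, 0)`).
#' @param tol root tolerance in deg C (default 0.01).
#' @return root temperature in deg C, or `NULL` if the curves do not cross.
#' @export
gelation_temperature_freezing <- function(params, ice = mu_ice_curve(),
                                          interval = c(-25, 0), tol = 0.01) {
  stopifnot(inherits(params, "hydration_params"))
  .bracketed_root(function(T_C)
    mu_hydration(T_C, params) - suppressWarnings(mu_ice(T_C, ice)),
    interval[1], interval[2], tol = tol)
}

#' Enthalpy penalty at the heating gelation temperature
#'
#' `|dH_rel|` evaluated at the `dG = 0` root, in kJ per mole of shell water:
#' the enthalpy that must be supplied to release hydration water at the
#' point where free energy first favours release. The fitted shell state
#' gives about 1.27 kJ/mol.
#'
#' @param params a [hydration_params()].
#' @return enthalpy penalty in kJ/mol.
#' @export
enthalpy_penalty_at_gelation <- function(params) {
  Tg <- gelation_temperature_heating(params)
  if (is.null(Tg)) stop("no heating gelation root: dG does not change sign")
  abs(delta_thermo(Tg, params)$dH_rel) / 1000
}

#' Heat-capacity deficit of the hydration shell
#'
#' `dCp = cp_water_ref - cp_shell` per mole of shell water, optionally
#' multiplied by the number of shell waters released per amino-acid residue
#' (release of two waters per residue corresponds to a heat-capacity
#' increase of `2 * dCp` per mole of residues).
#'
#' @param params a [hydration_params()].
#' @param waters_per_residue multiplier (default 1).
#' @return heat-capacity change in J/mol/K.
#' @examples
#' shell_cp_deficit(hydration_params(-69.7, 0.2, 57.9))     # 17.8
#' shell_cp_deficit(hydration_params(-69.7, 0.2, 57.9), 2)  # 35.6
#' @export
shell_cp_deficit <- function(params, waters_per_residue = 1) {
  stopifnot(inherits(params, "hydration_params"))
  waters_per_residue * (params$cp_water_ref - params$cp_shell)
}

#' Peptide hydrogen-bond enthalpy estimate from amide solution data
#'
#' A secondary amide forms three hydrogen bonds to water: two on the
#' carbonyl oxygen (acceptor) and one on the N-H (donor), with the acceptor
#' bonds 60-90% stronger than the donor bond. Distributing the solution
#' enthalpy of N-methylacetamide over the three bonds in that ratio, the
#' enthalpy of displacing the donor-bonded water plus one acceptor-bonded
#' water (as needed for beta-sheet formation) is
#' `|dH_solution| (1 + r) / (1 + 2 r)`, about 5.8 kJ/mol per peptide at the
#' midpoint ratio.
#'
#' @param dh_solution solution enthalpy of the model amide in kJ/mol
#'   (default -9.45, N-methylacetamide at 68 deg C).
#' @param acceptor_donor_ratio acceptor/donor bond-strength ratio (default
#'   1.75, the midpoint of the 1.6-1.9 range).
#' @param waters_displaced number of waters displaced per peptide
#'   (default 2: the donor water and one acceptor water).
#' @return list with the per-bond enthalpies (`donor`, `acceptor`), the
#'   displaced total per peptide (`per_peptide`) and the per-water value
#'   (`per_water`), all kJ/mol.
#' @examples
#' peptide_hbond_enthalpy()
#' @export
peptide_hbond_enthalpy <- function(dh_solution = -9.45,
                                   acceptor_donor_ratio = 1.75,
                                   waters_displaced = 2) {
  .stopifnot_num(dh_solution, "dh_solution")
  .stopifnot_num(acceptor_donor_ratio, "acceptor_donor_ratio", positive = TRUE)
  total <- abs(dh_solution)
  donor <- total / (1 + 2 * acceptor_donor_ratio)
  acceptor <- acceptor_donor_ratio * donor
  per_peptide <- donor + acceptor
  list(donor = donor, acceptor = acceptor, per_peptide = per_peptide,
       per_water = per_peptide / waters_displaced)
}
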