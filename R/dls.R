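## Dynamic light scattering: forward simulation of intensity autocorrelation
## decays and second-order cumulant extraction of the Z-average hydrodynamic
## radius via the Stokes-Einstein relation.

## Dynamic viscosity of water (mPa s) against temperature (deg C); standard
## handbook values, linearly interpolated. 20 degC anchor: 1.002 mPa s.
.water_viscosity_table <- data.frame(
  temperature = seq(0, 100, by = 5),
  viscosity = c(1.792, 1.519, 1.307, 1.138, 1.002, 0.890, 0.7972, 0.7190,
                0.6527, 0.5958, 0.5465, 0.5036, 0.4660, 0.4329, 0.4035,
                0.3774, 0.3540, 0.3329, 0.3145, 0.2978, 0.2818))

#' Viscosity of water
#'
#' Dynamic viscosity of liquid water at the given temperature, linearly
#' interpolated from a standard handbook table (1.002 mPa s at 20 deg C).
#'
#' @param temperature temperature in deg C, within `[0, 100]`.
#' @return viscosity in mPa s.
#' @export
water_viscosity <- function(temperature) {
  .stopifnot_num(temperature, "temperature")
  if (any(temperature < 0 | temperature > 100))
    stop("'temperature' outside the tabulated range [0, 100] degC")
  stats::approx(.water_viscosity_table$temperature,
                .water_viscosity_table$viscosity, xout = temperature)$y
}

#' DLS scattering vector
#'
#' `q = 4 pi n sin(theta/2) / lambda` for scattering angle `theta` in a
#' medium of refractive index `n`.
#'
#' @param angle scattering angle in degrees, in `(0, 180]`.
#' @param wavelength laser wavelength in vacuo, nm.
#' @param refractive_index refractive index of the medium.
#' @return q in nm^-1.
#' @examples
#' dls_q(173, 633, 1.33)  # typical backscatter geometry
#' @export
dls_q <- function(angle, wavelength, refractive_index) {
  .stopifnot_num(angle, "angle")
  .stopifnot_num(wavelength, "wavelength", positive = TRUE)
  .stopifnot_num(refractive_index, "refractive_index", positive = TRUE)
  4 * pi * refractive_index * sin(angle / 2 * pi / 180) / wavelength
}

#' Intensity autocorrelation record
#'
#' Container for a DLS measurement: lag times and the measured intensity
#' autocorrelation `g2`, together with the instrument geometry and sample
#' conditions needed to convert decay rates into hydrodynamic radii.
#'
#' @param lag delay times in seconds, strictly increasing, > 0.
#' @param g2 intensity autocorrelation values (baseline ~ 1).
#' @param angle scattering angle in degrees, in `(0, 180)`.
#' @param wavelength laser wavelength in nm.
#' @param temperature sample temperature in deg C.
#' @param refractive_index solvent refractive index (default 1.33, water).
#' @param viscosity optional solvent viscosity in mPa s; when absent it is
#'   computed from the temperature via [water_viscosity()].
#' @return object of class `"autocorrelation"`.
#' @export
autocorrelation <- function(lag, g2, angle = 173, wavelength = 633,
                            temperature = 25, refractive_index = 1.33,
                            viscosity = NULL) {
  .stopifnot_num(lag, "lag", positive = TRUE)
  .check_increasing(lag, "lag")
  .stopifnot_num(g2, "g2")
  if (length(g2) != length(lag)) stop("'lag' and 'g2' lengths differ")
  if (angle <= 0 || angle >= 180) stop("'angle' must lie in (0, 180)")
  .stopifnot_num(wavelength, "wavelength", positive = TRUE)
  if (!is.null(viscosity)) .stopifnot_num(viscosity, "viscosity", positive = TRUE)
  structure(list(lag = as.numeric(lag), g2 = as.numeric(g2), angle = angle,
                 wavelength = wavelength, temperature = temperature,
                 refractive_index = refractive_index, viscosity = viscosity),
            class = "autocorrelation")
}

#' @export
print.autocorrelation <- function(x, ...) {
  cat(sprintf(paste0("DLS autocorrelation: %d lags in [%.3g, %.3g] s, ",
                     "%g deg / %g nm, T = %g degC\n"),
              length(x$lag), min(x$lag), max(x$lag), x$angle, x$wavelength,
              x$temperature))
  invisible(x)
}

## diffusion coefficient (nm^2/s) of a sphere of radius rh (nm)
.stokes_einstein_D <- function(rh, temperature, viscosity) {
  T_K <- temperature + .const$T_zero_C
  # kB T / (6 pi eta r): eta mPa s -> Pa s (1e-3), r nm -> m (1e-9); m^2/s -> nm^2/s (1e18)
  .const$k_B * T_K / (6 * pi * viscosity * 1e-3 * rh * 1e-9) * 1e18
}

#' Simulate an intensity autocorrelation decay
#'
#' Forward model for a mixture of diffusing sphere populations:
#' `g2(tau) = 1 + beta * (sum_i w_i exp(-D_i q^2 tau))^2` with
#' `D_i = k_B T / (6 pi eta r_i)` (Stokes-Einstein). Intensity weights are
#' normalised internally; additive Gaussian noise is applied with the given
#' seed.
#'
#' @param rh hydrodynamic radii of the populations, nm (> 0).
#' @param weight intensity weights (>= 0, not all zero), same length.
#' @param lag lag-time grid in seconds.
#' @param beta coherence (intercept) factor, `g2(0) = 1 + beta`.
#' @param noise_sd standard deviation of additive Gaussian noise on `g2`.
#' @param seed optional RNG seed (the caller's RNG state is preserved).
#' @inheritParams autocorrelation
#' @return an [autocorrelation()] record.
#' @export
simulate_g2 <- function(rh, weight, lag = 10^seq(-7, -2, length.out = 100),
                        angle = 173, wavelength = 633, temperature = 25,
                        refractive_index = 1.33, viscosity = NULL,
                        beta = 0.9, noise_sd = 0, seed = NULL) {
  .stopifnot_num(rh, "rh", positive = TRUE)
  .stopifnot_num(weight, "weight")
  if (length(weight) != length(rh)) stop("'rh' and 'weight' lengths differ")
  if (any(weight < 0) || sum(weight) <= 0)
    stop("'weight' must be nonnegative with positive sum")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  w <- weight / sum(weight)
  eta <- if (is.null(viscosity)) water_viscosity(temperature) else viscosity
  q <- dls_q(angle, wavelength, refractive_index)
  gamma <- .stokes_einstein_D(rh, temperature, eta) * q^2
  g1 <- colSums(w * exp(-outer(gamma, lag)))
  g2 <- 1 + beta * g1^2
  if (noise_sd > 0)
    g2 <- with_seed(seed, g2 + stats::rnorm(length(g2), 0, noise_sd))
  autocorrelation(lag, g2, angle = angle, wavelength = wavelength,
                  temperature = temperature,
                  refractive_index = refractive_index, viscosity = eta)
}

#' Second-order cumulant analysis
#'
#' Fits `ln(g2 - 1) = ln beta - 2 Gamma tau + mu2 tau^2` over the lag window
#' in which the correlation amplitude is still significant (`g2 - 1` above
#' `amplitude_cut` times the intercept estimate), then converts the mean
#' decay rate `Gamma` to the Z-average hydrodynamic radius via
#' Stokes-Einstein at the record's temperature and viscosity. The
#' polydispersity index is `mu2 / Gamma^2` (clamped at zero).
#'
#' @param acorr an [autocorrelation()] record.
#' @param amplitude_cut fraction of the intercept below which lags are
#'   excluded from the fit (default 0.1).
#' @return object of class `"cumulant_fit"`: `z_average_rh` (nm), `pdi`,
#'   `decay_rate` (s^-1), `intercept_beta`, `n_points`, `converged`.
#' @export
cumulant_fit <- function(acorr, amplitude_cut = 0.1) {
  stopifnot(inherits(acorr, "autocorrelation"))
  y <- acorr$g2 - 1
  beta0 <- stats::median(y[seq_len(min(3, length(y)))])
  if (!is.finite(beta0) || beta0 <= 0)
    stop("no correlation signal: g2 - 1 is nonpositive at short lags")
  sel <- y > amplitude_cut * beta0
  # keep the contiguous leading run of admissible lags
  if (!sel[1]) stop("no correlation signal at the shortest lag")
  run <- which(!sel)
  if (length(run)) sel[run[1]:length(sel)] <- FALSE
  if (sum(sel) < 4) stop("fewer than 4 lags in the cumulant fit window")
  if (any(y[sel] <= 0)) stop("nonpositive g2 - 1 inside the fit window")
  tau <- acorr$lag[sel]
  f <- stats::lm(log(y[sel]) ~ tau + I(tau^2))
  cf <- stats::coef(f)
  gamma <- -cf[[2]] / 2
  if (!is.finite(gamma) || gamma <= 0)
    stop("no decaying correlation found (nonpositive decay rate)")
  mu2 <- cf[[3]]
  eta <- if (is.null(acorr$viscosity)) water_viscosity(acorr$temperature)
         else acorr$viscosity
  q <- dls_q(acorr$angle, acorr$wavelength, acorr$refractive_index)
  D <- gamma / q^2                                   # nm^2/s
  T_K <- acorr$temperature + .const$T_zero_C
  rh <- .const$k_B * T_K / (6 * pi * eta * 1e-3 * D * 1e-18) * 1e9
  structure(list(z_average_rh = rh, pdi = max(0, mu2 / gamma^2),
                 decay_rate = gamma, intercept_beta = exp(cf[[1]]),
                 n_points = sum(sel), converged = TRUE),
            class = "cumulant_fit")
}

#' @export
print.cumulant_fit <- function(x, ...) {
  cat(sprintf(paste0("Cumulant fit: Z-average Rh = %.3f nm, PDI = %.4f, ",
                     "Gamma = %.4g 1/s, beta = %.3f (%d lags)\n"),
              x$z_average_rh, x$pdi, x$decay_rate, x$intercept_beta,
              x$n_points))
  invisible(x)
}

#' @export
coef.cumulant_fit <- function(object, ...)
  c(z_average_rh = object$z_average_rh, pdi = object$pdi,
    decay_rate = object$decay_rate, intercept_beta = object$intercept_beta)

#' Aggregation onset from a temperature series of DLS results
#'
#' Applies the same rule as [aggregation_onset()] to the Z-average
#' hydrodynamic radius: the onset is the first temperature at which the
#' cumulant analysis failed or `R_H` exceeds the median of all prior values
#' by at least 50%.
#'
#' @param results list of [cumulant_fit()] results (entries may be `NULL`
#'   for failed records), sorted by temperature.
#' @param temperatures temperatures in deg C, same length, non-decreasing.
#' @return onset temperature in deg C, or `NULL`.
#' @export
rh_onset <- function(results, temperatures) {
  stopifnot(length(results) == length(temperatures))
  ok <- vapply(results, function(f)
    !is.null(f) && isTRUE(f$converged) && is.finite(f$z_average_rh), TRUE)
  rh <- vapply(results, function(f)
    if (!is.null(f) && is.finite(f$z_average_rh)) f$z_average_rh else NA_real_, 1)
  rh[!ok] <- Inf
  .onset_detect(temperatures, rh, ok)
}
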