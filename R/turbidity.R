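## Forward turbidity model (Rayleigh-Debye small-particle limit) and
## cloud-point detection from turbidity-vs-temperature traces.

#' Turbidity-versus-temperature trace
#'
#' @param temperature temperatures in deg C, non-decreasing.
#' @param turbidity turbidity values (cm^-1 or a.u.), same length.
#' @param wavelength probe wavelength in nm.
#' @param salt salt name (text).
#' @param salt_concentration salt concentration (% w/w or mol/kg).
#' @param protein_mass_fraction protein mass fraction.
#' @return object of class `"turbidity_trace"`.
#' @export
turbidity_trace <- function(temperature, turbidity, wavelength = 550,
                            salt = "", salt_concentration = NA_real_,
                            protein_mass_fraction = NA_real_) {
  .stopifnot_num(temperature, "temperature")
  if (any(diff(temperature) < 0)) stop("'temperature' must be non-decreasing")
  .stopifnot_num(turbidity, "turbidity")
  if (length(turbidity) != length(temperature))
    stop("'temperature' and 'turbidity' lengths differ")
  structure(list(temperature = as.numeric(temperature),
                 turbidity = as.numeric(turbidity), wavelength = wavelength,
                 salt = salt, salt_concentration = salt_concentration,
                 protein_mass_fraction = protein_mass_fraction),
            class = "turbidity_trace")
}

#' @export
print.turbidity_trace <- function(x, ...) {
  cat(sprintf("Turbidity trace: %d points, %g-%g degC%s\n",
              length(x$temperature), min(x$temperature), max(x$temperature),
              if (nzchar(x$salt))
                sprintf(", %s %g", x$salt, x$salt_concentration) else ""))
  invisible(x)
}

#' Forward turbidity of a dilute scatterer solution
#'
#' Rayleigh-Debye turbidity of small scatterers,
#' `tau = Q * (32 pi^3 / 3) * n0^2 * c * M * (dn/dc)^2 / (N_A lambda^4)`,
#' with the wavelength converted to cm so that `tau` comes out in cm^-1.
#' The transmittance dissipation factor `Q` is close to 1 for scatterers
#' small relative to the wavelength.
#'
#' @param c protein concentration in g/cm^3.
#' @param M scatterer molar mass in g/mol.
#' @param dn_dc refractive-index increment in cm^3/g.
#' @param wavelength wavelength in nm.
#' @param n0 solvent refractive index (default 1.33).
#' @param Q transmittance dissipation factor in `(0, 1]` (default 1).
#' @return turbidity in cm^-1.
#' @export
turbidity_forward <- function(c, M, dn_dc, wavelength, n0 = 1.33, Q = 1) {
  .stopifnot_num(c, "c"); if (any(c < 0)) stop("'c' must be >= 0")
  .stopifnot_num(M, "M", positive = TRUE)
  .stopifnot_num(dn_dc, "dn_dc", positive = TRUE)
  .stopifnot_num(wavelength, "wavelength", positive = TRUE)
  .stopifnot_num(n0, "n0", positive = TRUE)
  if (Q <= 0 || Q > 1) stop("'Q' must lie in (0, 1]")
  lambda_cm <- wavelength * 1e-7
  Q * (32 * pi^3 / 3) * n0^2 * c * M * dn_dc^2 / (.const$N_A * lambda_cm^4)
}

#' Turbidity from raw transmittance
#'
#' Converts transmitted-intensity readings to turbidity,
#' `-ln(T / T0) / pathlength`.
#'
#' @param transmittance transmitted intensity (or fraction).
#' @param reference reference (incident or initial) intensity, default 1.
#' @param pathlength optical path length in cm, default 1 (10 mm cell).
#' @return turbidity in cm^-1.
#' @export
turbidity_from_transmittance <- function(transmittance, reference = 1,
                                         pathlength = 1) {
  .stopifnot_num(transmittance, "transmittance", positive = TRUE)
  .stopifnot_num(pathlength, "pathlength", positive = TRUE)
  -log(transmittance / reference) / pathlength
}

#' Detect the cloud point of a turbidity trace
#'
#' The baseline mean and standard deviation are estimated from the first
#' `baseline_fraction` of points; the cloud point is the first temperature at
#' which the turbidity exceeds `mean + k_sigma * sd` for `persistence`
#' consecutive points. The rule is invariant to affine rescaling of the
#' turbidity axis. A trace whose baseline window itself trends upward beyond
#' the noise (no stable background) is rejected.
#'
#' @param trace a [turbidity_trace()].
#' @param baseline_fraction fraction of leading points used for the baseline
#'   (default 0.25).
#' @param k_sigma detection threshold in baseline standard deviations
#'   (default 5).
#' @param persistence number of consecutive points required above threshold
#'   (default 3).
#' @return cloud-point temperature in deg C, or `NULL` when no onset occurs.
#' @export
detect_cloud_point <- function(trace, baseline_fraction = 0.25, k_sigma = 5,
                               persistence = 3) {
  stopifnot(inherits(trace, "turbidity_trace"))
  y <- trace$turbidity; temp <- trace$temperature
  n <- length(y)
  if (n < 8) stop("at least 8 points are required for cloud-point detection")
  nb <- max(3, floor(baseline_fraction * n))
  base <- y[seq_len(nb)]
  # baseline flatness: reject if the linear trend over the window exceeds the
  # residual scatter by the detection factor (no stable background level)
  tf <- stats::lsfit(temp[seq_len(nb)], base)
  trend <- abs(tf$coefficients[2]) * diff(range(temp[seq_len(nb)]))
  resid_sd <- stats::sd(tf$residuals)
  if (is.finite(resid_sd) && resid_sd > 0 && trend > k_sigma * resid_sd)
    stop("no stable baseline: turbidity rises from the start of the trace")
  thr <- mean(base) + k_sigma * stats::sd(base)
  if (!is.finite(thr)) thr <- mean(base)
  above <- y > thr
  run <- 0L
  for (i in (nb + 1):n) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= persistence) return(temp[i - persistence + 1L])
  }
  NULL
}
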