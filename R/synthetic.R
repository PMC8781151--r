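## Seeded generators for every input stream the pipeline consumes. Defaults
## are anchored to the scale of native silk feedstock experiments: a 12.5 nm
## coil, a ~90 nm aggregate mode appearing above the ~65 degC onset, an
## amide II band drifting 1545 -> 1540 cm^-1 over 27 -> 81 degC, and
## cloud-point sets generated from the fitted shell state (-69.7, 0.2, 57.9).
## Noise is multiplicative for scattering (counting-like statistics) and
## additive for spectra, turbidity and g2, with defaults giving SNR ~ 20.
## Identical arguments + seed give identical output; the caller's RNG state
## is never disturbed.

#' Synthetic small-angle scattering temperature series
#'
#' Debye curves for a random coil of radius `rg`, with multiplicative
#' Gaussian noise. At and above the aggregation onset temperature a second,
#' much larger Debye component (`rg_aggregate`) is added with a weight that
#' grows with temperature, emulating the rise of low-q intensity on
#' aggregation.
#'
#' @param temperatures series temperatures in deg C.
#' @param rg single-chain radius of gyration, nm.
#' @param i0 forward intensity of the single-chain component (a.u.).
#' @param onset aggregation onset temperature in deg C (`Inf` for none).
#' @param rg_aggregate radius of gyration of the aggregate component, nm.
#' @param aggregate_scale forward-intensity multiple of the aggregate
#'   component at the onset (default 30; 0 disables aggregation).
#' @param q scattering-vector grid in nm^-1.
#' @param noise multiplicative noise standard deviation (default 0.05).
#' @param seed optional RNG seed.
#' @return list of [scattering_curve()] objects, one per temperature.
#' @export
gen_scattering_series <- function(temperatures = seq(25, 80, by = 5),
                                  rg = 12.5, i0 = 100, onset = 65,
                                  rg_aggregate = 80, aggregate_scale = 30,
                                  q = seq(0.05, 2, length.out = 120),
                                  noise = 0.05, seed = NULL) {
  .stopifnot_num(q, "q", positive = TRUE)
  if (noise < 0) stop("'noise' must be >= 0")
  with_seed(seed, lapply(temperatures, function(T_C) {
    I <- debye_intensity(q, i0, rg)
    if (is.finite(onset) && T_C >= onset && aggregate_scale > 0) {
      w <- aggregate_scale * (1 + (T_C - onset) / 5)
      I <- I + debye_intensity(q, w * i0, rg_aggregate)
    }
    sig <- pmax(noise * I, 1e-12)
    if (noise > 0) I <- I * (1 + stats::rnorm(length(q), 0, noise))
    scattering_curve(q, I, sigma = sig, temperature = T_C,
                     label = sprintf("synthetic %g degC", T_C))
  }))
}

#' Synthetic DLS temperature series
#'
#' Monomodal decays for a `rh` nm coil below the onset temperature; bimodal
#' (coil + aggregate mode) at and above it, with additive Gaussian noise on
#' `g2`.
#'
#' @param temperatures series temperatures in deg C.
#' @param rh single-chain hydrodynamic radius, nm.
#' @param rh_aggregate aggregate-mode radius, nm.
#' @param onset onset temperature in deg C (`Inf` for none).
#' @param aggregate_weight intensity weight of the aggregate mode above the
#'   onset (default 0.5).
#' @param lag lag-time grid in s.
#' @param beta coherence factor.
#' @param noise_sd additive noise standard deviation on `g2`.
#' @param seed optional RNG seed.
#' @return list of [autocorrelation()] records, one per temperature.
#' @export
gen_dls_series <- function(temperatures = seq(25, 80, by = 5), rh = 12.5,
                           rh_aggregate = 90, onset = 65,
                           aggregate_weight = 0.5,
                           lag = 10^seq(-7, -2, length.out = 100),
                           beta = 0.9, noise_sd = 0.002, seed = NULL) {
  with_seed(seed, lapply(temperatures, function(T_C) {
    if (is.finite(onset) && T_C >= onset && aggregate_weight > 0) {
      sizes <- c(rh, rh_aggregate)
      w <- c(1 - aggregate_weight, aggregate_weight)
    } else { sizes <- rh; w <- 1 }
    simulate_g2(sizes, w, lag = lag, temperature = T_C, beta = beta,
                noise_sd = noise_sd, seed = NULL)
  }))
}

#' Synthetic amide-region IR temperature series
#'
#' Two Gaussian bands (near 1640 and 1545 cm^-1) on a linear baseline; the
#' amide II center drifts linearly with temperature between the endpoints of
#' `drift` over the temperature range, while the 1640 cm^-1 band stays put.
#' Additive Gaussian noise.
#'
#' @param temperatures series temperatures in deg C.
#' @param wavenumber wavenumber grid in cm^-1.
#' @param amide_i_center center of the fixed band, cm^-1.
#' @param drift amide II center at the first and last temperature,
#'   cm^-1 (default `c(1545, 1540)` over 27-81 deg C).
#' @param amplitudes amplitudes of the two bands (a.u.).
#' @param widths Gaussian width parameters Delta of the two bands, cm^-1
#'   (sigma = sqrt(2) Delta).
#' @param baseline `c(intercept, slope)` of the linear baseline.
#' @param noise_sd additive noise standard deviation (a.u.).
#' @param seed optional RNG seed.
#' @return list of [spectrum()] objects with temperature tags.
#' @export
gen_ir_series <- function(temperatures = seq(27, 81, by = 6),
                          wavenumber = seq(1400, 1800, by = 1),
                          amide_i_center = 1640, drift = c(1545, 1540),
                          amplitudes = c(0.5, 0.35), widths = c(13, 11),
                          baseline = c(0.02, 0), noise_sd = 0.004,
                          seed = NULL) {
  tr <- range(temperatures)
  frac <- if (diff(tr) > 0) (temperatures - tr[1]) / diff(tr) else
    rep(0, length(temperatures))
  centers2 <- drift[1] + frac * (drift[2] - drift[1])
  with_seed(seed, lapply(seq_along(temperatures), function(i) {
    comp <- data.frame(amplitude = amplitudes,
                       center = c(amide_i_center, centers2[i]),
                       width = widths)
    mod <- peak_model(baseline[1], baseline[2], comp,
                      window = range(wavenumber))
    s <- evaluate_peak_model(mod, wavenumber)
    ab <- s$absorbance
    if (noise_sd > 0) ab <- ab + stats::rnorm(length(ab), 0, noise_sd)
    spectrum(wavenumber, ab, temperature = temperatures[i],
             label = sprintf("synthetic %g degC", temperatures[i]))
  }))
}

#' Synthetic turbidity trace
#'
#' Flat noisy baseline followed, from the onset temperature, by a sigmoidal
#' rise `amplitude * (2 / (1 + exp(-(T - onset)/steepness)) - 1)` (zero
#' exactly at the onset, saturating at `amplitude`).
#'
#' @param temperature temperature grid in deg C.
#' @param onset onset temperature in deg C.
#' @param amplitude rise amplitude (a.u.); 0 gives a flat trace.
#' @param steepness rise scale in deg C (default 0.2, a sharp cloud point).
#' @param baseline baseline turbidity level.
#' @param noise_sd additive noise standard deviation.
#' @param seed optional RNG seed.
#' @param salt,salt_concentration metadata passed to the trace.
#' @return a [turbidity_trace()].
#' @export
gen_turbidity_trace <- function(temperature = seq(20, 70, by = 0.5),
                                onset = 40, amplitude = 1, steepness = 0.2,
                                baseline = 0.02, noise_sd = 0.002,
                                seed = NULL, salt = "NaCl",
                                salt_concentration = NA_real_) {
  .stopifnot_num(steepness, "steepness", positive = TRUE)
  rise <- ifelse(temperature < onset, 0,
                 amplitude * (2 / (1 + exp(-(temperature - onset) / steepness)) - 1))
  y <- baseline + rise
  if (noise_sd > 0)
    y <- with_seed(seed, y + stats::rnorm(length(y), 0, noise_sd))
  turbidity_trace(temperature, y, salt = salt,
                  salt_concentration = salt_concentration)
}

## default three-level replicated concentration design per salt (mol/kg):
## levels chosen so that cloud points span roughly -7 to 69 degC under the
## default shell state (low / mid / high water activity)
.default_cloud_design <- list(
  NaCl = rep(c(0.015, 0.75, 1.76), c(3, 4, 3)),
  KCl  = rep(c(0.015, 0.78, 1.86), c(3, 4, 3)))

#' Synthetic cloud-point set from a ground-truth shell state
#'
#' For each salt concentration, the true cloud point solves
#' `mu_hyd(T) = mu_w(T) + R T_K ln(a)` with `a` from the packaged
#' water-activity table; Gaussian noise of `temp_noise_sd` deg C is then
#' added to the temperature. Concentrations whose curves do not cross in
#' `(-10, 100)` deg C are reported via a warning and an attribute, never
#' silently dropped. The default design places replicated points at three
#' concentration levels per salt, spanning cloud points from about -7 to
#' 69 deg C.
#'
#' @param params ground-truth [hydration_params()].
#' @param molality named list of molality vectors per salt (names must match
#'   packaged activity tables).
#' @param temp_noise_sd temperature noise standard deviation in deg C
#'   (default 0.3).
#' @param seed optional RNG seed.
#' @param water_curve water-curve [quadratic_mu()].
#' @return a [cloud_points()] data frame with a `concentration` column; any
#'   non-crossing concentrations are listed in `attr(, "no_crossing")`.
#' @export
gen_cloud_points <- function(params = hydration_params(-69.7, 0.2, 57.9),
                             molality = .default_cloud_design,
                             temp_noise_sd = 0.3, seed = NULL,
                             water_curve = mu_water_curve()) {
  stopifnot(inherits(params, "hydration_params"))
  if (temp_noise_sd < 0) stop("'temp_noise_sd' must be >= 0")
  rows <- list(); missed <- list()
  for (salt in names(molality)) {
    ms <- molality[[salt]]
    if (length(ms) == 0) next
    tab <- salt_activity_table(salt)
    a <- water_activity(tab, ms)
    for (j in seq_along(ms)) {
      f <- function(T_C) mu_hydration(T_C, params) -
        mu_solution(T_C, a[j], curve = water_curve)
      root <- tryCatch(.bracketed_root(f, -10, 100, tol = 1e-8),
                       error = function(e) NULL)
      if (is.null(root)) {
        missed[[length(missed) + 1L]] <-
          data.frame(salt = salt, molality = ms[j])
      } else {
        rows[[length(rows) + 1L]] <-
          data.frame(temperature = root, water_activity = a[j], salt = salt,
                     concentration = ms[j], weight = 1)
      }
    }
  }
  if (length(missed))
    warning(sprintf("%d concentration(s) give no shell-solution crossing in (-10, 100) degC",
                    length(missed)))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(temperature = numeric(), water_activity = numeric(),
               salt = character(), concentration = numeric(),
               weight = numeric())
  if (temp_noise_sd > 0 && nrow(out))
    out$temperature <- with_seed(seed,
      out$temperature + stats::rnorm(nrow(out), 0, temp_noise_sd))
  class(out) <- c("cloud_points", "data.frame")
  attr(out, "no_crossing") <- if (length(missed)) do.call(rbind, missed) else NULL
  out
}
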