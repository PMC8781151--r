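# Independent oracles used across tests.

# brute-force root location: finest sign change on a fixed-resolution grid
grid_scan_root <- function(f, lo, hi, by = 0.01) {
  grid <- seq(lo, hi, by = by)
  vals <- vapply(grid, f, numeric(1))
  sgn <- sign(vals)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(flip)) return(NULL)
  # midpoint of the bracketing cell
  (grid[flip[1]] + grid[flip[1] + 1]) / 2
}

# analytic cumulants of a finite exponential mixture:
# g1(tau) = sum w_i exp(-G_i tau); Gamma = sum w G, mu2 = sum w G^2 - Gamma^2
mixture_cumulants <- function(weights, gammas) {
  w <- weights / sum(weights)
  G <- sum(w * gammas)
  list(gamma = G, mu2 = sum(w * gammas^2) - G^2)
}

# Stokes-Einstein decay rate (1/s) for a sphere of radius rh (nm) at the
# default instrument geometry, written independently of the package internals
oracle_gamma <- function(rh, temperature = 25, angle = 173, wavelength = 633,
                         n = 1.33, viscosity = NULL) {
  eta <- if (is.null(viscosity)) silksol::water_viscosity(temperature) else viscosity
  q <- 4 * pi * n * sin(angle / 2 * pi / 180) / wavelength   # nm^-1
  D <- 1.380649e-23 * (temperature + 273.15) /
    (6 * pi * eta * 1e-3 * rh * 1e-9) * 1e18                 # nm^2/s
  D * q^2
}
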