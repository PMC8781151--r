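---
title: "The hydration-shell model of silk fibroin solubility: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hydration-shell model of silk fibroin solubility: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silksol)
```

## The scientific problem

Native silk feedstock (NSF) is the concentrated aqueous fibroin solution
stored in the silkworm gland (~23% w/w protein). In dilute solution the
fibroin chain behaves as a random coil under near-theta conditions, and the
protein stays dissolved because the water hydrogen-bonded to its peptide
backbone — the *hydration shell* — is thermodynamically more stable than bulk
water. Heating, freezing or salting out destabilises that shell; once the
chemical potential of shell water exceeds that of the surrounding bulk phase,
water is released, peptide-peptide hydrogen bonds form and the solution gels
or aggregates.

`silksol` implements that analysis end to end: coil-size arithmetic, Debye
fits of small-angle scattering, cumulant analysis of dynamic light
scattering, amide-band tracking in infrared spectra, turbidity cloud-point
detection, and the central three-parameter thermodynamic model of the shell.

## The model

All thermodynamics is per mole of water. The chemical potential of water in
a salt solution follows from its activity $a_w = p/p^{\#}$:

$$\mu_w(T, a_w) = \mu_w^{\#}(T) + R\,T_K \ln a_w,$$

with $\mu_w^{\#}$ the pure-water curve and $T_K$ the absolute temperature.
The pure-water and ice curves are the empirical quadratics (J mol$^{-1}$,
$T$ in $^\circ$C, referenced to the triple point):

$$\mu_{ice}(T) = 10.286 + 22.186\,T - 0.0717\,T^2, \qquad
  \mu_{water}(T) = 8.038 - 0.7842\,T - 0.1167\,T^2.$$

The hydration shell is described by three parameters — the enthalpy and
entropy offsets from bulk water at the reference temperature
$T_0 = 273.15$ K, and a constant molar heat capacity of shell water:

$$\mu_{hyd}(T) = \Delta H_{hyd}(T) - T_K\,\Delta S_{hyd}(T), \qquad
  \Delta H_{hyd}(T) = \Delta H^0 + C_p (T_K - T_0), \qquad
  \Delta S_{hyd}(T) = \Delta S^0 + C_p \ln (T_K / T_0).$$

A cloud or aggregation point observed at temperature $T_i$ in a solution of
water activity $a_i$ is interpreted as the condition
$\mu_{hyd}(T_i) = \mu_w(T_i, a_i)$. `hydration_fit()` estimates
$(\Delta H^0, \Delta S^0, C_p)$ by least squares on the chemical-potential
scale. Because $\mu_{hyd}$ is *linear* in all three parameters, the fit is a
deterministic linear least-squares solve — no starting values, no local
minima.

Relative (shell-minus-bulk) quantities use a constant bulk heat capacity
$c_{p,w} = 75.7$ J mol$^{-1}$ K$^{-1}$, so that
$\Delta C_p = c_{p,w} - C_p$ and

$$\Delta H_{rel}(T) = \Delta H^0 - \Delta C_p (T_K - T_0), \qquad
  \Delta S_{rel}(T) = \Delta S^0 - \Delta C_p \ln(T_K/T_0), \qquad
  \Delta G = \Delta H_{rel} - T_K\,\Delta S_{rel}.$$

$\Delta G = 0$ on heating marks the gelation temperature
(`gelation_temperature_heating()`); the crossing of $\mu_{hyd}$ with the ice
curve below 0 $^\circ$C marks gelation on freezing
(`gelation_temperature_freezing()`); $|\Delta H_{rel}|$ at the heating root
is the enthalpy penalty of releasing shell water
(`enthalpy_penalty_at_gelation()`).

### Temperature-unit conventions

The empirical quadratics take $T$ in $^\circ$C, exactly as they are stated.
The shell expressions use Kelvin inside both the enthalpy increment and the
log ratio, with $T_0 = 273.15$ K: a Celsius log ratio would be undefined at
0 $^\circ$C, while temperature *differences* are unit-invariant. The two
conventions are documented on every function and meet consistently in the
fit.

An alternative convention for the $\Delta G$ baseline would difference the
shell curve against the quadratic water curve itself rather than against a
constant-$c_p$ bulk reference; the two give crossings a couple of degrees
apart (about 70 versus 67.6 $^\circ$C). The constant-75.7 convention is used
for all relative quantities because it makes $\Delta C_p$ explicit and keeps
$\Delta G$ a three-parameter expression.

## Fitting cloud-point data

* **Objective.** Vertical (chemical-potential) residuals at the observed
  temperatures, unit weights by default. A `weight` column on the data is
  honoured.
* **Temperature noise.** The dominant experimental error is in the measured
  cloud-point temperature, not in the activity. A temperature error
  $\sigma_T$ maps onto a *heteroscedastic* potential residual with standard
  deviation $\sigma_T\,|d(\mu_{hyd}-\mu_w)/dT|$ at each point. With
  `t_noise_sd > 0`, `hydration_fit()` iterates effective-variance weights
  (four passes) — the standard errors-in-variables treatment when the
  predictor error is known.
* **Study design.** The default synthetic design
  (`gen_cloud_points()`) places replicated points at three concentration
  levels per salt (NaCl and KCl), spanning cloud points from roughly
  $-7$ to $69\ ^\circ$C — mirroring a study that anchors the curve with
  sub-zero freezing-gelation points as well as high-temperature turbidity
  points. The three-level, extreme-leaning placement was chosen by a
  standard-error analysis of the linear design matrix: the basis functions
  $1$, $-T_K$ and $(T_K - T_0) - T_K\ln(T_K/T_0)$ are strongly collinear
  over a narrow temperature span, and only a wide, end-weighted design
  separates $\Delta H^0$ from $\Delta S^0$ at realistic noise
  ($\sigma_T = 0.3\ ^\circ$C).
* **Water activities.** Packaged tables for NaCl (0-6 mol/kg) and KCl
  (0-4.8 mol/kg) compiled from standard 25 $^\circ$C osmotic-coefficient
  data, $a_w = \exp(-2\phi m M_w/1000)$, linearly interpolated and never
  extrapolated. Temperature dependence of $\phi$ is neglected (a ~1% effect
  over the working range, small against the activity span used).

## The measurement stages

**Scattering (SAXS/SANS).** The Debye form factor
$I(q) = 2 I_0 (e^{-x} + x - 1)/x^2$, $x = q^2 R_G^2$, is fitted on the
linear intensity scale by Levenberg-Marquardt, weighted $1/\sigma^2$ when
uncertainties are present and unweighted otherwise (log-space fitting is
deliberately not used). Initial values come from a Guinier analysis with a
fallback of $R_G = 2\pi/q_{max}$. The Guinier fit includes a second-order
term in $q^2$ and reports $R_G$ from the linear coefficient: for
Gaussian-chain curves the classic straight-line fit inside $q R_G \le 1.3$
carries a systematic ~5-8% underestimate from curvature that the extended
fit removes (residual bias below 0.5%). The window is re-restricted twice
to $q R_G \le 1.3$ using the running estimate. $q$ is in nm$^{-1}$
throughout; readers convert from Å$^{-1}$ on request.

**Aggregation onset.** Over a temperature series, the onset is the first
temperature at which the fit fails *or* the size estimate exceeds the median
of all prior estimates by 50%, with at least three successful points below
it. The 50%/median rule is an operational definition chosen here; the
phenomenon it encodes is that fits become impossible once aggregates
dominate. The same rule serves the DLS $R_H$ series.

**DLS.** Second-order cumulant analysis,
$\ln(g_2 - 1) = \ln\beta - 2\Gamma\tau + \mu_2\tau^2$, fitted over the
leading lags where the correlation amplitude is above 10% of the intercept;
$R_H$ via Stokes-Einstein at the record's temperature and viscosity (water
viscosity from a packaged handbook table, linear interpolation, 1.002 mPa s
at 20 $^\circ$C). The polydispersity index $\mu_2/\Gamma^2$ is clamped at
zero. The 10% amplitude cut-off trades bias for noise robustness: for
strongly bimodal decays the finite window biases $\Gamma$ a few percent
below the analytic first cumulant, which the tests quantify against the
closed-form two-exponential mixture. Instrument defaults are 173$^\circ$,
633 nm, $n = 1.33$.

**Infrared band tracking.** The band model is a linear baseline plus
Gaussians evaluated *exactly* as
$S(\nu) = a + m\nu + \sum_i A_i \exp(-((\nu - \nu_i)/(2\Delta_i))^2)$ —
note $2\Delta$ inside the square, so the usual Gaussian width is
$\sigma = \sqrt{2}\,\Delta$. This half-width convention is preserved
deliberately (re-parameterising it silently would corrupt width comparisons)
and documented on the function. Two components in a 1450-1750 cm$^{-1}$
window (the band near 1640 cm$^{-1}$ plus amide II) are the default; fits
use five restarts from deterministically alternated center offsets (0,
$\mp5$, $\pm2.5$ cm$^{-1}$), keeping the best converged solution. Series
fits warm-start from the previous temperature and propagate failures as
gaps. Restart-to-restart center agreement on well-conditioned data is
within 0.1 cm$^{-1}$.

**Turbidity.** The forward model is the small-particle Rayleigh-Debye
turbidity $\tau = Q\,(32\pi^3/3)\, n_0^2\, c M (dn/dc)^2 / (N_A \lambda^4)$
with $Q = 1$ by default ($Q$ lies between 0.99 and 1 for scatterers small
against the wavelength). Cloud points are detected as the first temperature
at which turbidity exceeds the baseline mean plus $5\sigma$ for three
consecutive points, with the baseline estimated from the first quarter of
the trace; a trace whose baseline window itself trends upward beyond the
noise is rejected as having no stable background. The rule is invariant to
affine rescaling of the turbidity axis. The specific threshold constants
are operational choices made here.

## Synthetic data: what it emulates, and what it does not

Every input stream has a seeded generator whose defaults are anchored to the
scale of the real system: a 12.5 nm coil with a large-aggregate scattering
component appearing at 65 $^\circ$C; monomodal 12.5 nm DLS decays turning
bimodal (12.5 + 90 nm) above the onset; amide II drifting 1545 to 1540
cm$^{-1}$ over 27-81 $^\circ$C; sharp sigmoidal turbidity onsets; and
cloud-point sets generated from the shell state
$(-69.7, 0.2, 57.9)$ through the packaged salt-activity tables. Noise is
multiplicative for scattering (counting-like) and additive elsewhere, with
default amplitudes giving a signal-to-noise ratio near 20. Generators are
byte-deterministic in their seed and restore the caller's RNG state.

Passing the round-trip and recovery tests therefore demonstrates that the
estimators invert the stated forward models at realistic noise — it does not
demonstrate robustness to instrument artefacts the generators deliberately
omit: ATR penetration-depth effects, detector nonlinearity, multiple
scattering, number fluctuations near the cloud point, hysteresis, or
concentration drift. The turbidity generator's rise is zero exactly at the
configured onset (a delayed logistic), which makes "detected within one grid
step" a well-defined claim; real cloud points have no such sharp ground
truth.

## Numerical choices

* Root-finding for gelation temperatures: a 0.5 $^\circ$C sign-change scan
  (rejecting multiple crossings) followed by Brent bracketing to
  0.01 $^\circ$C; tests verify agreement with an independent 0.01 $^\circ$C
  grid-scan oracle to 0.02 $^\circ$C.
* The Debye function switches to its series expansion for
  $x < 10^{-4}$ to avoid cancellation; its $q = 0$ limit is exact.
* Grid alignment (background subtraction, water subtraction, salt tables,
  viscosity) is always piecewise-linear interpolation, never smoothing, and
  never extrapolation.
* Physical constants: $N_A$ (CODATA), $k_B$ (CODATA),
  $R = 8.314$ J mol$^{-1}$ K$^{-1}$, $M_{w} = 18.015$ g mol$^{-1}$.
* Coil density uses the uniform-sphere-of-equal-$R_G$ convention
  ($R = \sqrt{5/3}\,R_G$), which reproduces the quoted ~0.045 g cm$^{-3}$
  for the 419.6 kDa chain at $R_G = 12$ nm to within 0.5%; the convention is
  stated because other choices (e.g. a sphere of radius $R_G$) give
  materially different numbers.

## Problem sizes

The shipped tests and the demonstration pipeline run on deliberately modest
sizes, chosen as the smallest that exercise every claim: 120-150 point
scattering curves, 100-lag correlation records, 400-point spectra, 101-point
turbidity traces, and cloud-point sets of 20-40 points with 20 replicates
for the parameter-recovery checks. All of them complete in well under a
minute on a single core; `run_pipeline()` executes the full synthetic
analysis in a few seconds.

## Known limitations

* The model treats $C_p$ of shell water as constant; the real bulk value
  varies by ~1% over 0-100 $^\circ$C.
* $\Delta S^0$ is intrinsically poorly determined: it is small (0.2
  J mol$^{-1}$ K$^{-1}$) and nearly collinear with $\Delta H^0$ over any
  practical temperature span, so its relative uncertainty is large even in
  well-designed studies.
* Only cumulant DLS analysis is provided; no inverse-Laplace size
  distributions.
* No Mie or wavelength-resolved corrections to the turbidity model; no
  absolute-intensity calibration or 2-D reduction on the scattering side.
* Salt activities are 25 $^\circ$C compilations; strongly
  temperature-dependent electrolytes would need their own tables.

## Interfaces

The package is a library: the fitting functions, the generators,
`run_pipeline()` (YAML/JSON-configurable, JSON results) and
`report_acceptance()` are the programmatic surface, and
`scripts/acceptance.R` recomputes the headline predictions from the command
line. Delimited-text readers cover scattering curves, correlation records,
spectra (including minimal JCAMP-DX), turbidity traces and cloud-point
tables.
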