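---
title: "Methods: models, estimators and design choices in cellugel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in cellugel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellugel)
```

cellugel compares the structure of enzymatically synthesized cellulose II
gels across growth conditions using four independent measurement
modalities. This vignette documents the underlying models, the estimators
and their assumptions, the numerical choices that are not forced by the
science, and what the synthetic-data validation does and does not
demonstrate.

## The two-level unified scattering model

Small-angle scattering from CDP-cellulose gels shows at least two
structural populations: large aggregates tens of nanometres across, and
the lamellar crystallites a few nanometres thick whose Guinier knee
produces a Kratky peak near Q ≈ 0.9 nm⁻¹. A single Guinier analysis fails
on such mixtures, so intensities are modelled with the unified
Guinier/power-law form with two levels:

$$I(Q) = bkg + \sum_{i=1}^{2}\left[G_i e^{-Q^2 Rg_i^2/3} +
  B_i e^{-Q^2 Rg_{i+1}^2/3}\left(\frac{1}{Q_i^*}\right)^{P_i}\right],
\qquad Q_i^* = \frac{Q}{[\mathrm{erf}(Q\,Rg_i/\sqrt 6)]^{3}}$$

Each level contributes a Guinier exponential (prefactor $G_i$, radius of
gyration $Rg_i$ in nm) and a power law (prefactor $B_i$, exponent $P_i$)
whose error-function rescaling $Q_i^*$ switches it off below the level's
own Guinier knee; the $e^{-Q^2 Rg_{i+1}^2/3}$ factor cuts it off above the
next smaller level's knee. We fix $Rg_3 = 0$, so the smallest level's
power law has no high-Q cutoff — the standard convention for the lowest
level, and the published parameter tables for this system list no third
radius. $Rg_3$ is exposed as a constant, never a free parameter.

Power-law exponents near 2 indicate thin plate-like scatterers; the
built-in reference parameters give a model slope of about $Q^{-2.35}$ over
0.07–0.5 nm⁻¹ (`local_power_law_slope()`), consistent with platelet
lamellae.

### Evaluation and its validation

`evaluate_unified_model()` computes the power-law term in log space
($\exp(-Q^2Rg_{i+1}^2/3 - P_i \log Q_i^*)$), so that at small Q, where
$Q_i^* \propto Q^{-2} \to \infty$, large exponents underflow to zero
instead of overflowing; $Q^*$ itself is returned as $Q/\mathrm{erf}^3$,
which preserves $Q^* \ge Q$ exactly in floating point. The implementation
is validated against an independent 50-digit-arithmetic transcription of
the model (100 random parameter/Q draws frozen into the test fixtures
before the implementation was written), and against the analytic limit
$I(Q\to 0) = bkg + G_1 + G_2$.

### Fitting

`fit_unified_model()` minimizes weighted residuals with bounded
Levenberg–Marquardt (minpack.lm). Two weightings are offered:

* `"sigma"` (default when uncertainties exist): $(I_{obs} - I_{model})/\sigma$.
  For curves from the synthetic generator, $\sigma = noise \cdot I_{model}$,
  so a correct fit gives $\chi^2/\mathrm{point} \approx 1$.
* `"none"`: residuals on log intensity. A SAXS curve spans several decades;
  unweighted linear residuals would let the lowest-Q decade dominate
  completely, while log residuals give each decade comparable leverage.
  Which weighting was used in the original analyses of this system is not
  recorded, so the choice is exposed.

The level ordering $Rg_1 > Rg_2$ is enforced through box bounds that split
the two radii at the geometric mean of their initial values. Reported
uncertainties are 1-σ values from the covariance at the optimum. Because
the fitted surface has shallow local minima in the $Rg_1$/$P_1$ trough,
the optimizer always takes two additional deterministic restarts from
perturbed starting points and keeps the lowest-deviance solution;
further restarts are taken only if convergence is not reported.

One genuine identifiability limit is worth stating plainly: with the
measured window 0.07–2.5 nm⁻¹, the level-1 Guinier knee
($\sqrt 3/Rg_1 \approx 0.05$ nm⁻¹ for $Rg_1 = 34.4$ nm) lies *below* the
lowest measured Q. At 2% noise the global least-squares optimum for a
particular noise realization can therefore place $Rg_1$ tens of percent
away from the generating truth — this is a property of the data window,
not of the optimizer, which is why parameter-recovery quality for the
radii is quantified as a median over 20 seeded replicates (medians run
about 2–6% for both radii) rather than promised per realization. $Rg_2$,
whose knee sits well inside the window, is much better determined.

## WAXS peak quantification

The working assumption is that solvent (water) scattering across
5–16 nm⁻¹ is smooth and monotone and forms no peak, so everything peaked
above it is crystalline diffraction. `estimate_smooth_background()` fits
polynomials of degree 1–4 to the points outside the peak windows and
selects the degree by BIC; when the out-of-window data are monotone, only
monotone candidates are eligible (degree 1 always is). BIC matters in one
specific geometry: the 020 window (15.6 ± 0.8 nm⁻¹) touches the upper end
of the measured range, so the polynomial extrapolates there, and an
over-fitted quartic extrapolates erratically under noise where a
BIC-selected lower degree stays stable.

Peaks are fitted per window as single Gaussians on the
background-subtracted profile; `area = amplitude × FWHM × √(π/(4 ln 2))`.
The peak shape is a modelling choice (the published analyses do not state
a profile function); a Gaussian is sufficient for the recovery tests and
consistent with the smooth-background assumption. Windows default to
± 0.8 nm⁻¹ around the cellulose II positions and are configurable;
backgrounds are fitted per profile, never shared across capillary
positions. Positions convert to lattice spacings by d = 2π/Q (Å after the
nm conversion) and to scattering angles by 2θ = 2 arcsin(Qλ/4π) with
λ = 0.92 Å by default; FWHMs in 2θ are converted endpoint-wise so the
arcsine nonlinearity is respected. Reflection assignment takes the nearest
reference plane within a 2% relative tolerance, one-to-one, ties toward
the smaller reference spacing.

Position averages are reported both at full precision and rounded to a
caller-stated number of decimals, because printed reference tables carry
heterogeneous precision (an integer area next to one-decimal areas) that
cannot be inferred from the numeric values themselves.

## MALDI degree of polymerization

Cellodextrin series peaks sit on the mass comb
$m_n = 162.14\,n + m_{adduct}$. The default adduct offset is 41.0 Da
(water 18.0 + sodium 23.0), i.e. sodiated oligosaccharides — the common
MALDI species for this chemistry. The offset is an inference: applied to
the reported mean molecular weights 1160 and 1072 Da it gives DP 6.90 and
6.36 against the reported 6.89 and 6.35 (within 0.03), but the original
convention is not recorded, so the offset is configurable and the
inference is documented rather than asserted. The residue mass 162.14 Da
is the average anhydroglucose mass; reported "162 Da" spacings are treated
as rounded.

Peak picking takes local maxima above a robust floor (median + 5 × MAD of
the whole spectrum — no peak-picking criterion is recorded for the
original analyses, and this floor is scale-invariant), matches them to the
comb within a tolerance (default 8 Da), and keeps the longest consecutive
run of degrees of polymerization. The envelope is fitted as a Gaussian in
m/z through the peak tops — in m/z rather than in DP index because mean
molecular weight is the primary reported quantity; mean DP is derived
afterwards. Note one interaction: with the default envelope width
(σ = 1.2 DP units) the DP-10/11 tail peaks are genuinely below the robust
floor once baseline noise is present, so noisy spectra yield a central
subset of the series; envelope-mean recovery stays unbiased (< 0.05 DP
over 20 seeds at 5% noise) because the Gaussian fit uses whichever tops
are detected.

## Ribbon-width morphometry

Micrographs are segmented by Otsu's threshold (or a fixed one), cleaned of
objects under 20 px and holes under 20 px, and thinned to an 8-connected
skeleton with Zhang–Suen iterations (written in vectorized R; no installed
package provides thinning). At each skeleton pixel the diameter sample is

$$d = (2\,\mathrm{EDT}_{ridge} - 0.5) \times \mathrm{pixel\ size}$$

where EDT is the Euclidean distance transform of the mask and
$\mathrm{EDT}_{ridge}$ is its maximum over the pixel's 3 × 3
neighbourhood. The two corrections are deliberate: the thinned skeleton
can sit a pixel off the true medial ridge on oblique fibers (the
neighbourhood maximum recovers the ridge value), and the EDT measures to
background pixel *centers*, about half a pixel beyond the true boundary,
while the best lattice ridge point sits about a quarter pixel inside the
medial axis — a net half-pixel correction. Calibrated on rasterized
continuum ribbons, this leaves axis-aligned integer-width ribbons reading
w + 0.5 px and oblique ribbons essentially unbiased; end-to-end recovery
of lognormal width distributions is within a few percent for the mean and
SD.

Skeleton pixels within one local radius (their own EDT value) of an
endpoint or junction are excluded, because the distance transform is
inflated where fibers cross and the skeleton retracts where they end.
Endpoints and junctions are classified by the crossing number — the count
of background-to-foreground transitions around the 8-neighbour ring
(1 = endpoint, ≥ 3 = junction) — which, unlike a raw neighbour count, is
not fooled by the staircase pixels of diagonal skeleton segments. This
exclusion rule is this package's own defined estimator, validated against
constructed fixtures; the exact rule used by the plugin-based analyses it
parallels is unpublished, so published diameter tables are not
reproduction targets.

Statistics follow fixed conventions: sample SD, Fisher skewness $g_1$,
and *excess* kurtosis $g_2$. Excess kurtosis is the only coherent reading
of the published reference statistics for this system: the microgravity
column (skewness 1.31, kurtosis 2.70) would violate the raw-kurtosis
moment bound $k \ge s^2 + 1$ (2.70 < 2.72). The mode is the center of the
fullest histogram bin and therefore depends on the bin width (default
0.05 µm, configurable) — a continuous sample has no unique mode, and the
original binning is not stated. Diameters, not radii, are the canonical
output; conversion happens once, at sampling.

## What the synthetic generators emulate — and what they do not

Every generator is fully seed-deterministic (identical configuration →
bit-identical output), echoes machine-readable ground truth, and reduces
to the exact noiseless forward model at `noise = 0`.

* **SAXS**: multiplicative Gaussian noise with constant fractional error,
  mirroring count-dominated synchrotron data at moderate intensity;
  reported σ equals the true per-point error. Points that would go
  negative are regenerated with the deviate truncated at ± 5 and flagged
  (never clamped); for fractional noise below 0.2 this guarantees
  positive intensities. Not emulated: instrument smearing, incoherent
  background drift, inter-position correlations.
* **WAXS**: polynomial monotone water background plus Gaussian peaks,
  additive noise scaled to the mean clean intensity; peaks closer than
  0.2 × FWHM are generated but flagged unresolvable. Not emulated:
  preferred orientation, amorphous halos, detector artefacts.
* **MALDI**: Gaussian comb with a Gaussian height envelope in DP
  (default mean 6.9, σ = 1.2, support DP 4–11) and one-sided additive
  baseline noise (intensities stay non-negative). The default σ keeps the
  truncated-support envelope-weighted mean within 0.01 of the configured
  mean DP. Not emulated: isotope patterns, matrix peaks, detector
  saturation.
* **Ribbons**: straight, constant-width ribbons with lognormal widths
  parameterized by arithmetic mean and SD (defaults 0.254 and 0.128 µm at
  0.05 µm/px), uniform orientation and length; two-level contrast
  (200 vs 20 of 255) with optional light blur. Widths drawn from the
  distribution are used exactly as drawn — truncating sub-3-px draws
  would bias the echoed truth sample upward by over 10% — while
  *explicitly requested* widths under 3 px are rejected as unmeasurable.
  Not emulated: curvature, branching fibers, width variation along a
  ribbon, charging artefacts. Passing the end-to-end recovery test
  therefore shows the estimator is calibrated for straight dense
  networks, not that curved real-world fibrils are measured without bias.

## Problem sizes and runtime choices

The validation suite uses 300-point SAXS curves with 20 fit replicates,
550-point WAXS profiles with 50 noise seeds, 0.25-Da-grid MALDI spectra
with 20 seeds, and one 1024 × 1024 ribbon network with 300 ribbons
(≈ 20 000 diameter samples). These sizes put every Monte-Carlo estimate
well inside its tolerance while keeping the full suite and the
reproduction script each within about a minute of compute; all are
configuration parameters, not limits.

## Known limitations

* The unified fit reports covariance-based 1-σ errors; whether published
  "±" values for this system are fit errors or replicate spreads is
  unknown, so no equivalence is claimed.
* Pseudo-Voigt peak shapes, Scherrer crystallite sizes and crystallinity
  indices are out of scope for WAXS; the comparisons rest on areas and
  FWHMs only.
* MALDI analysis assumes a single adduct species and no baseline
  correction beyond the robust floor.
* The ribbon estimator assumes locally straight, approximately cylindrical
  fibers; strongly curved or branching structures bias the junction
  exclusion.
* Raw measured curves and micrographs for the reference system are not
  distributed; the built-in tables carry the published per-position
  values, and all estimator validation is against synthetic ground truth.
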