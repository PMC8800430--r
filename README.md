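# cellugel

Quantitative characterization of enzymatically synthesized cellulose II
gels, built to compare gel structure across synthesis conditions — for
instance material grown under microgravity against material grown under
normal gravity. The package is aimed at structural scientists who have
radially integrated X-ray scattering curves, MALDI-ToF spectra and electron
micrographs of cellodextrin-phosphorylase (CDP) cellulose and want the
complete analysis chain as tested, scriptable functions.

Four analysis stages are implemented, each backed by a seeded
synthetic-data generator with exact ground truth:

**SAXS — two-level unified (Beaucage) model.** Scattering curves I(Q) are
described by a sum of two structural levels, each a Guinier exponential
plus an error-function-rescaled power law:

    I(Q) = bkg + Σ_{i=1,2} [ G_i exp(−Q²Rg_i²/3)
                           + B_i exp(−Q²Rg_{i+1}²/3) (1/Q*_i)^{P_i} ]
    Q*_i = Q [erf(Q·Rg_i/√6)]⁻³ ,   Rg_3 = 0

with Q = 4π sin θ/λ in nm⁻¹. Level 1 captures large aggregates (Rg₁ ≈ 30
nm), level 2 the lamellar crystallites (Rg₂ ≈ 4–7 nm) that produce the
Kratky peak near Q ≈ 0.9 nm⁻¹. The package evaluates the model (validated
to ≥ 10 significant digits against a 50-digit arithmetic transcription),
fits it by bounded Levenberg–Marquardt least squares, and provides Kratky
transforms, positional reference subtraction, local power-law slopes and
position-averaged parameter summaries.

**WAXS — crystalline peak quantification.** Water scattering rises
smoothly and forms no peak, so a BIC-selected low-order polynomial fitted
outside the peak windows serves as background; Gaussian peaks fitted on the
excess give areas and FWHMs (in Q and in degrees 2θ). Peak positions are
converted by d = 2π/Q and assigned to the cellulose II reflections
1-10, 110, 020 (d = 7.23, 4.45, 4.03 Å).

**MALDI-ToF — degree of polymerization.** Cellodextrin series peaks at
m_n = 162.14·n + 41.0 Da (sodiated species, anhydroglucose repeat) are
picked above a robust noise floor, and a Gaussian envelope through the peak
tops gives the mean molecular weight and mean DP.

**Micrographs — ribbon-width morphometry.** Fibers are segmented (Otsu),
skeletonized (Zhang–Suen), and diameters sampled from the Euclidean
distance transform along the skeleton, excluding junction and endpoint
neighbourhoods; the full statistic set (mean, SD, mode, median, min, max,
Fisher skewness, excess kurtosis, n) and a histogram are reported.

A pipeline layer (`run_pipeline()`) orchestrates all stages per condition
and capillary position from a YAML configuration and writes deterministic
CSV tables. Published reference values for the microgravity comparison are
built in (`waxs_reference_table()`, `saxs_reference_table()`,
`diameter_reference_table()`, `maldi_reference_table()`).

## Worked example

```r
library(cellugel)

# lamellar-level parameters measured for gel grown under microgravity
truth <- reference_unified_params("space", "upper")

# simulate a 2%-noise SAXS measurement and fit it back
g <- generate_saxs_curve(synth_config("saxs", seed = 1, noise = 0.02,
                                      grid = list(n = 300), truth = truth))
fit <- fit_unified_model(g$curve, truth)
fit
#> unified two-level fit (sigma-weighted): chi2/point = 0.9034, converged
#>   background      0.79615  +/- 0.00902
#>   G1               3607.4  +/- 603
#>   B1              0.69114  +/- 0.0723
#>   Rg1              35.395  +/- 2.49
#>   P1                2.726  +/- 0.0526
#>   G2               57.676  +/- 5.41
#>   B2               1.3095  +/- 0.0113
#>   Rg2              6.5997  +/- 0.23
#>   P2               2.7205  +/- 0.0463

# the lamellar radius of gyration is recovered within ~2%
# (truth: Rg2 = 6.48 nm), and chi2/point ~ 1 as expected for sigma weighting

# position-averaged lamellar size, as reported for the two conditions
saxs <- saxs_reference_table()
average_with_sem(saxs$Rg2[saxs$condition == "space"], digits = 2)
#> 6.60667 +/- 0.0896908 (n = 3)   # reported as 6.61 +/- 0.09

# crystalline peak contrast between conditions
mk <- function(cc) condition_summary(
  cc, saxs_params = subset(saxs_reference_table(), condition == cc),
  peak_table = subset(waxs_reference_table(), condition == cc))
compare_conditions(mk("space"), mk("ground"))
#> comparison space (a) vs ground (b):
#>   mean 020 area ratio b/a: 2.17
#>   FWHM relative difference (b-a)/a: -10.3%
#>   Rg2 space: 6.61 +/- 0.09 nm
#>   Rg2 ground: 4.57 +/- 0.84 nm
#>   B2 uniformity space: 1.06
#>   B2 uniformity ground: 2.94
```

The comparison reads: the ground-grown gel has about twice the 020 peak
area (larger or better-oriented crystals), a ~10% narrower peak, a smaller
lamellar Rg₂ with much larger position-to-position spread, and a B₂
(lamellar number density) that varies almost 3x along the capillary where
the space-grown gel is uniform within ~6% — the quantitative signature of
gravitational settling.

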