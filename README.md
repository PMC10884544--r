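# b0dti

Orientation dependence of diffusion tensor MRI measures relative to the
main magnetic field, driven by compartmental T2 anisotropy.

## What this is for

In white matter, the extra-axonal transverse relaxation rate depends on the
angle θ between the fibre axis and B0, approximately as

    R2,e(θ) = R2,iso + R2,aniso · sin⁴θ        (1/s)

Because diffusion-weighted signals are acquired at finite echo time, this
relaxation anisotropy re-weights the intra- and extra-axonal compartments as
a function of θ and makes the diffusion tensor measures — MD, AD, RD, FA —
orientation-dependent. `b0dti` is for researchers who want to simulate,
quantify and statistically test this effect:

- a two-compartment (stick + zeppelin) forward model with per-compartment
  angular relaxation laws (constant, sin⁴θ, or dipolar (3cos²θ−1)²), its
  analytic ADC
  `ADC(TE) = (f·Dᵢ·e^{−R2,i·TE} + (1−f)·Dₑ·e^{−R2,e(θ)·TE}) /
  (f·e^{−R2,i·TE} + (1−f)·e^{−R2,e(θ)·TE})`,
  and Watson fibre-dispersion integration by deterministic spherical
  quadrature;
- Rician noise and diffusion tensor estimation by iterative weighted linear
  least squares, with θ recomputed from the principal eigenvector;
- anisotropy statistics: least-squares fits of `F(θ) = A + B·sin⁴θ` with
  AIC model selection (joint ΔAIC > 2 and 85% CI rules), 1° binning with
  count-weighted smoothing splines, signed anisotropy magnitudes and
  variance-contribution fractions;
- a synthetic cohort generator (subjects × tracts × segments × voxels, two
  head orientations 18° apart about the left–right axis, gradients fixed in
  the scanner frame) replacing the in vivo acquisition;
- three pipelines: the f × TE simulation grid, the pooled single-fibre
  analysis, and the tractometry comparison between head orientations.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, `autoplot()` for each result type.

## Worked example

```r
library(b0dti)

# Anisotropy of the analytic tensor measures at f = 0.4, TE = 54 ms
grid <- run_simulation_grid(f_values = 0.4, te_values = 54,
                            conditions = "analytic")
grid[, c("measure", "a_hat", "b_hat", "selected")]
#>   measure  a_hat     b_hat    selected
#> 1      md 0.9019 -0.002158 anisotropic
#> 2      ad 2.2829  0.019421 anisotropic
#> 3      rd 0.2114 -0.012947 anisotropic
#> 4      fa 0.8997  0.007378 anisotropic
```

`a_hat` is the orientation-independent level of each measure (μm²/ms for the
diffusivities) and `b_hat` the fitted sin⁴θ anisotropy magnitude: axial
diffusivity and FA increase with θ while radial diffusivity decreases —
the signature of extra-axonal relaxation anisotropy leaking into the
diffusion measures through the T2 weighting.

A full synthetic study runs in a few lines:

```r
cfg <- cohort_config(seed = 1)                  # 2 subjects, 5 tracts, ...
scheme <- default_scheme()                      # b = 0/750/1500, 4 TEs
signals <- generate_cohort_signals(build_cohort(cfg), scheme)
fits <- fit_cohort_dt(signals, scheme)
pooled <- run_pooled_analysis(fits)             # bins + spline + sin4 fits
tract <- run_tractometry(fits)                  # Δmeasure = B·Δsin⁴θ
autoplot(pooled$splines[["rd_54"]])
```

See `vignettes/orientation-anisotropy.Rmd` for the model, the estimator
caveats (cumulant-truncation and direction-set biases) and every default.

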