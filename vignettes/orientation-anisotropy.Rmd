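---
title: "Orientation dependence of diffusion tensor measures: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orientation dependence of diffusion tensor measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(b0dti)
```

## The problem

In white matter, the transverse relaxation rate of the extra-axonal water
compartment depends on the angle $\theta$ between the fibre axis and the main
magnetic field $\vec B_0$. Because diffusion-weighted acquisitions are also
$T_2$-weighted (the signal is read out at a finite echo time), any
$\theta$-dependence of compartmental $R_2 = 1/T_2$ leaks into apparent
diffusion quantities: mean (MD), axial (AD) and radial (RD) diffusivity and
fractional anisotropy (FA) become functions of how a tract happens to be
oriented in the scanner. `b0dti` implements the simulation and statistical
machinery to generate, quantify and test this effect, together with a
synthetic multi-subject cohort that stands in for a tiltable-coil in vivo
acquisition.

## Forward model

A single-fibre voxel is modelled as two non-exchanging, axially symmetric
compartments sharing one axis $\mathbf n$:

* an intra-axonal *stick* with signal fraction $f$, parallel diffusivity
  $D_{i,\parallel}$ and zero perpendicular diffusivity, and
* an extra-axonal *zeppelin* with diffusivities
  $D_{e,\parallel} \ge D_{e,\perp}$.

For a measurement with b-value $b$, unit gradient $\mathbf g$ and echo time
$TE$,

$$
S(b, \mathbf g, TE) = f\,e^{-R_{2,i}\,TE}\,e^{-b D_i(\mathbf g)}
  + (1-f)\,e^{-R_{2,e}(\theta)\,TE}\,e^{-b D_e(\mathbf g)},
$$

with the projected diffusivity of each compartment
$D = D_\perp + (\mathbf g \cdot \mathbf n)^2 (D_\parallel - D_\perp)$ and the
angular relaxation law

$$
R_{2,e}(\theta) = R_{2,\mathrm{iso}} + R_{2,\mathrm{aniso}} \sin^4\theta .
$$

A dipolar alternative $R_2(\theta) \propto (3\cos^2\theta - 1)^2$ — zero at
the magic angle $\arccos(1/\sqrt 3) \approx 54.7^\circ$ — is available for
either compartment via `relaxation_model("dipolar", ...)` but is off by
default; by default the intra-axonal rate is constant.

Units follow the field's mixed convention: $b$ in s/mm², $D$ in μm²/ms
(dimensionless exponent $b D \cdot 10^{-3}$), $TE$ in ms, rates in 1/s.
Defaults are $[D_{i,\parallel}, D_{e,\parallel}, D_{e,\perp}] =
[2.6, 2, 0.4]$ μm²/ms, $R_{2,i} = 12$ 1/s,
$R_{2,e} = 17.4 + 2.4\sin^4\theta$ 1/s, SNR 100. All orientation-dependent
quantities use the folded angle $\arccos|\mathbf u \cdot \mathbf v| \in
[0^\circ, 90^\circ]$, since fibres are axes, not vectors.

The apparent diffusion coefficient of this mixture is the first-order
Maclaurin coefficient of $\ln S$ in $b$: a $T_2$-weighted average of the
projected compartment diffusivities (`adc_analytic()`). AD and RD evaluate
it along and across the fibre; FA comes from the axisymmetric triple
(AD, RD, RD). Because the compartment weights are the only
$\theta$-dependent factor, the ADC is exactly $\theta$-independent at
$TE = 0$ — orientation dependence enters through relaxation weighting alone.

## Fibre dispersion

`signal_with_dispersion()` averages the coherent signal over a Watson
distribution of sub-fibre axes with concentration $\kappa$ about the mean
axis; every sub-compartment carries its own extra-axonal rate at its own
angle to $\vec B_0$. The integral uses a deterministic product quadrature:
Gauss–Legendre in $t = \cos\psi$ on $[0, 1]$ (the integrand is antipodally
symmetric) crossed with a periodic trapezoid in azimuth, 1024 nodes by
default. For $\kappa > 30$ the polar interval is split at
$t_0 = \sqrt{1 - 20/\kappa}$ with half the nodes on each piece, so the
near-delta limit stays resolved; the tests verify agreement with the
coherent signal to $10^{-4}$ at $\kappa = 10^6$, rotation invariance at
$\kappa = 0$, and agreement with a rejection-sampling Monte-Carlo average
within its sampling error at $\kappa = 16$. A dispersion index can be
converted via `od_to_kappa()` (OD $= (2/\pi)\arctan(1/\kappa)$); the
dispersed simulation condition uses $\kappa = 16$ (OD $\approx 0.04$).

## Noise and tensor estimation

Rician noise is applied as the magnitude of a complex Gaussian perturbation
with $\sigma = S(b{=}0, TE{=}0)/\mathrm{SNR}$ (`add_rician()`, default
SNR 100). Tensors are fitted per echo time by iterative weighted linear
least squares on $\ln S = \ln S_0 - \sum b_{ij} D_{ij}$: ordinary least
squares initialises, then weights equal to the squared model-predicted
signals are iterated until the relative parameter change falls below
$10^{-6}$ (at most 10 iterations). Non-positive noisy signals are clipped to
$10^{-10} \times \max S$ before the log and counted; negative eigenvalues
are flagged, never repaired. $\theta$ is recomputed from the principal
eigenvector, exactly as an in vivo pipeline must.

Two numerical facts shape the tests and deserve emphasis:

* **Cumulant-truncation bias.** The two-compartment signal is
  bi-exponential, so a tensor fitted on $b \in \{0, 750, 1500\}$ s/mm²
  differs from the analytic $b \to 0$ ADC by a deterministic amount
  (about $+0.008$ μm²/ms for AD and $-0.025$ μm²/ms for RD at the default
  parameters), shrinking roughly linearly with the maximum b-value. The
  pipeline-recovery tests therefore verify exact ($10^{-4}$) agreement on a
  low-b scheme and separately bound the bias at the study shells.
* **Direction-set bias.** With a finite gradient direction set the
  truncation bias varies slightly with fibre orientation relative to the
  set (order $10^{-4}$–$10^{-3}$ μm²/ms at 30 directions, several-fold
  smaller at 60). This is a true, deterministic orientation dependence of
  the *estimator*, not of the tissue; null-hypothesis checks of the
  selection statistics use 60-direction schemes so it stays negligible.

The log-domain IWLLS estimator coincides with a signal-domain nonlinear
least-squares fit only where the tensor representation is exact; on
bi-exponential data the two differ at second order in the misfit
($\sim 2 \times 10^{-4}$ μm²/ms at the study shells). The test suite checks
their equivalence in the model-consistent low-b regime and bounds the gap
elsewhere.

## Quantifying anisotropy

`fit_sin4()` fits $F(\theta) = A + B\sin^4\theta$ by (weighted) least
squares and compares it against the isotropic representation $F(\theta) = A$
with a least-squares AIC, $n \ln(\mathrm{RSS}/n) + 2k$ with $k$ counting
mean parameters plus one variance parameter (the $+1$ cancels in
differences; constants shared by both models are dropped). The anisotropic
representation is selected only if its AIC is minimal, the isotropic
$\Delta\mathrm{AIC}$ exceeds 2, *and* the 85% t-interval of $B$ excludes
zero. Support labels follow the conventional bands
($\le 2$ substantial, $< 10$ considerably less, $\ge 10$ none; the
conventional gaps 2–4 and 7–10 are folded into the middle band). Under a
true null this joint rule selects anisotropy in roughly 4–5% of cases; the
suite verifies < 15% empirically over 1000 seeded repeats.

The nonparametric route bins voxels into half-open 1° angle subsets
(`bin_average()`; a point on an edge belongs to the bin it starts), then
fits a cubic smoothing spline to the bin means as a function of the mean bin
angle, weighted by bin counts, with the smoothing parameter chosen by
generalized cross-validation and recorded in the output
(`spline_anisotropy()`). The signed magnitude is
$\max(\mathrm{curve}) - \min(\mathrm{curve})$, negated when the minimum
falls below the curve's value at the smallest observed angle (a $10^{-6}$
relative guard protects monotone curves from boundary undershoot). The
curve is tabulated on a 0.1° grid over the observed angle range only. The
contribution of orientation to the variance across voxels is
$(\mathrm{std}_\mathrm{iso} - \mathrm{std}_\mathrm{aniso}) /
\mathrm{std}_\mathrm{iso}$, with $\mathrm{std}_\mathrm{iso}$ the raw
standard deviation and $\mathrm{std}_\mathrm{aniso}$ that of the residuals
about the curve (re-centred at the fitted mean) — the reading under which
accounting for orientation can only reduce variation for least-squares fits.

## The synthetic cohort

`build_cohort()` emulates the in vivo study structure with no imaging data:
subjects × tracts × segments × voxels, acquired in a default and a tilted
head orientation. Defaults are 2 subjects, 5 tracts, 10 segments of 8
voxels (800 voxels per orientation), an 18° tilt about the left–right
(scanner x) axis, and SNR 100. The anatomy rotates; $\vec B_0$ and the
gradient directions stay fixed in the scanner frame, so tilting re-maps
every fibre's $\theta$ without touching the encoding. Tract directions are
drawn uniformly on the sphere by default (the in vivo angular distribution
is not publicly tabulated; a `custom_histogram` mode accepts one). Segment
directions scatter about their tract's axis and voxel orientations about
their segment's, each with Watson-like scatter of ~5° angular standard
deviation — segment wobble makes the tractometry regressor vary within
tracts, and voxel scatter emulates the fanning that motivates end-segment
exclusion. Per-voxel tissue parameters jitter multiplicatively
(truncated-Gaussian, CV 5% by default) about the defaults with
$f = 0.6$ — the upper of the two headline analytic conditions and a
plausible white-matter fraction. All voxels are single-fibre by
construction; crossing fibres, partial volume, spatial structure and coil
effects are deliberately out of scope, so passing tests certify the
statistical machinery, not robustness to those confounds.

Everything is reproducible: a mandatory seed fixes the cohort, the noise
stream (cohort seed + 1) and hence every downstream table bit-for-bit.

## The three analyses

* `run_simulation_grid()` sweeps $f \times TE$ under three conditions —
  analytic curves, noisy voxel simulations (1000 repeats per cell by
  default, angles cycling over a 1° grid), and noisy simulations with
  Watson dispersion — and fits the $\sin^4$ representation per measure and
  cell. $B$ is reported for every cell; the selection travels separately so
  unsupported cells can be greyed out in `autoplot()`.
* `run_pooled_analysis()` pools all single-fibre voxels from all subjects
  and both head orientations and, per measure × TE, runs both the binned
  spline and the unbinned $\sin^4$ fit, reporting $A$, $B$, the signed
  spline magnitude and the variance contribution.
* `run_tractometry()` compares matched anatomy across head orientations:
  segment-mean differences $\langle m_{0^\circ}\rangle_s - \langle
  m_{18^\circ}\rangle_s$ are regressed through the origin on
  $\langle \sin^4\theta_{0^\circ}\rangle_s - \langle
  \sin^4\theta_{18^\circ}\rangle_s$ (the isotropic representation predicts
  zero difference, so the null model is $y = 0$ and a cell is starred when
  the anisotropic AIC advantage exceeds 2). The outermost 10% of segments
  at *each* end of every tract are excluded (20% in total; the stricter
  20%-per-end reading is available via `trim_frac`), as are segments with
  3 or fewer voxels in either orientation.

On the default synthetic cohort the three analyses agree on the sign of
anisotropy wherever both detection rules support it: AD and FA increase
with $\theta$, RD decreases. MD is the fragile case — under the model its
anisotropy is a small negative number (the $T_2$-weighted mixture of the two
compartment mean diffusivities shifts toward the intra-axonal value as
$\theta$ grows), typically below the estimators' sampling noise, so its
per-TE sign is not a stable observable and no test asserts it.

## Worked example

```{r example, eval = FALSE}
library(b0dti)

# analytic anisotropy at one grid cell
grid <- run_simulation_grid(f_values = 0.4, te_values = 54,
                            conditions = "analytic")
grid[, c("measure", "b_hat", "selected")]

# a small noisy cohort end to end
cfg <- cohort_config(n_subjects = 1, n_tracts = 5,
                     n_segments_per_tract = 6, n_voxels_per_segment = 6,
                     seed = 1)
scheme <- default_scheme(te = c(54, 75))
signals <- generate_cohort_signals(build_cohort(cfg), scheme)
fits <- fit_cohort_dt(signals, scheme)
pooled <- run_pooled_analysis(fits)
tract <- run_tractometry(fits)
autoplot(pooled$splines[["rd_54"]])
```

## Problem sizes and defaults used by the checks

The shipped checks use desk-scale problem sizes chosen to make every
statistical claim measurable with comfortable margins: 1° $\theta$ grids
(91 points), 1000 noisy repeats per simulation-grid cell for selection-rate
statistics, $10^5$–$10^6$ Monte-Carlo samples for the Watson oracle, and the
default 2×5×10×8 cohort for the end-to-end run. Direction counts are 30 per
shell for general use and 60 where null-selection statistics are the
quantity under test (see the direction-set bias note above).

## Known limitations

* The tensor measures reported at the study b-values include the documented
  truncation bias; they are DTI estimates, not the analytic $b \to 0$
  limits.
* The $\sin^4$ representation is an approximation even for the analytic
  ADC; the spline route exists precisely to expose deviations from it.
* Watson dispersion is unimodal and antipodally symmetric; fanning,
  bending and crossing geometries are not modelled.
* The synthetic cohort draws orientations, not anatomy: no spatial
  autocorrelation, no shared-segment covariance beyond orientation, no
  coil or motion effects, no gradient non-linearity.
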