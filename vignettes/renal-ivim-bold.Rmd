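---
title: "Methods: renal IVIM diffusion and BOLD T2* analysis with renomri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: renal IVIM diffusion and BOLD T2* analysis with renomri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

renomri implements a complete, tested pipeline for quantitative renal
MRI biomarkers on a desk scale: a synthetic kidney phantom with known
ground truth, voxelwise parameter estimation for diffusion and BOLD
acquisitions, robust region-of-interest (ROI) summaries, and the
statistics of a repeatability / pharmacological-challenge study. This
vignette is the package's account of the science behind each step, the
parameters that matter, and the design choices made where more than one
defensible option existed.

## Signal models and units

Renal tissue shows non-monoexponential diffusion decay: beyond random
tissue water diffusion (coefficient D), incoherent flow in vessels and
tubules contributes a rapidly decaying pseudodiffusion component
(coefficient D*, fractional amplitude f). The package uses the standard
two-compartment IVIM form

$$S(b) = S_0\left[f\,e^{-b D^*} + (1-f)\,e^{-b D}\right],$$

the monoexponential ADC model $S(b) = S_0 e^{-b\,\mathrm{ADC}}$, and
gradient-echo BOLD decay $S(\mathrm{TE}) = S_0 e^{-\mathrm{TE}/T_2^*}$.
Internally all diffusivities are mm^2/s and times ms; the conventional
reporting scales (ADC, D in 1e-5 mm^2/s; D* in 1e-2 mm^2/s; fD* in
1e-4 mm^2/s; f in percent) are applied only at the reporting boundary
(`to_reporting_units()`), which keeps unit conversions out of the
numerics. The perfusion fraction is stored as a fraction in [0, 1]
throughout.

The default acquisition schemes are the nine-b-value protocol
(0, 20, 40, 60, 80, 100, 200, 400, 800 s/mm^2) and the five-echo BOLD
protocol (TE = 5, 10, 20, 30, 40 ms).

## The synthetic kidney phantom

`make_phantom()` builds a single 2D coronal slice: an elliptical
whole-kidney mask (default 89 voxels on a 32 x 32 grid, within the
91 +/- 12 voxels typical of rodent kidney ROIs at clinical resolution)
partitioned into a one-voxel cortical rim (28 voxels by default,
matching reported cortex ROI sizes) and a medullary interior. Ground
truth is constant within each region; the default values are published
baseline medians for healthy rat kidney at 1.5 T (whole kidney
f = 26.9 %, D = 124.5e-5 mm^2/s, D* = 4.0e-2 mm^2/s, T2* = 32.8 ms,
with distinct cortex/medulla values available, or a uniform kidney via
`default_kidney_params(uniform = TRUE)` when whole-kidney recovery is
the target).

**Noise.** Noise is additive Gaussian on the magnitude signal, matching
the Gaussian-likelihood fitting assumption; a Rician (two-channel
magnitude) mode exists for robustness studies but is off by default.
The noise SD is set through `snr_target` (default 20) with the
convention that the *weakest image of a series* reaches that SNR:
acquisitions in this protocol are screened so that every image used for
fitting — including the TE = 40 ms echo and the b = 800 s/mm^2 image —
has SNR above 20, so `noise_sigma` = (minimum kidney forward-model
signal across the series) / `snr_target`. Anchoring the SNR at the
unattenuated S0 instead would put the last echo at SNR ~6 and violate
that screening condition. Signal averaging in the emulated protocol is
folded into this single noise scale rather than simulated
average-by-average; for Gaussian noise the two are statistically
equivalent.

**Challenges.** `challenge_transform()` encodes each drug as
multiplicative pre-to-post factors on f, D, D* (and per-timepoint
factors on T2* at the three post-administration BOLD timepoints,
labelled 2m15s / 6m51s / 11m24s). The built-in defaults are the ratios
of reported whole-kidney medians after each agent to its baseline:
hydralazine (vasodilator) lowers D and T2* and raises f and D*;
furosemide (loop diuretic) raises D and T2* (to ~126 % of baseline T2*
at the second post timepoint); angiotensin II (vasoconstrictor)
transiently lowers T2*. Transforms are pure functions of the ground
truth and compose exactly, so `m` followed by `1/m` restores the
original phantom to machine precision.

**What the phantom does not emulate.** No EPI distortion, partial
volume, slice profile, respiratory motion, coil sensitivity, or
between-voxel biological texture (truth is piecewise constant), and a
single slice rather than a volume. Passing recovery tests on this
phantom therefore demonstrates correctness of the estimators under the
study's noise and geometry assumptions, not robustness to the full
physics of in vivo acquisition.

## Parameter estimation

**Perfusion-insensitive ADC** (`fit_adc`): Levenberg–Marquardt
nonlinear least squares (minpack.lm) on b >= 200 s/mm^2, initialised
from the two-point log-linear solution. The high-b threshold is
*inclusive* by default: the protocol statement "b = 200 s/mm^2 and
above" is adopted for both the ADC fit and the segmented
initialisation, since an exclusive threshold would leave only two
points (b = 400, 800) and make the three-parameter stage exactly
determined; the flag `include_b_min` restores the exclusive reading.

**Segmented IVIM initialisation** (`segmented_init`): the high-b
monoexponential fit gives D; projecting it back to b = 0 gives an
intercept A, and f = 1 − A/S(0), clamped into [0, 1] (noise can push
the raw value slightly negative). D* is initialised at a fixed multiple
of D (default 25x) because the high-b segment carries no information
about the fast compartment's rate.

**Bayesian IVIM fit** (`fit_ivim_bayesian`): all b-values, Gaussian
likelihood, uniform priors on all four parameters. Default prior box:
f in [0, 1]; D in [1e-5, 1e-2] mm^2/s; D* in [1e-3, 1] mm^2/s; S0 in
(0, 2 S(0)] — spanning reported renal values by more than an order of
magnitude each way. The bounds travel with every fit result for audit.

* *Noise scale.* The likelihood needs a noise SD. It is estimated per
  curve from the residuals of the segmented initialisation, with the
  pseudodiffusion rate refined by a one-dimensional least-squares
  search first so the residuals are not dominated by the arbitrary D*
  start; sigma^2 = SSR/(n − 4). It is then held fixed. The alternative
  (marginalising sigma under a Jeffreys prior) was considered and
  rejected for the default because a fixed, per-curve sigma is simple,
  deterministic and directly testable; `sigma` can always be supplied
  explicitly.
* *Posterior computation.* The default engine is a deterministic grid
  integration: S0 enters the model linearly, so its uniform-prior
  integral is evaluated in closed form (a Gaussian integral; the
  truncation of the S0 prior carries negligible mass at usable SNR),
  leaving a 3D grid over (f, D, D*) — f linear, D and D* log-spaced,
  with trapezoidal cell weights. Two zoom passes refine the grid onto
  the region holding all but ~1e-6 of the posterior mass, so the same
  engine resolves both broad noisy posteriors and near-degenerate
  noiseless ones. Marginal medians and central 95 % intervals are read
  off the cellwise cumulative distribution with within-cell linear
  interpolation; the S0 marginal is a mass-weighted mixture of the
  conditional Gaussians. The engine is bit-for-bit reproducible and
  needs no seed. A random-walk Metropolis engine (`engine = "mcmc"`)
  samples the identical posterior as a cross-check.
* *Point estimates* are marginal posterior medians, consistent with
  the ROI-median reporting philosophy and robust to the heavy tails
  that D* posteriors develop at low SNR.
* *Convergence.* A fit is flagged rather than trusted when (a) the
  majority of full-prior marginal mass for f or D sits in the outermost
  grid cells (prior-boundary pile-up), or (b) the posterior medians
  order as D* < D ("compartment-swapped", the classic biexponential
  failure mode); no hard D* > D constraint is imposed. Least-squares
  fits are non-converged when the solver fails, retained signals are
  non-positive, or (for T2*) the estimate runs into the non-decaying
  regime. Non-converged voxels stay in the map but are excluded from
  ROI medians.

**T2*** (`fit_t2star`): Levenberg–Marquardt monoexponential fit in TE
with no noise-floor term — the emulated protocol verifies SNR > 20 at
all echoes, so Rician bias is negligible by design.

**Degenerate inputs.** Constant or non-finite curves, all-non-positive
signals, and empty masks produce flagged non-converged results or
warnings, never exceptions, so voxelwise drivers continue. One genuine
limitation: for *exactly* noiseless data whose solution manifold is not
a point (e.g. a pure monoexponential curve, where any f with D* = D
fits perfectly), the estimated sigma collapses toward zero and the grid
posterior concentrates at grid resolution on an arbitrary point of the
manifold. With any realistic sigma the posterior behaves sensibly (D*
reported unidentifiable via a credible interval spanning most of the
prior); supply `sigma` explicitly when fitting synthetic noiseless
data.

## Regions and summaries

The whole-kidney mask is split by one-step morphological erosion
(EBImage): the cortex is the single-voxel outline, the medulla the
interior, so the two partition the kidney exactly. Erosion uses
4-connectivity by default — on convex masks it yields a true one-voxel
rim — with 8-connectivity behind a flag. ROI summaries report the
*median* over converged voxels only, which suppresses the influence of
fit failures; even-count medians are the usual lower-midpoint average,
noted because ROIs here are small. BOLD maps are summarised
whole-kidney only by default (slice partial volume precludes a reliable
cortex/medulla split in the emulated protocol); subregions can be
forced for synthetic studies. Kidneys can be excluded with an audited
reason (`exclude_kidney`); statistics refuse to run when every kidney
is excluded.

## Study statistics

* **Repeatability** is the within-subject root-mean-square CoV of
  paired scans, $100\sqrt{\tfrac{1}{2N}\sum_i (d_i/m_i)^2}$, invariant
  to rescaling and scan order. The source protocol does not state its
  CoV formula, and published CoVs cannot be re-derived from summary
  tables alone, so this standard test–retest form is adopted and
  documented rather than asserted as identical.
* **Paired pre/post comparisons** use the two-sided Wilcoxon
  signed-rank test at 5 %, exact null for up to 25 non-zero pairs,
  normal approximation with continuity correction beyond; zero
  differences are removed (Wilcoxon's convention), and an all-zero
  sample reports p = 1 with a degeneracy note.
* **BOLD timecourses** use one-way repeated-measures ANOVA with the
  kidney as subject unit; when the omnibus test is significant at 5 %,
  paired t-tests flag each post timepoint against baseline and against
  the previous timepoint. Kidneys nested in animals are *not* modelled
  as a hierarchy — a stated limitation mirroring the emulated
  analysis.
* **Percent change** expresses each kidney's T2* timecourse relative
  to its own baseline (identically 100 % at baseline) with cohort
  mean +/- SE.
* **ADC–D agreement** is the Pearson correlation of ROI medians; it is
  reported as undefined when either vector has zero variance.
* No multiple-testing correction is applied across parameters or
  regions, matching the emulated analysis; reports state this.

## Reproducibility and problem sizes

Every stochastic step takes a seed; `run_experiment()` derives
per-stage seeds deterministically from one master seed and logs them,
so identical configurations reproduce identical outputs. Configurations
serialise to YAML; results go out as tidy CSV summaries, JSON results
with all seeds and versions, and NIfTI maps.

The shipped checks run at desk scale by choice: the 89-voxel phantom
with 20 independent noise realisations for recovery endpoints, 25
curves against a 100-points-per-axis brute-force posterior for oracle
equivalence, 100 curves for model comparison, and four-kidney cohorts
for repeatability. These sizes give sub-percent Monte Carlo error on
the reported means while keeping a full run in minutes on one CPU.

## Known limitations

Beyond those noted above: D* is intrinsically poorly identified from
nine b-values at SNR 20 — its posterior medians carry a small upward
bias from the vague uniform prior and a CoV several times that of D,
which is the expected behaviour of renal IVIM, not an implementation
artefact; the all-b monoexponential comparison fit shares the IVIM
curve's data, so residual-based model comparison is an ordering
property, not a formal test; and the pipeline reads only NIfTI (convert
DICOM upstream).
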