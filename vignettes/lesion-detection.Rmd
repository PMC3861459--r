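---
title: "Methods: parametric ultrasound and optical mapping analysis of thermal ablation lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parametric ultrasound and optical mapping analysis of thermal ablation lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hifumap)
```

This vignette is the package's account of its science: the models behind
each stage, the parameters that matter, what the synthetic generators do and
do not emulate, and the numerical decisions taken where the underlying
methodology leaves the choice open.

## The detection problem

Thermal ablation (HIFU, RF, laser) coagulates a roughly ellipsoidal volume of
myocardium.  In a transmural imaging plane, three signatures of the forming
lesion are available:

1. the first-order statistics of the high-frequency ultrasound speckle
   change as scatterers (cell nuclei, fibre structure) are disrupted;
2. the optically mapped action potential loses amplitude (APA), shortens
   (APD50, APD80), triangulates (APD50/APD80 falls), and its upstroke slows;
3. histology (trichrome staining, TTC, gross photographs) shows the pale
   coagulated region that serves as ground truth.

The package scores per-pixel ultrasound and electrophysiology features
against lesion masks by ROC analysis, trains operating thresholds, and
validates them across subjects by leave-one-out cross-validation.

## Parametric ultrasound imaging

Envelope amplitudes `A` inside a sliding window are treated as draws from a
first-order speckle model.  Two models are fitted per window by closed-form
maximum likelihood:

* Rayleigh, `f(a) = (a/α²) exp(−a²/2α²)`, with MLE `α̂ = sqrt(Σa²/2N)` —
  fully developed speckle;
* log-normal, with `μ̂ = mean(ln a)` and `σ̂² = mean((ln a − μ̂)²)` —
  heavier-tailed amplitude mixtures typical of structured or poly-disperse
  scatterer populations.

`goodness_of_fit()` quantifies either fit with an adjusted R² of the model
pdf against the 45-bin amplitude histogram (degrees of freedom
`bins − parameters − 1`, i.e. in the low 40s), plus a χ² statistic.

Choices a user can change:

* **Window** (`window_spec`): default 100×13 px, the conventional estimation
  window for ~30 MHz envelope data where pixels are ~50–115 µm.  The
  acceptance-scale phantoms use 7×7 windows on 64×64 grids, keeping roughly
  the same window-to-lesion area ratio.  Windows trade estimator variance
  (`sd(σ̂) ≈ σ/√(2N)`) against spatial blur at the lesion boundary.
* **Edge policy**: `"shrink"` (default) recomputes border anchors with a
  truncated window so maps keep the frame shape; `"na"` marks them missing.
  Truncated windows have fewer samples and hence *inflated estimator
  variance*; because the cumulative-extrema operator takes a running
  maximum, that inflation systematically raises border scores.  Detection
  analyses in this package therefore use `edge = "na"`; with the shrink
  policy a null phantom's border pixels would bias chance-level AUC
  downward.
* **dB reference** for GS/IBS: the maximum envelope over the pre-ablation
  baseline frames; zero amplitudes map to a −60 dB floor.

## Temporal-evolution maps

For a parameter sequence `X(x, y; t)` with pre-ablation baseline frames `B`:

* transient: `|ΔX|_t = |X(t) − X(t−1)|` (first frame undefined, `NA`);
* cumulative: `ΔX_c = X(t) − mean_{t∈B} X(t)`, kept both signed and
  absolute;
* cumulative extrema: the per-pixel running maximum of `|ΔX_c|`,
  normalized to `[0, 1]`.

**Normalization scope.**  The extrema map is scaled by a *single global
maximum per sequence*, not per frame: per-frame scaling would destroy the
per-pixel monotonicity that makes the extrema image interpretable as "the
largest excursion so far", and a single dimensionless threshold per
parameter only makes sense with one scale factor.

**Threshold transfer.**  A normalized threshold is only meaningful within
sequences that contain a genuine lesion (the lesion sets the scale).  On a
null sequence the noise maximum is rescaled to 1 and any normalized
threshold fires.  Operating points intended to transfer across sequences —
in particular the "does this sequence contain a lesion at all?" question —
are therefore trained and applied on the *raw* (pre-normalization) extrema
scale.  The acceptance suite verifies that a raw-scale threshold trained on
lesioned phantoms flags under 5% of pixels on null phantoms, while
normalized thresholds are used for pooled within-cohort ROC.

## Optical-mapping feature extraction

Preprocessing follows the standard optical-mapping chain: 3×3 spatial
binning, then a zero-phase FIR band-pass of each pixel trace.  The kernel is
symmetric (linear phase) and applied once, centred, via FFT — zero net
delay, equivalent to forward–backward filtering of a linear-phase design.
Its DC coefficient is forced to exactly zero (high-pass edge) or exactly
unity (pure low-pass), so constant offsets behave predictably.  The default
order is 1024 at 1000 frames/s: a 1 Hz lower edge needs a long kernel, and
shorter designs (order 512) measurably distort the passband (gain error
~2% at 10 Hz vs. 0.5% at order 1024).

Drift from photobleaching and slow thermal effects is removed by
`correct_drift()`: linear, logarithmic, and cubic-polynomial models are fit
to the diastolic samples (the last 10% of each pacing cycle, just before
the next stimulus) and the best-fitting model's prediction is subtracted
per pixel.

Features, per pixel and pacing cycle:

* **Activation**: the time of maximal dΔF/dt (central differences, a 5 ms
  centred boxcar on the derivative, parabolic sub-frame refinement of the
  peak).  The boxcar suppresses the noise bias of the max statistic and is
  exact on linear ramps and symmetric peaks.
* **APD at fraction f**: time from activation to the first post-peak
  crossing of `diastole + (1 − f)·(peak − diastole)`, with linear sub-frame
  interpolation.  "50% repolarization" is read as amplitude fallen to half
  the peak above diastole (the standard APD50); for the normalized traces
  used here the ambiguous alternative reading coincides.
* **APA / ΔAPA**: per-cycle peak-to-diastole amplitude normalized by the
  per-pixel mean over baseline cycles (so baseline APA ≡ 1);
  `ΔAPA = APA − 1`, negative meaning loss.
* **Triangulation**: APD50/APD80, which falls when the plateau collapses
  faster than late repolarization.
* **Upstroke rate**: the refined maximum derivative of the per-cycle
  normalized trace.  Because this is a maximum statistic, additive noise
  biases it upward, and the bias is worst exactly where the signal is
  weakest — inside the lesion, whose amplitude is reduced ~5-fold.  The
  recommended noisy-data path is classic beat averaging
  (`average_cycles()`) over steady post-ablation cycles before the
  derivative; three beats reduce the bias by √3 with no shape distortion.
* **Conduction velocity**: a local plane fit (default 5×5) to the
  activation map gives the gradient `g` in ms/mm; `CV = g/|g|²` in mm/ms
  points along propagation.  Pixels with `|g|` under 0.02 ms/mm
  (near-simultaneous activation) are masked rather than divided.

For low-noise or noiseless data the band-pass is unnecessary; for noisy data
at 1000 ms pacing cycles, note that the 1 Hz high-pass edge sits *on* the
pacing fundamental and visibly sags the plateau.  Since drift is removed
explicitly by `correct_drift()`, the package's recommended noisy pipeline is
binning + 100 Hz low-pass + drift correction, keeping the full band-pass
available for data whose drift is not separately modelled.

## Histology segmentation and registration

`segment_lesion()` converts sRGB to L\*a\*b\*, clusters the (a\*, b\*)
chroma by 2-class k-means (seeded deterministically — reproducibility is
required because thresholds are trained downstream), picks the lesion
cluster by a colour prior (the paler, higher-L\* class: coagulated tissue on
trichrome slides and TTC-negative necrosis are both pale), then regularizes
the binary labels with an Ising-prior MRF solved by checkerboard iterated
conditional modes.  The unary term is a unit cost for disagreeing with the
observed k-means label and the pairwise weight is the user's
`smoothing_weight` (default 1.0): any weight above 1/4 flips isolated
mislabelled pixels, while extended structures survive.  A morphological
closing (disc radius 3) removes residual boundary roughness.  TTC
photographs use the same operator — the necrotic core is likewise the pale
class — rather than a separate algorithm.

Registration uses the closed-form (Procrustes/Umeyama) similarity fit:
rotation, isotropic scale, and translation.  The fiducial is a rigid carving
on a flat screen, so affine shear freedom is unjustified; the fit is exact
(zero residual) whenever the landmark pairs truly are similarity-related.
Masks are resampled nearest-neighbour, intensity images bilinearly.

## ROC machinery

Curves are built over all distinct score thresholds with ties grouped; the
trapezoid AUC then equals the pair-counting probability
`P(score_lesion > score_other) + ½P(tie)` exactly, which the tests verify
against an exhaustive oracle.  The optimal threshold maximizes Youden's
`J = sensitivity + specificity − 1` (the criterion is prevalence-free, which
matters because lesion pixels are a minority); ties break toward higher
specificity, and the returned value is the midpoint of the score gap at the
operating point, so cleanly separated classes yield the centre of the
separating gap.  Pixel non-independence is deliberately ignored within a
curve — spatial correlation from overlapping estimation windows shrinks the
effective sample size, which is why per-subject AUCs on null phantoms
scatter around 0.5 with a spread far wider than a binomial count would
suggest; uncertainty is instead quantified across subjects by leave-one-out
cross-validation, matching how such cohorts are actually analysed.  The
three-band ΔAPA classifier defaults to bounds −0.43 (lesion) and −0.19
(detectable non-lesion change).

Kruskal–Wallis group comparison is exposed as a thin wrapper over
`stats::kruskal.test()` for phantom cohort summaries.

## The synthetic generators

**Speckle phantoms** draw per-pixel envelope amplitudes i.i.d. from the
configured model (log-normal by default, `σ₀ = 0.3`); inside the lesion
ellipse the shape parameter is multiplied by a time profile: identity before
ablation, a linear ramp to `lesion_shift` (default 1.8) across the 4 s
ablation window, then exponential relaxation (τ = 1.5 s) toward a retained
fraction (default 0.5) of the peak shift.  The relaxation models the
reversible component of the echogenicity change — transient gas bodies and
heating — and is what makes the cumulative-extrema operator genuinely
superior to the plain cumulative change at the end of the sequence: with a
purely monotone trajectory the two coincide on lesion pixels while the
extrema's running maximum raises background noise scores, and the observed
ordering extrema ≥ cumulative ≥ transient could not emerge.  Acquisition
defaults mirror the imaging conditions the pipeline targets: 11 frames/s
starting at t = 4 s, ablation at 4.5–8.5 s, with imaging extended past the
window so the relaxation is observable.

What the speckle generator does *not* emulate: the point-spread function of
the imaging system (samples are spatially independent, whereas real speckle
is correlated at the resolution-cell scale), attenuation, depth-dependent
gain, cavitation artefacts, or motion.  Passing tests therefore demonstrate
the correctness and calibration of the estimators and detection chain, not
the clinical detectability of lesions.

**AP movies** render
`F = drift(t) · (F₀ + APA(x,y,cycle) · template(t − activation(x,y))) + noise`.
The template has a raised-cosine upstroke (default 20 ms), a flat plateau,
and an exponential repolarization whose plateau end and rate are solved so
the 50% and 80% crossings land exactly at the configured APD50/APD80
(defaults 160/200 ms, ratio 0.8).  A strictly linear upstroke was rejected:
its derivative is constant, so the operational activation marker (arg-max of
dΔF/dt) would be ill-posed and sub-frame recovery untestable.  The 20 ms
upstroke matches the magnitude of typical optical upstroke rates
(~0.2 %ΔF/ms at a few percent ΔF amplitude); optical upstrokes are much
slower than cellular ones because of photon scattering.  Lesion effects
(APA ×0.2, APD50 ×0.67, APD80 ×0.79, upstroke ×0.58 — the ~80% amplitude
loss, 33%/21% shortening, and ~0.19→0.11 %/ms slowing regime) ramp linearly
over the ablation window, evaluated at each cycle's start.  Ground-truth
feature maps come from the generative parameters, never from the rendered
movie.  Defaults include mild photobleaching drift and sensor noise at
~20 dB amplitude SNR; recovery tests switch these off explicitly where the
noiseless contract is asserted.

Not emulated: motion, dual-wavelength ratiometry, spatial heterogeneity of
APD across the wall, arrhythmic beats, and optical blurring of the lesion
border (each pixel is purely lesion or non-lesion).

**Histology images** place Gaussian colour noise around two class colours
(pale pink lesion on dark red background) with isolated swapped-class
outlier pixels to exercise the MRF step.  Real slides add stain variability,
out-of-plane structure, and borders that are genuinely gradual — none of
which are modelled.

**ΔAPA cohorts** draw per-pixel ΔAPA from inside/outside histogram moments
typical of pooled wedge cohorts (−0.57 ± 0.16 over 2058 pixels vs.
−0.16 ± 0.15 over 4117 pixels, 13 subjects), making the pooled ROC of the
cohort land in the regime the pipeline is designed for.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen as
the package's own test design: 64×64×88 speckle phantoms (13-phantom
cohorts, 20-seed sweeps), 40×40 AP movies at 1000 frames/s with 12 pacing
cycles, 120×160 histology images, and Monte-Carlo estimator checks at
n = 10⁵.  Sub-frame interpolation is linear at APD crossings and parabolic
at derivative peaks; derivative estimation uses central differences (wider
stencils overshoot at slope discontinuities and were rejected).  Stack i/o
stores 32-bit float TIFF pages rescaled to `[0, 1]` with the affine scale
in a JSON sidecar; round trips are lossless to float-32 precision of the
data range.  Degenerate inputs error early and explicitly: all-zero
reference frames, single-class labels, empty baselines, coincident
landmarks, windows larger than frames; all-zero estimation windows yield
`NA` sentinels with a warning rather than silent zeros.

## Known limitations

* Speckle is modelled at the envelope-statistics level; there is no
  scatterer-field convolution path, so spatial speckle correlation and
  resolution-cell effects are absent.
* The lesion-trajectory shape (ramp + partial relaxation) is a modelling
  choice; the literature does not parameterize envelope-statistics kinetics
  inside a forming lesion.
* ROC curves treat pixels as exchangeable; cluster-level (spatially aware)
  inference is out of scope.
* The optical model omits motion and border blurring, which in real data
  contaminate activation and CV estimates near the lesion edge.
* Upstroke-rate estimates on noisy low-amplitude (intralesional) traces are
  upward-biased unless beat averaging is applied; the package provides the
  tool but cannot remove the bias for single-beat data.
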