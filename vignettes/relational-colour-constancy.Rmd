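---
title: "Simulating misidentification of illuminant changes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating misidentification of illuminant changes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coneratios)
```

## The problem

When the illumination of a scene changes, the light reflected from every
surface changes, yet observers can usually tell an illuminant change from a
change in the surfaces themselves. A long-standing explanation is
*relational colour constancy*: within each cone class, the ratio of cone
excitations at two scene points is approximately invariant under a global
illuminant change, so the visual system can use the stability of these
*spatial cone-excitation ratios* as a cue. The operational test is a spatial
two-alternative forced-choice (2AFC) task: two identical renderings of a
scene change illuminant side by side, one of them additionally *corrected*
so its spatial ratios are preserved exactly; observers report which side was
a pure illuminant change. Misidentifying the corrected side as the
illuminant change indicates that residual deviations in ratios — not any
other cue — drive the judgement.

`coneratios` implements the full computational chain of such an experiment:
rendering hyperspectral reflectance scenes under Planckian illuminants,
estimating deviations in spatial ratios, constructing ratio-corrected
stimuli, quantifying appearance changes in CAM02-UCS, and running and
analysing a simulated experiment with a synthetic observer.

## The stimulus model

**Scenes.** A scene is an effective spectral reflectance cube
(H × W × 33 bands, 400–720 nm at 10 nm). Rendering under a global
illuminant is the per-band product of reflectance and illuminant power.
Camera data can be smoothed by 2 × 2 block averaging and downscaled
(band-wise bilinear) with `preprocess_cube()`; odd trailing rows are
dropped, the simplest reproducible choice.

**Illuminants.** Planck's law (CODATA radiation constants, radiance per
unit wavelength) parameterised by temperature between 2000 K and
100 000 K. Pairs are sampled uniformly in *reciprocal* temperature, which
spaces illuminant colours approximately uniformly. Spectra are normalised
to 1 at 560 nm; the convention is harmless because spatial ratios are
scale-invariant and displayed images are renormalised to a target mean
luminance (8 cd m⁻² by default).

**Cone excitations and ratios.** Per-pixel LMS excitations are rectangle-
rule integrals of radiance against cone fundamentals. The package ships the
Hunt–Pointer–Estévez 2° fundamentals (derived from the CIE 1931 2° CMFs,
unit peak) as the default sensor set; any two-column-per-class tabulation —
e.g. Stockman–Sharpe 2° from CVRL — can be supplied through
`read_sensor_functions()`. For a pixel pair, the ratio vector is the
component-wise quotient r = (q_L(1)/q_L(2), q_M(1)/q_M(2), q_S(1)/q_S(2)),
and its relative deviation across two illuminants is

Δr = |r′ − r| / min(|r′|, |r|),

with Euclidean norms. The **mean relative deviation (MRD)** over a random
sample of 50 000 pixel pairs is the stimulus-strength variable; it is
stable across resamplings (SD < 5 % of the mean on 128 × 128 scenes) and
classified into seven half-open 1 %-wide bins (centres 0.5 %–6.5 %). Pairs
with any excitation below 10⁻⁶ times its channel mean are rejected — the
theory assumes positive divisors but fixes no threshold, so a conservative
relative guard is used.

**Ratio correction.** For each cone class, test-image excitations are
regressed *through the origin* on the reference-image excitations over all
pixels, k_c = Σ B_c(i) A_c(i) / Σ A_c(i)², and the corrected image is
C = diag(k) · A. Since C is a per-class scaling of A, every spatial ratio
of A is preserved exactly; MRD(A, C) ≤ 10⁻¹⁰ is the package's central
invariant (floating-point only — the identity is algebraic). The direction
of the regression is genuinely ambiguous in the source design (excitations
"under one illuminant regressed on the other" can be read either way);
the package scales the *reference* image, because both sides of a trial
must start from the identical reference rendering and the corrected side
must carry zero ratio deviation from it while approximating the test
rendering. The transposed reading is available via
`fit_correction_gains(..., direction = "reference_on_test")`.

## Appearance and generalized metamerism

Colour appearance is computed with the CIECAM02 forward model followed by
the CAM02-UCS transform, reported as (J, a, b). The implementation matches
the published worked example of the standard to four decimals. Two
numerical facts are worth knowing:

* With the standard matrices, an exactly neutral sample does not map to
  a = b = 0 but to |a|, |b| ≈ 3 × 10⁻³ — the HPE matrix's L row sums to
  1.00001. Row-normalising would remove the residual but visibly change
  the verification values, so the standard matrix is kept.
* Viewing parameters are not dictated by the experimental design, so they
  are config-exposed with documented defaults: adopted white = the trial
  illuminant scaled to the display white (five times the 8 cd m⁻² mean
  luminance), L_A = 1.6 cd m⁻² (one fifth of the mean), Y_b = 20,
  surround "dim" (a darkened room and a low-luminance display).

For a pixel pair, the colour relation under one illuminant is the
difference vector Δc = (ΔJ, Δa, Δb); the change of that relation across
illuminants, ΔE = |Δc′ − Δc|, measures generalized metamerism — the
colorimetric signature of failed relational constancy. Mean ΔE is computed
over the *same* pair sample as the MRD of the condition, so the two
statistics describe identical point sets.

**Degree of adaptation.** The pipeline computes cross-illuminant appearance
with the illuminant fully discounted (D = 1) by default. With incomplete
adaptation (the CIECAM02 formula gives D ≈ 0.74 at L_A = 1.6), the global
appearance shift left undiscounted dominates ΔE and obscures the
relational signal entirely. Discounting is the conventional assumption when
appearance is compared across illuminants, and it is what makes ΔE track
MRD. The formula-based D remains the default of `viewing_conditions()`
itself and a `full_adaptation` switch is exposed in both places.

**A structural caveat.** The ratio correction is a von Kries transform in
receptor (fundamental) space, but CIECAM02 adapts in CAT02 space. The
conjugated transform is not diagonal, so a corrected image retains a floor
of *apparent* relational change that grows with the illuminant gap rather
than with the scene's ratio deviations. On saturated scenes at large gaps
the corrected image still changes appearance less than the uncorrected one,
but on weakly chromatic scenes the ordering can invert. The package
reports both mean ΔE(A, B) and mean ΔE(A, C) in the stimulus manifest so
the effect is visible rather than hidden.

## Synthetic scenes

`generate_scene()` emulates the statistics the analysis assumes of natural
scenes without reproducing any particular scene: a Voronoi mosaic of
surfaces (irregular patches, count controls spatial scale); per-patch
spectra that are convex combinations of Gaussian-bump basis spectra
(width `smoothness` = 60 nm, guaranteeing smooth, bounded reflectances in
[0, 1]); patch lightness log-normal with coefficient of variation
`lightness_cv` = 0.4; chromatic contrast of magnitude CV `chroma_cv` = 0.15
tilted about a preferred axis (`chroma_bias_deg` = 90°, the yellow–blue
axis); multiplicative log-normal within-patch texture; and a fraction
(`red_fraction` = 0.15) of saturated long-wavelength-shoulder surfaces,
which produce the largest ratio deviations. Defaults were chosen once so
that generated scenes satisfy the display constraints of the experimental
design — at least 95 % of colours inside the sRGB gamut under 3000 K and
25 000 K renderings — while random reciprocal-uniform illuminant pairs
span MRDs of 0–9 %, covering the seven experimental bins.

Dispersion contract: with `lightness_cv` > `chroma_cv`, generated scenes
show larger lightness than chromatic variation in CAM02-UCS units
(SD(J) ≈ 8 vs SD(chroma) ≈ 4 at defaults). The comparison is made in
absolute dispersion, not coefficients of variation: UCS chroma inherits
lightness dispersion through the model's √(J/100) factor and hue-dependent
gains, which puts a floor under CV(chroma) that no generator can undercut.

What the generator does **not** emulate: illumination geometry, shadows and
mutual reflection; the spatial power spectra and textural detail of real
scenes; measured natural reflectance bases. Tests passing on synthetic
scenes therefore certify the computational chain and its invariants, not
quantitative agreement with any particular natural-scene dataset.

## The simulated experiment

A session tests every (scene, MRD level) condition once in random order —
70 trials for the standard 10 scenes × 7 levels — with the corrected side
assigned uniformly at random per trial; 10 sessions by default. Stimulus
conditions are found by rejection sampling: temperature pairs are drawn
until the measured MRD lands in the target bin, with a cap of 500 attempts
per condition (unmet conditions are reported and tolerated — low-chroma
scenes may not reach the highest bins). Presentation timing (1 s
interchanges, four cycles, 8 s trials) is recorded as design metadata only.

The synthetic observer misidentifies the corrected side with probability

p(x) = 0.5 + (0.5 − λ) Φ((x − μ) / σ),

where x is the condition's MRD in percent: guessing floor 0.5, ceiling
1 − λ. The same family is fitted to simulated data by binomial maximum
likelihood with λ bounded in [0, 0.06] (the conventional ceiling that
prevents lapse/σ trade-off), multi-start L-BFGS-B from a quantile-based
(μ, σ) grid, convergence tolerance 10⁻⁸ on the log-likelihood. Maximum
likelihood is the standard estimator for binomial psychometric data; the
percentage of variance accounted for on the level proportions is reported
alongside for comparability with percentage-of-variance summaries.
Discriminability is d′ = √2 Φ⁻¹(p) with p the proportion choosing the
corrected side, clamped to [1/(2n), 1 − 1/(2n)]; using the systematically
preferred side keeps d′ ≥ 0 a monotone index regardless of which side is
nominally "correct". Uncertainties are 95 % BCa bootstrap intervals
(B = 1000; bias correction from the bootstrap distribution, acceleration
from jackknife skewness; degenerate distributions fall back to percentile
intervals with a flag). Locally weighted linear or quadratic regression is
available through `loess_fit()` (tricube weights, exact-surface fitting).

## Problem sizes and determinism

The test suite and the acceptance script run at sizes chosen to exercise
every stage at full fidelity while completing quickly: synthetic scenes of
64 × 64 pixels (32 × 32 in the smallest pipeline tests), 10 000–50 000
pixel pairs per MRD estimate, 100-replicate parameter-recovery and
2000-replicate bootstrap-coverage simulations. Exhaustive-oracle checks
run on cubes up to 8 × 8, where all pairs can be enumerated. All
randomness flows from one master seed; stage streams (scenes, illuminants,
pairs, trials) are derived with `child_seed()` so each stage is
independently reproducible and a full pipeline rerun is bit-identical.

## Known limitations

* The default sensor set is Hunt–Pointer–Estévez, not Stockman–Sharpe;
  for quantitative reuse with measured fundamentals, supply a CVRL table.
* The CAM02-UCS inverse model, display-primaries modelling and monitor
  calibration are out of scope; sRGB rendering exists for illustration and
  gamut checks only.
* Per-scene asymptotic misidentification summaries use bins 2–6, which
  presumes performance has levelled off by 2.5 % MRD, as it does for the
  default observer (μ = 3, σ = 1.5); steeper observers may need a
  different cut.
* The ΔE-vs-MRD coupling is asserted on synthetic ensembles; real-scene
  coupling strength depends on reflectance statistics the generator only
  sketches.
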