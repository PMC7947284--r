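---
title: "Reading emotion-resembling cues from neutral faces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading emotion-resembling cues from neutral faces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facetriad)
```

## The scientific problem

Neutral faces are not socially silent. Incidental features — brow
height, lip-corner curvature, skin contrast, surface roughness —
partially resemble emotional expressions, and perceivers overgeneralize
from that resemblance to stable trait impressions (an angry-looking
neutral face reads as dominant; a fearful-looking one as submissive and
trustworthy). These resemblances are also confounded with gender:
stereotypically, male neutral faces carry more anger-like cues and
female neutral faces more fear-like cues.

`facetriad` implements the full measurement chain for this phenomenon:
extract three independent cue channels ("the triad") from the face
interior, classify each channel's emotion resemblance, combine the
channels by their reliability, project the result into a
dominance–affiliation social face space, manufacture stimuli that move
a neutral face toward chosen face-space positions, and test the
statistical links to human impression ratings. Every stage runs on a
synthetic generator with planted effects, so every claim in the test
suite is a parameter-recovery claim.

## The synthetic face generator

Faces are drawn procedurally on a 128 x 128 canvas (no external
assets): a skin-toned oval with a vertical shading gradient, brows,
eyes, nose and mouth rasterized from a fixed 42-point landmark template
(10 brow, 8 eye, 5 nose, 12 mouth, 7 jaw/cheek points), Gaussian cheek
blush, additive band-limited noise for surface roughness, and an
optional oriented sinusoidal "grain". The template and all offsets
scale linearly with the canvas.

Each emotion class plants signal in all three channels:

* **structure** — a 42 x 2 landmark displacement field following
  textbook action tendencies (anger: brows down and in; fear/surprise:
  brows up, eyes wide; happy: lip corners up and out; sad: inner brows
  up, corners down). Magnitudes (2–6 px) are free parameters of the
  generator, not claims about real expressions.
* **color** — a per-emotion RGB shift on the cheek region (anger
  reddens, fear pales, happy adds rosiness, and so on).
* **texture** — a per-emotion roughness-amplitude delta plus an
  oriented grain component at an emotion-specific orientation x
  wavelength (random phase per face). The grain exists because
  amplitude alone cannot separate classes near the amplitude floor:
  the sampling variance of band-limited-noise energies over a face
  interior is substantial, while an orientation signature survives it.
  Default amplitude levels are deliberately spaced far apart for the
  same reason.

A gender covariate adds a heavier brow and wider jaw, a slight cheek
desaturation and extra roughness to male faces. The *confound
specification* plants the stereotypic gender-emotion association on
neutral faces only: `list(male = c(anger = 0.5), female = c(fear =
0.5))` moves male neutral faces half-way along the anger
displacement/color/texture fields and female neutrals half-way along
fear. Per-face idiosyncrasy (landmark jitter, default SD 1 px) and
pixel noise (default SD 0.01) control difficulty. All randomness flows
from one seed through per-face counter-derived substreams, so cohorts
are order-independent and byte-reproducible; with all planted fields
and noise SDs at zero, every generated image is byte-identical — a
property the suite asserts.

Rating tables are linear functions of per-face latent dominance and
affiliation scores plus Gaussian noise; masculinity is planted on
latent dominance and femininity as its noisy negation, reproducing the
strongly negative masculinity–femininity correlation of normed rating
data. Trial tables plant exact counts of low-variance participants and
out-of-range reaction times, recorded in a ground-truth manifest.

What the generator does *not* emulate: photorealistic appearance, 3-D
pose and lighting, identity covariance structure, age, race, or the
distribution of any real face database. Passing tests therefore
demonstrate that the pipeline recovers what was planted under its
stated geometry — not that the defaults match human faces.

## Feature extraction

Landmarks are similarity-normalized (eye midpoint at the origin, eye
line horizontal, interocular distance 1) so structure features measure
shape only; the suite checks invariance to rotation, scaling and
translation at 1e-6. The interior mask is the filled convex hull of
the template; named regions are the thickened brow lines, lid quads,
nose hull and lip outline, and the cheeks are the hull minus all other
regions so skin statistics never include eye or mouth pixels.

Structure: the 84 normalized coordinates plus brow–eye gaps, mouth
width and corner curvature, eye–mouth distance and nose length (in
interocular units). Color: per-region mean and SD of CIELAB L, a, b
(CIELAB for perceptual uniformity), plus two contrast features —
cheek-minus-eye and cheek-minus-mouth *linear* luminance (mean RGB).
The contrast features deliberately stay in linear pixel units rather
than Lab L so that a planted darkening of 0.2 is recovered as 0.2;
the oracle is a direct pixel average. Texture: mean modulus and
modulus SD of a 4-orientation (0°, 45°, 90°, 135°) x 3-wavelength
(4, 8, 16 px) complex Gabor bank on the luminance channel over the
interior mask, with sigma = 0.56 x wavelength; even kernels are
DC-corrected so constant images give exactly zero energy.

## Classification and the weighted combination

The base learner is decay-regularized multinomial logistic regression
(`nnet::multinom`, decay 0.01 on z-scaled features), with a config
hook for gradient-boosted trees (`xgboost`). The downstream face-space
algebra only needs calibrated class probabilities, which a linear
model supplies on these features. Neutral is a seventh training class;
the projection later consumes only the six expressive entries.

Splits are stratified by emotion x gender when every cell has at least
two members, otherwise by emotion, with every stratum represented on
both sides; train/test disjointness is asserted in every evaluation.
The combined output renormalizes the accuracy-weighted sum by the
total weight so it stays on the simplex (with equal weights it reduces
to the arithmetic mean). Accuracy comparisons between models are done
by paired binomial reasoning (two standard errors) rather than an
omnibus test.

## Face space, selection, morphing

The circumplex coefficient table (dominance: anger 1, disgust 0.6,
happy 1, fear −0.5, sad −1, surprise −0.5; affiliation: anger −1.5,
disgust −1, happy 2, fear 0.5, sad 0.1, surprise 0.1) is the package
default and the basis of its exact worked examples. Design choices
worth stating:

* The six-emotion vector is **not** renormalized after dropping the
  neutral probability: a mostly-neutral face should sit near the
  origin, which renormalization would destroy.
* Angles use x = affiliation, y = dominance: θ = atan2(D̂, Â), wrapped
  to [0, 360); the origin gets θ = 0 by convention.
* Quadrant windows are inclusive on both ends: I 10–80°, II 100–170°,
  III 190–260°, IV 280–350°, with a strict Ê > 0.15 distance rule.
  The quadrant-IV window is set by symmetry with the other three
  (covering the lower-right quadrant's middle portion); the distance
  and window rules together define "prototypical" faces.
* Ranking ties (prototype pools by descending Ê or class probability,
  origin bases by ascending Ê) are broken lexically by face id for
  reproducibility.

Morphing is a two-image blend: landmarks are averaged pointwise and
both images are piecewise-affine-warped onto the blended shape over a
Delaunay triangulation computed once on the mean template (Bowyer–
Watson, written in-package) and reused everywhere, then pixel-averaged
with bilinear sampling and clipping. A prototype "transform" that adds
a source–target difference and this 50–50 morph coincide at alpha 0.5
up to the base's own deviation from the average — a documented
approximation, not an equivalence. Manual artifact inspection is
replaced by an automated QC flag (landmark bounds and pixel-range
sanity). Donor sampling per base x category is without replacement,
falling back to with-replacement (flagged) for undersized pools.

## Mediation and preprocessing

Mediation uses standardized OLS paths in closed form (a from m ~ x; b
and c′ from y ~ x + m; c from y ~ x), which makes the decomposition
c = c′ + ab an exact identity — asserted on every call at 1e-8. A
binary predictor is standardized like any column. The indirect effect
gets a percentile interval (not BCa) over case-resampled bootstrap
replicates, re-standardized within each replicate; 10,000 resamples by
default. If x and m are perfectly collinear the two-predictor model is
rank deficient; the package then attributes the shared variance to the
mediator (b from y ~ m, c′ via the identity), the natural convention
for a deterministic causal chain. Correlation matrices use `cor.test`
p-values at alpha 0.05 with no multiple-testing correction;
zero-variance cells are NA, not errors.

Trial preprocessing drops whole participants with response SD < 0.4,
then trials with RT < 50 ms or > 10,000 ms, then shifts responses by
−1 to the 0–6 range. The shift is guarded by a range check (only
applied to tables still on the 1–7 scale), which makes preprocessing
idempotent in practice. Mixed-model contrasts on preprocessed trials
are delegated to `lme4`/`lmerTest` behind a thin wrapper — standard
estimation, not re-implemented.

## Problem sizes and numerical conventions

The test suite's heavier checks use: a noise-free 56-face cohort for
separability (each metric must reach held-out accuracy 1.0); a
140-face default-noise cohort for chance-level behavior under permuted
labels (within three binomial standard errors of 1/7); a 336-face
attenuated-signal cohort (fields scaled to 0.4, grain to 0.15,
landmark jitter SD 2 px, pixel noise SD 0.05) where each metric is
partially informative and the weighted combination must not fall more
than two binomial standard errors below any single metric; 200
mediation replications at n = 183 with 1,000 bootstraps each for
recovery of a planted indirect effect ab = 0.16 (mean error below
0.05, interval coverage between 90% and 99%), plus 100 null
simulations; and a 406-face confounded cohort for directional recovery
of the planted male→anger / female→fear association. Pixel coordinates
are 0-based, x rightward, y downward; polygon rasterization includes
boundary pixels; all probability vectors are checked to sum to 1
within 1e-9.

## Known limitations

Procedural faces have no photometric realism, so absolute accuracy
numbers on synthetic cohorts say nothing about accuracy on real
photographs. Landmark detection is out of scope — landmarks are an
input. The texture channel's oriented grain is an identifiability
device, not a model of skin microstructure. The circumplex projection
is linear by construction and inherits the coefficient table's scale;
positions are comparable within a run, not across coefficient tables.
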