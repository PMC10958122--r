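---
title: "Temporal inpainting of endoscopic specular highlights: models and methods"
author: "SpecFill"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal inpainting of endoscopic specular highlights: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(SpecFill)
```

## The problem

Specular highlights are mirror-like reflections of the light source on wet
tissue. In gastrointestinal endoscopy they saturate the sensor, occlude the
mucosal texture (veins, pits, lesions), and introduce bright, fast-moving
false features that corrupt downstream vision tasks: sparse feature
matching, optical flow, relative camera-pose estimation and stereo
disparity. Unlike object occlusions, specularities jump, appear and
disappear between frames, so the texture hidden in one frame is often
visible in a neighbouring frame at the same tissue location.

SpecFill implements a fully unsupervised pipeline that exploits this:

1. **detect** specular highlights per frame with a chromaticity rule;
2. **construct pseudo ground truth** by translating the detected masks onto
   unoccluded tissue, so the content "behind" the translated mask is known;
3. **inpaint** with a spatial-temporal transformer generator trained
   adversarially, which searches for matching feature patches spatially
   *and* across neighbouring and distant frames;
4. **evaluate** with masked image metrics and with the effect on
   correspondence-based geometry (pose, disparity).

Everything is testable offline because a seeded synthetic generator
produces endoscopy-like clips, calibrated two-view scenes and stereo pairs
with exact ground truth.

## Highlight detection

Detection builds on the dichromatic reflection model: the
interface (specular) reflection is bright and colourless while the body
reflection of mucosa is strongly red-saturated. Published detectors of this family do not
agree on fixed constants, so `detectSpecularMask()` implements the
standard two-criterion rule with every constant exposed in
`detectionParams()`:

* **absolute rule**: HSV value > 0.85 and HSV saturation < 0.25;
* **relative rule**: any channel exceeding 1.5 times its local median in a
  15 px window (catches bright-but-not-saturated highlights);
* connected components below 5 px² are discarded as noise.

The defaults were chosen once against the synthetic generator: the
saturated blob cores it renders satisfy the absolute rule by construction,
and a uniform red field triggers neither rule.

## Pseudo ground truth

A raw detection is first dilated with a **diamond** element (radius 1) to
close pixel noise, then with an **ellipse** (radii 5 × 3) because
specularities carry darkened rings around the saturated core that must be
inpainted too; an elliptical element preserves the rounded shape of real
specularities better than box or cross elements. The mask is then
**translated by a fixed offset for the whole sequence** — by default 20 %
of the frame width to the right, far enough to land on unoccluded tissue —
and any overlap with a **ball**-dilated (guard radius 3) copy of the
original detection is removed, so the pseudo mask only covers pixels whose
true texture is known.

Two orderings exist:

* **training** variant: dilate (ellipse) → translate → remove overlap;
* **evaluation** variant: translate → remove overlap → dilate (ellipse).

The evaluation ordering can re-enter the guard zone through its final
dilation, which would break the defining property that pseudo masks cover
only originally-valid pixels; `makePseudoMask()` therefore re-applies the
overlap removal after the final dilation. Both variants are asserted
disjoint from the guard-dilated detection in the test suite. Whether the
training ordering should also guard-dilate the original before overlap
removal is genuinely open; the package applies the guard in both variants,
defaulting both to the same radius, each independently configurable.

For the initialisation training phase, `bezierRandomMasks()` generates one
random star-shaped blob per sequence and moves its centroid along a cubic
Bezier curve. The control points are spaced so that the curve's velocity
bound (three times the largest control-point gap) keeps the per-frame
centroid displacement below about half the blob radius — this is what
makes the motion "smooth" in a testable sense (consecutive-frame IoU stays
above 0.5).

## The generator

Frames are masked (`X = Y ⊙ (1 − M)`, holes zeroed in `[-1, 1]` space) and
encoded frame-by-frame with a 2-D convolutional stack containing two
stride-2 convolutions, giving feature maps at 1/4 resolution. A stack of
transformer layers then runs three steps per head:

* **embedding**: 1 × 1 convolutions map features to query, key and value;
* **matching**: each head splits its channel slice into non-overlapping
  `r1 × r2` patches across *all* frames of the window and scores every
  query/key pair with the normalised dot product
  `s = (p_q · p_k) / (r1 r2 c)`;
* **attending**: softmax weights over the *valid* patches only (a patch is
  invalid iff it intersects the hole region at feature scale; invalid
  patches receive weight exactly 0 and are excluded from the softmax
  denominator, so the weights over the unoccluded region sum to 1), then a weighted sum of
  value patches.

Heads run at different patch scales (default schedule for 288 × 288 input:
72², 36², 18², 9² on the 72 × 72 feature map — a coarse-to-fine ladder
whose sizes all divide the feature map; no canonical schedule exists for
square inputs, so this ladder is a package default and fully
config-driven). Head outputs
are concatenated, fused by a 1 × 1 convolution with a residual connection,
and passed through a two-convolution feed-forward block, again residual.
Multiple layers (default 8) let later layers attend with already-updated
hole features. A convolutional decoder with nearest-neighbour upsampling
maps back to full resolution with a tanh output.

Numerical choices: the softmax is stabilised by max-subtraction; a query
row with *no* valid key (e.g. an all-hole window at the coarsest head) is
returned as an all-zero attention row and flagged degenerate, so the
residual path passes the encoder feature through unchanged and the output
stays finite. With compositing enabled (the default), the final output is
`X ⊙ (1 − M) + Ŷ ⊙ M`, so valid pixels pass through bit-exact.

Temporal conditioning follows the multi-to-multi formulation: each group
of `2n + 1` consecutive target frames is processed together with distant
frames sampled at stride `s` across the whole clip (defaults `n = 2`,
`s = 10`, both config keys). Forcing single-frame windows (`temporal = FALSE`) is the
no-temporal ablation.

## Losses and training

The objective is `L = λ_hole L_hole + λ_valid L_valid + λ_adv L_adv` with
the standard weights λ_hole = λ_valid = 1, λ_adv = 0.01. The two L1 terms
are means of absolute error over hole and valid pixels respectively, each
normalised by its own pixel count. The adversarial pair is the hinge
formulation of a spatio-temporal patch discriminator (three 3-D
convolutions, kernel 3 × 5 × 5, spatial stride 2): the generator minimises
`-mean(D(fake))`, the discriminator minimises
`mean(ReLU(1 - D(real))) + mean(ReLU(1 + D(fake)))`. A zero-initialised
critic therefore scores every patch 0 and has discriminator loss exactly
2, a useful analytic anchor.

The whole network — convolutions via im2col and BLAS matrix products,
attention, fold/extract — is implemented with hand-written forward and
backward passes; the backward pass is verified against central finite
differences to 1e-4 in the test suite. Optimisation is Adam. The
full-scale defaults (`trainSchedule()`) are learning rate 1e-4,
β = (0, 0.99), batch of 2 windows and a 1:1 generator/discriminator update
ratio; these optimiser settings are package decisions.

Training runs in two phases (transfer learning): an initialisation phase
on random Bezier masks, then fine-tuning on the translated pseudo masks.
Checkpoints store parameters, Adam moments, the loss log and the RNG
state, so a resumed run reproduces the remaining loss log bitwise.

**Desk-scale demonstration sizes.** The tests and the acceptance script
train a reduced configuration — 64 × 64 frames, 32 channels, one
transformer layer, heads 8² and 4² on the 16 × 16 feature map — for 300
iterations on a single 8-frame synthetic clip with learning rate 3e-3 and
β₁ = 0.5 (a single-clip overfit converges faster with momentum than the
full-scale β₁ = 0 setting). This drops the hole loss by more than 90 % and
is enough to demonstrate every architectural property, including the
temporal-versus-single-frame ordering; it says nothing about perceptual
quality on real endoscopy, which requires full-scale training on real
video.

## Classic baselines

* `diffusionInpaint()` fills holes with the harmonic interpolant of the
  boundary values (Laplace equation, Dirichlet boundary, reflecting image
  border), solved exactly as a sparse linear system or iteratively
  (Jacobi). Harmonic fills are maximum-principle bounded and reproduce
  linear ramps, which the tests exploit.
* `temporalPatchInpaint()` is a greedy onion-peel exemplar search: hole
  patches are processed boundary-first; candidates within a
  spatio-temporal window (fully valid under the original masks) are scored
  by SSD over the known overlap, normalised by overlap size; ties break by
  smallest temporal offset, then raster order; the unknown pixels are
  copied from the winner. If no candidate exists, the window widens before
  erroring.

Both are identity outside the mask, bit-exact. They are deliberately
canonical, simplified versions sufficient for the qualitative-ordering
experiments the package reproduces.

## Evaluation

Masked metrics are computed at the pseudo-mask region on the 8-bit scale:
MSE and PSNR (`10 log10(255² / MSE)`, capped at 100 dB for identical
content and flagged), and SSIM computed on the *full frame* first (11 px
Gaussian window, σ = 1.5, standard constants — window parameters are
package defaults) and then averaged over the region of interest, so
local-window statistics are well defined at mask borders. Aggregation is
two-level: mean over frames within a video, then the unweighted mean over
videos, with an evaluation-time cap of 927 frames per video (configurable).

Disparity error metrics over a region of interest are RMS, endpoint error
(mean absolute difference) and Bad3 (percent of pixels whose absolute
error strictly exceeds 3 px), with stereo-occluded pixels includable,
excludable or ignored. Improvement is reported as the signed relative
difference `100 (orig − inp) / orig`.

## Correspondence geometry

The downstream harness quantifies how inpainting changes correspondence:

* `matchFeatures()` detects Harris corners and describes them with a
  256-bit BRIEF-style binary descriptor on the smoothed image, matched
  brute-force by Hamming distance with Lowe's ratio test (default 0.75,
  the canonical value). The original pipeline uses ORB; no R
  implementation of ORB exists, and this detector/matcher is the same
  family (binary descriptors, brute-force matching, ratio filtering),
  which is what the harness's conclusions depend on. It is not
  rotation-invariant, which is irrelevant for the small inter-frame
  rotations of endoscopic video and for the synthetic tests.
* `estimateRelativePose()` estimates the essential matrix with a
  **five-point minimal solver** inside RANSAC. The solver builds the
  4-dimensional null space of the 5 × 9 epipolar system, imposes
  `det(E) = 0` and the trace constraint `2 E Eᵀ E − tr(E Eᵀ) E = 0`
  (ten cubic polynomials in three unknowns), and reads all real solutions
  off the eigen-decomposition of the action matrix of multiplication by
  one variable in the degree-two monomial basis of the quotient ring.
  Inliers are scored by Sampson distance (threshold 1 px divided by the
  focal length; confidence 0.999, at most 2000 iterations, seeded), the
  consensus set is refit linearly and projected back onto the essential
  manifold, and the four decompositions are disambiguated by the
  chirality check (most triangulated points in front of both cameras).
  The translation is returned unit-norm.
* **Degeneracy**: under pure rotation every translation direction is
  epipolar-consistent, so the solver's elimination collapses. Before
  RANSAC the harness fits a rotation-only model by Procrustes alignment
  of the bearing vectors; if its median angular residual is within three
  times the inlier threshold the pair is flagged degenerate (and the
  Procrustes rotation returned if RANSAC finds nothing).
* `translationError()` folds the ± sign ambiguity of the essential-matrix
  translation (`min(θ, 180° − θ)`) to avoid spurious 180° errors;
  `rotationError()` is the geodesic angle.
* `windowPairs()` pairs frames `(i, i + 20)` with stride 1 by default
  (stride is a config key), and `summarizePoseErrors()` reports Min/Max/Mean/quartiles/IQR of
  the per-pair difference `orig − inp` with linear-interpolation
  quantiles, plus a mean per-pair signed relative difference in percent.
  Summary tables in this field often mix percent means with native-unit
  medians without defining the normalisation, so the convention is stated
  here and carried in the outputs; pairs with a zero original value are
  excluded from the relative mean.
* `estimateFlow()` is a compact pyramidal Lucas-Kanade dense flow used as
  the in-repo correspondence provider for tests; production flow networks
  are out of scope and pluggable via `flowToMatches()`.

## The synthetic generator

`generateClip()` emulates what matters for this pipeline and nothing more:

* a reddish multi-octave value-noise texture with dark Bezier vein curves
  (endoscopic scenes have few distinctive features, mostly vasculature);
* temporally coherent global motion (translation drift, slow rotation,
  sinusoidal wobble) sampled from a larger canvas;
* saturated highlight blobs with a clipped-Gaussian profile and a
  multiplicatively darkened ring — the ring exists specifically to
  exercise the elliptical dilation stage — that jitter, jump with a
  configurable probability and blink in and out, mimicking the
  discontinuous motion of real specularities.

The returned mask marks every modified pixel (core and ring), and the
corrupted clip equals the clean clip outside it exactly. What it does
*not* model: perspective parallax and non-rigid deformation of tissue,
physically based reflectance, fluids, instruments and interface overlays.
Passing tests therefore demonstrate correctness of the algorithms and the
claimed orderings under controlled conditions, not clinical image quality.
Two-view scenes (`generateTwoViewScene()`) and disparity-warped stereo
pairs (`generateStereoPair()`) carry exact geometric ground truth: the
essential matrix of a noiseless scene annihilates every correspondence to
machine precision.

## Conventions and limitations

Frames are `(H, W, 3, T)` arrays in `[0, 1]`; masks `(H, W, T)` with
1 = hole; indices are 1-based throughout, in keeping with R; translations
are `(dx, dy)` = (columns right, rows down). PNG I/O uses `%05d.png`
frame directories with masks as 0/255 single-channel PNGs. mp4 extraction
delegates to an `ffmpeg` executable on the PATH and errors cleanly
without one.

Known limitations: the detector inherits the weaknesses of chromatic
rules (overlaid UI text and graphics can be detected as specularities;
saturated non-specular regions are missed); the desk-scale model is a
demonstration, not a clinically useful restorer; the patch baseline is
single-scale and greedy; and SSIM over very small regions of interest
should be interpreted with caution since few windows contribute.
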