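---
title: "Synthetic trabecular phantoms, image translation and bone morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic trabecular phantoms, image translation and bone morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(trabeculagen)
```

## The problem

Trabecular bone microarchitecture — bone volume fraction (BV/TV), mean
trabecular thickness (Tb.Th) and separation (Tb.Sp) — predicts bone strength
beyond what bone mineral density captures, but measuring it requires
micro-CT resolution (tens of micrometres), which is not available in vivo.
Clinical MDCT reaches only ~0.2–0.5 mm in plane with 0.6 mm slices. The idea
studied here is to learn an unpaired image-to-image mapping from MDCT slices
to micro-CT-like slices and then run standard morphometry on the translated
images.

Real paired cadaver scans are not publicly available, so this package makes
the whole chain testable on synthetic vertebral phantoms whose ground-truth
microstructure is known by construction. Every stage — phantom, rendering,
slice pairing, translation model, morphometry, statistics — is implemented
and verified against independent oracles.

## The phantom generator

`generate_trabecular_volume()` builds a binary microstructure by
thresholding an anisotropic band-pass-filtered Gaussian random field (white
noise smoothed at scale $\sigma$ minus the same noise smoothed at $2\sigma$,
variance-normalised). A random field was chosen because it gives a tunable,
plate/rod-like interconnected texture with exact volume-fraction control: the
threshold is the empirical quantile of the field inside the cancellous
region, so $|\mathrm{BV/TV}_{\mathrm{true}} - \mathrm{target}|$ is at most
one voxel's worth by construction.

There is no closed form linking the filter scale to the realised Tb.Th, so
the scale is calibrated: the generator measures Tb.Th on a small (56³)
calibration cube and adjusts the scale multiplicatively over three
iterations; the result is cached per (voxel size, target, anisotropy)
condition. On the default 52 µm grid the realised ground-truth Tb.Th lands
within ±20% of the target (verified in the tests); the realised Tb.Sp
follows from the field geometry and is recorded as ground truth rather than
controlled independently — at BV/TV 0.18 the band-pass field yields a
Tb.Sp/Tb.Th ratio around 3, somewhat below the ~4.3 of reference lumbar
specimens. Anatomy is deliberately schematic: an elliptical body
cross-section (optionally notched by a circular canal), a cortical shell of
configurable thickness added within the body boundary, soft tissue outside.

Key parameters (defaults): BV/TV 0.180, Tb.Th 0.218 mm, Tb.Sp 0.934 mm
(reference micro-CT values for lumbar cancellous bone), 52 µm isotropic
voxels, axial anisotropy weight 1.3 (trabeculae elongated along the primary
compressive direction), cortical shell 0.4 mm, intensity levels bone 200,
marrow 50, soft tissue 80 on the 8-bit scale (CT numbers are not modelled;
these are conventions, not fits to any scanner). Feasibility guard: a target
Tb.Th below two voxels is refused by name, since thickness cannot be
represented below that limit.

Renderers: `render_micro_ct()` relabels the binary volume to the intensity
levels, applies a mild sub-voxel PSF (Gaussian, σ = 0.3 voxel) and additive
Gaussian noise (sd 8 by default). `render_mdct()` blurs the continuous
intensity field with a separable Gaussian PSF (FWHM 0.4 mm in plane, 0.6 mm
axially — inside the 200–500 µm clinical resolution range), resamples to the
MDCT grid (0.195 mm pixels: a 512 matrix over a 100 mm field of view) with
half the micro-CT slice count over the same extent (the 2:1 ratio used for
pair replication), adds noise (sd 4) and quantises to 8 bits. With the PSF
and noise disabled the renderings are pure two-level relabelings and IsoData
re-binarisation recovers the ground truth exactly — the identity the tests
pin down.

`make_study_set()` jitters per-vertebra targets around the template
(BV/TV sd 0.016, Tb.Th sd 0.015 mm, matching the between-specimen spread of
the reference data) and derives every per-vertebra seed from one master
seed.

## Morphometry

`isodata_threshold()` iterates the intermeans map
$t_{k+1} = (\mu_{\le t_k} + \mu_{> t_k})/2$ on the 8-bit histogram from the
masked mean to a fixed point. The tests check it against an exhaustive
search over all integer histogram cuts. One global threshold is used per VOI
(a per-slice mode exists behind a flag).

Local thickness follows the largest-inscribed-sphere definition: the
thickness at a voxel is the diameter of the largest sphere containing it
that fits in the phase. Implementation: exact Euclidean distance transform
(Felzenszwalb–Huttenlocher parabolic envelopes), a distance-ridge reduction
that removes centres whose sphere lies strictly inside a neighbour's (ties
kept, so the reduction can only add redundant paint sources, never lose a
maximal sphere), and sphere painting. Conventions, pinned by the tests: the
sphere radius at a centre voxel is the distance to the nearest background
voxel centre minus half a voxel, and a voxel is covered when its centre lies
strictly inside the sphere. This makes a 3-voxel slab measure exactly 3 and
an isolated voxel exactly 1; on strongly curved digitised shapes (a small
ball) the measure is conservative by up to ~1.5 voxels relative to the
continuous diameter — the digitisation cost of restricting sphere centres to
the lattice, shared with the standard implementations of this measure and
with the brute-force oracle used in the tests. Tb.Th averages the
bone-phase map over the mask; Tb.Sp applies the identical measurement to the
background phase; standard deviations are over voxels. Complement duality
(Tb.Th of the inverted volume equals Tb.Sp) holds exactly. Anisotropic
stacks (MDCT) are resampled to isotropic voxels first, since the sphere
definition assumes them; thickness maps are computed on the VOI's bounding
box, so spacing spheres are bounded by the crop, as in common practice.

The VOI is a cylinder, default 15 mm diameter × 5 mm height, axis along the
slice normal. `position_voi_from_body_mask()` reproduces the anterior
construction: take the sagittal midline of the axial body mask, find its
intersection with the anterior edge, move 5 mm interior to get the tangent
point, and place the cylinder tangent to it extending posteriorly; the two
VOIs sit 5 mm above and below the mid-transverse plane. A cylinder that
leaves the body mask is flagged `clipped`.

## Slice pairing

MDCT and micro-CT stacks of one specimen have a 2:1 slice-count ratio and no
recorded correspondence. The pairing stage upsamples each MDCT slice
(bicubic) to the micro-CT in-plane grid — keypoint coordinate distances are
only comparable on one grid — detects difference-of-Gaussian keypoints with
SIFT-style 4×4×8 gradient-orientation descriptors, matches them with the
Lowe ratio test (0.75) plus mutual-nearest-neighbour filtering, and takes
the mean Euclidean distance between matched coordinates as the slice-pair
distance. Dominant-orientation normalisation is omitted: the stacks are
axially aligned by construction, and in-plane rotation search is out of
scope. Pairs with fewer than three matches get the sentinel distance
`max(finite) + 1`, keeping the subsequent dynamic program total.

`dtw_align()` is the standard dynamic time warping program over the distance
matrix with steps (1,0), (0,1), (1,1); backtracking ties prefer the
diagonal, then the micro-advance, then the MDCT-advance, fixing a unique
deterministic path. Optimality is verified against exhaustive monotone-path
enumeration on 200 random matrices. `replicate_and_pair()` assigns every
micro slice the MDCT slice the path gives it (the first, when the path
visits several), so 250 MDCT + 500 micro slices give exactly 500 one-to-one
pairs. On phantom stacks, where slice `2j−1` of the micro stack is the true
partner of MDCT slice `j`, at least 90% of recovered pairs fall within ±1
slice at default noise.

## The translation model

The generator decomposes into a content encoder $E_x$ (instance-normalised
convolutions, three stride-2 stages, residual blocks; a 64×64 slice becomes
an 8×8 spatial code), a class encoder $E_y$ (plain convolutions, global
average pooling, a fully connected head; codes of K class images are
averaged), and a decoder $F_x$ in which two fully connected networks map the
class code to one scale/bias pair per AdaIN residual block (scales kept
positive through a softplus), applied uniformly at every spatial location,
followed by nearest-neighbour ×2 upsampling stages and a tanh output. The
discriminator is a two-class patch discriminator: a stem convolution, ten
Leaky-ReLU residual blocks without normalisation interleaved with four 2×2
average poolings (64×64 input → 4×4 score map), and a final convolution with
one channel per class.

Training alternates a discriminator ascent step on the saturating objective
$\mathbb{E}\log D^{c_x}(x) + \mathbb{E}\log(1 - D^{c_y}(\bar{x}))$ with a
generator descent step on the adversarial term plus
$\lambda_R \|x - G(x,x)\|_1$ and
$\lambda_F \|D_f(\bar{x}) - D_f(y)\|_1$, where $D_f$ is the discriminator
minus its last layer. The generator uses the non-saturating surrogate
$-\log D^{c_y}(\bar{x})$ by default (the literal form stalls early training;
the optimum is unchanged, and a config flag restores the literal form). Each
iteration draws one image from each of the two classes in random order, so
the discriminator sees both classes as real and as fake across iterations.
Defaults: $\lambda_R = 0.1$, $\lambda_F = 1$, RMSProp with learning rate
1e-4, probabilities clamped at 1e-7 inside logarithms; one master seed
drives weight initialisation and batch sampling, and a reloaded checkpoint
reproduces the forward pass bit-identically.

All forward and backward passes are written in the package (im2col GEMM
convolutions in C++, layer algebra in R, double precision). Analytic
gradients of the full composite losses agree with central finite differences
to 1e-4 relative on toy networks — the single strongest correctness check a
hand-written backpropagation can offer.

Channel widths are configurable; the defaults are deliberately thin (stem
width 4 for both generator and discriminator) so that a 2,000-iteration
smoke training on 64×64 phantom slices completes in minutes on one CPU while
still beating bicubic upsampling on the feature Fréchet distance and
improving paired SSIM over the untrained model. Width multipliers restore
heavier regimes when hardware allows; the package makes no claim of matching
any particular full-scale training run.

## Evaluation

SSIM uses the standard 11×11 Gaussian window (σ 1.5), $C_1=(0.01L)^2$,
$C_2=(0.03L)^2$, averaged over fully contained windows, on 8-bit images
(L = 255); for paired comparisons the pairs come from the DTW alignment or,
for phantoms, from the known ground-truth correspondence. The Fréchet
distance is computed between Gaussian fits of image-set feature embeddings
with a symmetric eigendecomposition square root (small negative eigenvalues
clipped at −1e-8; singular covariances get a logged ridge). Without network
downloads there is no pretrained embedding, so the default embedder is a
seed-frozen random convolutional projector (two strided conv+ReLU stages,
per-channel mean and sd pooling, 16 features — narrow enough that
desk-scale slice sets give well-conditioned covariances). Random projections
preserve coarse texture statistics well enough to order "blurry upsampled"
versus "sharp translated" sets, but the values are comparable only within
one run configuration; every report header says so, and a hook accepts a
user-supplied pretrained extractor.

The statistical battery wraps the standard R tests (Kolmogorov–Smirnov,
Levene via `car`, Friedman, Mann–Whitney U, paired t, OLS with
$F = R^2(n-2)/(1-R^2)$, Fisher-z comparison of two correlations). One
defined edge case: on fully tied rows the Friedman statistic is 0 by
definition, where the ties-corrected formula degenerates to 0/0. ICC uses
the two-way random-effects, absolute-agreement, single-measures form
(ICC(2,1)) with F-based confidence bounds — the form appropriate for "do two
measurement methods agree in value", which is the question asked of
generated versus reference morphometry; consistency-type ICCs would forgive
scale bias and are not used.

## What the phantoms do and do not show

The phantoms emulate: two-phase trabecular texture with controllable
morphometry, partial-volume blur and noise at both resolutions, the 2:1
slice-count ratio, a cortical shell and a soft-tissue background. They do
not emulate: CT physics (beam hardening, scatter, reconstruction kernels),
marrow heterogeneity, posterior elements beyond a simple canal, fixation
effects, or between-specimen anatomical variability beyond target jitter. A
translation model that works here has been shown to learn a resolution/texture
mapping under controlled conditions — not to work on clinical data. The same
applies to the statistics: passing tests demonstrate correct implementations,
not clinical conclusions.

## Problem sizes used in the checks

The shipped tests and the acceptance script run at desk scale, chosen so the
whole suite completes on one CPU: phantoms at 0.1 mm voxels (Tb.Th target
2.2 voxels, just above the feasibility limit; the 52 µm default is exercised
on a smaller extent), 15 mm × 5 mm VOIs on 19 mm phantoms, 64×64 training
slices, 2,000 smoke-training iterations, and oracle sweeps of 200 (DTW) and
100 (IsoData) random cases. The 25×(250+500)-slice pairing worked example
runs with the keypoint stage stubbed by a precomputed quasi-diagonal
distance matrix; the keypoint path itself is exercised on full small stacks
where ground-truth correspondence is known.

## Known limitations

* Tb.Sp is an emergent property of the random field, not an independently
  controlled target.
* The local-thickness value on strongly curved digitised structures is
  conservative (lattice-restricted sphere centres); comparisons against the
  brute-force oracle share the convention, and the Tb.Th calibration absorbs
  the bias for the generator's targets.
* The default feature embedder is a random projector; Fréchet distances are
  run-configuration-relative.
* The keypoint detector omits rotation invariance; stacks must be axially
  aligned, which the phantom geometry guarantees.
* Training at full-scale image sizes and widths is reachable by config but
  not validated here.
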