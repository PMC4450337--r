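---
title: "Two-layer adaptive diffeomorphic registration: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-layer adaptive diffeomorphic registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepdemons)
```

# The problem

Deformable registration seeks a spatial transform $T$ that aligns a moving
image $M$ with a fixed image $F$ by optimizing a similarity energy
$S(F, M \circ T)$.  The standard two-step strategy — one affine
preregistration followed by iterative nonrigid refinement — breaks down
when the moving image is simultaneously rotated by a large angle *and*
heavily deformed: feature-correspondence affine estimators (SURF-style
keypoints, mutual-information affine search) lose their matches, the
preregistration misfires, and the nonrigid stage converges to the wrong
basin.

`deepdemons` implements a two-layer alternative.  The affine layer
estimates rotation, scale and translation *separately* — rotation with a
convolutional classifier trained on difference images, scale and
translation from intensity moments, which remain well-defined under severe
deformation.  The nonrigid layer is diffeomorphic log-demons.  The two
layers alternate: each demons pass removes deformation, which lets the
next affine pass re-estimate the linear part more accurately, and so on
until the similarity metric stops improving.

# The nonrigid layer: diffeomorphic log-demons

The transform is parameterized by a stationary velocity field $v$; the
warp is its group exponential $\varphi = \exp(v)$, computed by scaling and
squaring: divide $v$ by $2^N$, treat the result as a small displacement,
and compose it with itself $N$ times.  Parameterizing in the log domain
keeps the transform diffeomorphic (smooth, invertible — certified
numerically by a positive Jacobian determinant) and makes inversion
trivial: $\varphi^{-1} = \exp(-v)$.

Each iteration computes a demons force from the intensity mismatch.  With
$f = F(p)$, $m = M(\varphi(p))$ and image gradients $\nabla f$, $\nabla m$:

* Thirion force: $u = \dfrac{(m-f)\,\nabla f}{\|\nabla f\|^2 + (m-f)^2}$
* symmetric force: $u = \dfrac{(m-f)\,\nabla f}{\|\nabla f\|^2 + \alpha^2 (m-f)^2}
  + \dfrac{(m-f)\,\nabla m}{\|\nabla m\|^2 + \alpha^2 (m-f)^2}$

The $(m-f)^2$ term self-stabilizes the denominator; a hard guard zeroes
the force where the denominator falls below $10^{-9}$ (exactly-zero
gradient with matched intensities).  $\alpha$ (default 1, exposed in
`demons_config()`) trades force strength against stability.

These formulas give the velocity of *moving-image content* toward the
fixed image.  The package warps in pull-back convention
(`out(x) = img(x + disp(x))`), under which that velocity enters the
log-domain update with a negative sign:
$v \leftarrow \mathrm{smooth}_{\sigma_d}\!\big(v - \mathrm{smooth}_{\sigma_f}(u)\big)$,
a first-order log-domain (BCH) update with fluid smoothing
$\sigma_f = 1$ px on the update and diffusion smoothing $\sigma_d = 1$ px
on the velocity (both Gaussian, reflect boundary, exposed in the config).
The energy is the SSD $\sum (F - M\circ\exp(v))^2$, and each pyramid
level stops when the relative metric change over a 5-iteration window
falls below `stop_tol` ($10^{-4}$) or after `max_iter` (50) iterations.

Registration is three-level coarse-to-fine (Gaussian blur, decimate by 2);
the velocity field is upsampled and doubled between levels.

## Numerical choices

* **Exponential map step size.**  $N$ is the smallest integer with
  $\max\|v\|/2^N \le 1/32$ px.  The scaling-and-squaring error of the
  first-order small step decays like $2^{-N}$; with a 0.5 px cap a linear
  rotational field misses its matrix-exponential value by about
  $5\times10^{-3}$ px, while the 1/32 px cap brings interior agreement
  below $10^{-3}$ px for warps up to several pixels of amplitude, at the
  cost of a handful of extra compositions.
* **Force choice and plateau behavior.**  The symmetric force roughly
  doubles the per-iteration step and reaches lower energy in fewer
  iterations, but near its plateau the update overshoots and the energy
  trace oscillates within a few percent of the level's starting energy;
  the single-force (Thirion) update descends near-monotonically
  (transients under 2%).  No damping factor is introduced — the method
  defines none — so the tests assert monotonicity for the Thirion force
  and bounded transients plus overall descent for the symmetric one.
* **Boundary handling.**  Warps clamp to the edge (replication): sampled
  intensities stay in the observed range, and no artificial zero edges
  perturb the demons forces.  Field compositions use the same rule.
* **Denominator guard.** $10^{-9}$, with $u = 0$ fallback.

# The affine layer

## Rotation: a CNN classifier on difference images

Rotation between $F$ and $M$ is treated as classification: each angle on a
grid of $c$ classes ($c \in \{360, 180, 90, 36\}$) is one class, and the
classifier input is the absolute difference image $|F - M|$ of the
\[0, 1\]-normalized pair, resized to the network's input side.  The
difference keeps its magnitude: per-sample min-max rescaling would blow
the near-zero difference of a correctly derotated pair up into a
full-range pattern unlike anything seen in training, which matters both
for the zero-rotation class and for residual re-estimation inside the
outer loop.  For training, each base image is rotated to every class
angle and the difference images are labeled by angle.

The network alternates valid convolutions and $2\times2$ mean-pooling
subsampling layers — kernel sides 9, 5, 5, 5 — so a $128\times128$ input
traverses map sides $120, 60, 56, 28, 24, 12, 8, 4$; smaller inputs keep
the leading pairs that fit (a $28\times28$ input ends at $3\times3$).
Convolutional layers carry one shared kernel per *input* map; output map
$j$ is $f(\sum_i \alpha_{ij}\, x_i * k_i + b_j)$ with the combination
weights constrained to the simplex ($\sum_i \alpha_{ij} = 1$,
$\alpha_{ij} \ge 0$, re-projected after every update).  Subsampling
computes $f(\beta_j\,\mathrm{down}(x_j) + b_j)$ with non-overlapping mean
pooling.  The activation is the logistic sigmoid throughout.  A full
connection maps the final maps to per-class sigmoid output units; reported
scores are normalized to sum to one.

Training minimizes the total square error
$E = \tfrac12 \sum_n \sum_k (t_k^n - y_k^n)^2$ by mini-batch gradient
descent (batch size 10), with every parameter — kernels, biases, pooling
multipliers, $\alpha$, full-connection weights — updated from analytic
gradients that match central finite differences to $<10^{-4}$ relative
error on a toy network.

Two design points deserve explanation:

* **Output units.**  Squared-error training *through* a softmax Jacobian
  has gradients of order $1/c^2$; with $c = 36$ the stack provably sits on
  a plateau at chance level and, at higher learning rates, collapses into
  saturation.  Per-class sigmoid outputs under the same squared-error loss
  are the classical, trainable combination used by this network family,
  and normalizing the sigmoid scores preserves the probability-like
  interface (scores sum to 1; an all-zero output layer scores every class
  $1/c$).
* **Initialization.**  Each logistic sigmoid attenuates signal variance by
  its slope $1/4$, and a conv+pool pair contains two of them.  With plain
  Glorot initialization the inter-sample variance of the final features
  collapses to $\sim 3\times10^{-5}$ — numerically informative but
  unlearnable at finite learning rates.  Kernels are therefore initialized
  with an 8-fold gain over the Glorot envelope, and pooling layers start
  at $\beta = 4$, $b = -\beta/2$ (a unit-gain, centered pooling sigmoid).

## Scale and translation from intensity moments

Scale and translation are rotation-invariant measurements, so they are
estimated independently of the classifier:

* **Translation** is the difference of intensity centroids.
* **Scale** is the ratio of foreground radii of gyration.  Foreground is
  defined by the *fixed* image's Otsu threshold applied to both images,
  weighting each pixel by its intensity excess above the threshold.
  Re-running Otsu per image lets the threshold jump as resampling reshapes
  the histogram (up to 2.8% scale error on the recovery suite); the shared
  soft threshold is continuous and measures 0.7% worst-case.

Because the moment estimators do not depend on rotation, the package
estimates scale and translation first, rectifies a classification copy of
$M$, and lets the classifier see a difference image close to its
pure-rotation training regime.  The three corrections are composed into
one affine map and applied with a single bilinear resampling.

## Triplanar 3D preregistration

For volumes, the classifier estimates *slice position* instead of
rotation: one CNN per axis, each class a bucket of consecutive slice
indices (default 8 slices per class, exposed; the coarsest granularity at which the networks reliably memorize their training slices, which exact recovery presumes).  Ten label points are drawn
from a Normal distribution centered mid-volume (sd = dims/6, clipped to an
interior margin); the three orthogonal slices through each point are
classified, and the integer translation in a $\pm8$-voxel window
minimizing the total Hamming distance between predicted and shifted label
buckets is applied.  Slices are recentred on their intensity centroid (by
an integer shift) before classification, which makes the representation
invariant to the in-plane translation that a volume shift induces.  Ties
in the Hamming objective — unavoidable when a within-bucket shift moves no
label point across a bucket boundary — break by the per-voxel SSD between
the fixed volume and the shift-corrected moving volume on their overlap,
then by the smaller L1 norm; with perfect slice classifiers this makes
integer-shift recovery exact.  The search family is restricted to
translations: the transformation family of the Hamming adjustment is
otherwise unconstrained, and translation is the component the slice
representation actually measures.

# PCA-combined similarity metrics

Beyond SSD, the package scores similarity with Pearson, Spearman, or
Kendall correlation, either on raw intensities or on PCA projection
scores.  For 2D, the rows of the image are the sample vectors; the basis
is fit on the fixed image's rows and *both* images are projected onto it
(separate bases would put the two score matrices in incomparable
coordinates), keeping components explaining 95% of variance, capped at 32.
For 3D, PCA is applied to every slice along each axis, per-slice score
matrices are summed into one per-axis summary, and the metric compares the
concatenated summaries of the three axes.  Component signs are fixed by
the largest-loading-positive rule; Kendall is tau-a (no tie correction —
metric inputs are continuous); Spearman uses average ranks.

Convergence traces are reported per pyramid level; for cross-metric
comparison the package applies the mean-then-normalize rule — per-iteration
mean across levels, then min-max scaling to $[0,1]$ — with equal iteration
budgets per metric.  The normalized trace is oriented to descend
(correlations ascend and are flipped) and a metric's convergence iteration
is the first at which it has completed 95% of its total normalized
descent; raw-scale change rules would penalize metrics whose noise floor
is small relative to their range.

# The outer loop

`two_layer_register()` alternates preregistration and multiresolution
demons for up to `outer_iters` (default 3) iterations, stopping when the
configured metric improves by less than `tol` ($10^{-3}$, relative).
Rotation is re-estimated every iteration by default — the residual pair
changes as deformation is removed — with a flag to freeze it after the
first pass.  The composed transform is carried as a dense
source-coordinate map, so the output image is always a *single*
interpolation of the original moving image regardless of how many stages
ran; the affine part composes first, the displacement second.

# What the synthetic data emulates — and what it does not

The generator provides four phantom families (`blobs`, `rings`, `bars`,
`brainlike`) plus smooth random diffeomorphic warps (Gaussian-smoothed
white noise, rescaled to a stated maximum amplitude, exponentiated — the
Jacobian stays positive by construction) and affine compositions with
recorded ground truth, in the exact convention the estimators invert.
Structures occupy about two thirds of the frame and a 6%-of-peak floor is
subtracted so phantoms have compact support: the scale factors (0.8–1.25)
and shifts (up to 15 px) exercised by the recovery suites keep all mass in
the field of view, and intensity moments remain unbiased.

The `brainlike` family is one canonical "anatomy" (outer ellipse, two
ventricle-like dark bands, two bright nuclei) with small subject-to-subject
jitter — the regime of a homogeneous anatomical-model family.  The jitter
amplitude is set so that rotation difference images are nearest-neighbour
separable by angle across subjects; that separability is the precondition
under which classifier recovery tests are meaningful.

What passing these tests shows: the estimators invert exactly the
transform families they model, at realistic noise-free contrast, and the
classifier generalizes across subjects *within a homogeneous family*.
What they do not show: robustness to acquisition noise, bias fields,
occlusion, multi-modal contrast, or anatomy families more heterogeneous
than the jitter model — none of which the generator simulates.

# Problem sizes used by the tests

The test-suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which every property is meaningfully exercised: 64 px
phantom bases with 28 px classifier inputs and a 36-class grid; 20-case
recovery and ablation suites at 64–128 px; 48–64 voxel cubes for the
triplanar stage.  Rotation-classifier training uses batch size 10 and
runs a few hundred epochs with early stopping once training accuracy has
held at 1 for ten epochs.

# Known limitations

* The demons forces are computed in pixel units; anisotropic spacing is
  stored but not folded into the forces.
* The rotation classifier quantizes to its class grid (10 degrees at
  $c = 36$); residual sub-grid rotation is left to the demons layer.
* The 3D affine stage estimates integer translation only; 3D rotation and
  scale are out of scope.
* Kendall-metric registration is substantially slower than the other
  metrics (O(n^2) per evaluation) and, consistent with the convergence
  experiments, the least effective of the offered metrics.
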