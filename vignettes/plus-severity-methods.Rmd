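---
title: "Quantifying Plus-disease severity from fundus images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Plus-disease severity from fundus images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plusquant)
```

## The problem

Plus disease — abnormal dilation and tortuosity of the posterior retinal
vessels — is the key treatment-decision marker in retinopathy of prematurity
(ROP). Its diagnosis is notoriously subjective: experienced graders apply
different internal cut-points when they sort the same continuum of vascular
abnormality into categories, so categorical labels disagree while the
underlying ranking largely agrees. `plusquant` implements a quantitative
pipeline that (i) segments the vessels, (ii) measures dilation, tortuosity,
curvature and density, and (iii) regresses a *continuous* severity index on a
1–5 scale (1 = Normal, 2 = pre-Plus, 3–5 = increasingly severe Plus) against
the mean of a multi-expert grade panel. A grading-statistics layer (majority
reference diagnosis, linearly weighted kappa, per-expert error against the
panel mean) quantifies the inter-expert variability that motivates the
continuous index in the first place.

Because no clinical images ship with the package, every component is
validated against a seeded synthetic phantom generator with analytically
known ground truth; the same generator doubles as the package's demo data
source.

## Vessel segmentation

Preprocessing converts an RGB fundus photograph to the green channel (the
highest vessel contrast in fundus imaging), applies contrast-limited
adaptive histogram equalisation (CLAHE; normalised clip limit 0.01, 8×8
tiles), and divides by a large-scale background estimate to remove
vignetting. The background estimator is a block-mean pyramid: area-average
downsampling to blocks of `background_scale`·min(H,W)/4 px (default scale
0.25), a 3×3 binomial smooth, and centre-anchored bilinear upsampling with
linear extrapolation at the margins. On an analytically vignetted constant
image the corrected output is flat to well under 2% relative deviation, and
re-applying the correction moves pixels by less than 1% RMS.

The segmenter is an encoder/decoder convolutional network (U-Net family)
with configurable depth (default 3 resolution levels, 16 base channels,
nearest-neighbour upsampling and skip concatenation), trained with the
*Tversky loss* `1 - TI`,

$$TI = \frac{\sum p\,t}{\sum p\,t + \alpha \sum (1-p)\,t + \beta \sum p\,(1-t)},$$

with α = 0.7, β = 0.3 by default: weighting false negatives above false
positives protects the thin-vessel recall that pixel-wise cross-entropy
sacrifices under class imbalance. At α = β = 0.5 the index reduces exactly
to the Dice coefficient, which the test suite exploits as an oracle.
Training patches of 128×128 px are centred on skeleton bifurcation points
(junction pixels with ≥ 3 neighbours in 8-connectivity) — these
vessel-crossing neighbourhoods are the most informative patches — and split
80/20 into training and validation. The network is implemented in
single-precision RcppArmadillo with im2col GEMM convolutions; its analytic
gradients are verified against central finite differences in the test suite.
Inference tiles the image with overlap averaging, thresholds at 0.5, and
removes connected components below 200 px (area opening). A literal
morphological opening with a 200-px element would erase every vessel, so the
area-opening reading of that cleanup is the default; a `literal_disk` switch
provides the classical opening for comparison. Segmentation quality is
scored with the boundary-F1 (BF) score: precision/recall of boundary pixels
matched within 0.75% of the image diagonal.

Trained on ~200 phantom patches for 10 epochs (a few minutes on one CPU),
the segmenter reaches Dice ≈ 0.95 on a held-out phantom; the acceptance
suite requires ≥ 0.8.

## Vessel morphometry

The cleaned mask is thinned with Zhang–Suen thinning plus a serial cleanup
pass that deletes residual pixels whose foreground neighbours form a single
8-connected component. The cleanup matters: parallel thinning leaves 2-px
staircase residue whose pixels masquerade as junctions, and without it a
single unbranched vessel fragments into dozens of false segments. The
skeleton decomposes into simple paths between endpoints and junctions
(junction pixels belong to no segment; traversal is row-major
deterministic); paths shorter than 10 px are discarded as thinning spurs.

Per segment the pipeline computes:

* **Centerline.** The integer pixel chain is refined to subpixel accuracy by
  moving each point along its local normal to the parabolic maximum of the
  interpolated Euclidean distance transform (the tube's medial ridge),
  capped at 0.6 px.
* **Curvature.** Signed point-based curvature
  `kappa = (x'y'' - y'x'') / (x'^2 + y'^2)^{3/2}` along the arc-length
  parametrisation. The default estimator fits penalized smoothing splines to
  x(s) and y(s) with ~one effective degree of freedom per 10 px of arc and
  differentiates analytically, trimming 8 px at each end where the spline is
  unsupported. A plain central-finite-difference estimator
  ([curvature_profile()]) is exact to better than 2% on analytic curves and
  serves as the reference on clean inputs.
* **SDC tortuosity.** The squared-derivative-curvature tortuosity
  `tau = (1/L) * sum(((k[i+1]-k[i])/ds)^2 * ds)` (units px⁻⁴): zero for
  straight segments and circular arcs, rotation/translation/reversal
  invariant, scaling as s⁻⁴ under spatial rescaling. Unlike the arc-to-chord
  ratio it responds to the *frequency* of direction change, not only its
  total amount.
* **Diameter.** Twice the distance-transform value at each centerline point
  minus a 0.25 px subpixel boundary correction (the transform measures
  centre-to-first-background-pixel-centre distance).

A fourth-order statistic such as SDC tortuosity is extraordinarily sensitive
to centerline noise: on an integer skeleton with fixed-σ Gaussian smoothing
the noise floor sits two to three orders of magnitude above typical vessel
values. The refinement + spline estimator brings the floor down to
~2·10⁻⁶ px⁻⁴ at the package's default phantom scale; recovered τ agrees with
high-resolution quadrature truth to within about a factor of two for sine
amplitudes ≥ 4 px and is strictly monotone in amplitude. Segments shorter
than 30 px carry no curvature statistics (`tau = NA`) — on such chains the
statistic measures only discretisation noise — and the per-region mean
tortuosity weights segments by arc length. Consequently phantom-level
tortuosity comparisons are order-of-magnitude-and-monotonicity checks, while
exactness is asserted on analytic curves; claims about real images inherit
the same caveat.

## Features and regions

Ten morphometric features form a 5-measure × 2-region grid: {max diameter,
mean diameter, mean SDC tortuosity, top-1% |curvature| mean, vessel density}
× {3DD annulus, whole vascularized region}. The 3DD region extends three
disc diameters outward from the optic-disc border (`r_d < d ≤ r_d + 3D`,
strict inner inequality); a centre-anchored disk alternative is available.
The regression quartet is aliased on top of the grid: **F1** max diameter in
3DD, **F2** mean segment tortuosity in 3DD, **F3** vessel density of the
whole vascularized region, **F4** top-1% point-based |curvature| over the
whole image. Vessel density is `N_vessel / (N_region - N_vessel)`.

The *vascularized region* is the retinal area the vessels have reached
(bounded clinically by the vascular/avascular ridge). The default
implementation is the filled convex hull of the vessel mask: a radial vessel
tree's territory is star-shaped about the disc, and a convex hull tracks it
at any tree sparsity. The often-suggested alternative — morphological
closing at ~5% of the image size — was measured to under-cover sparse trees
badly (the inter-vessel gaps grow linearly with radius and quickly exceed
any tractable structuring element, leaving "density" ≈ vessels/dilated
vessels), so closing is retained only as an explicit `method = "closing"`
option for dense masks.

Per-point statistics (diameter, curvature pool) use per-point region
membership; a segment's tortuosity is assigned to the region containing its
midpoint.

## Grading statistics

Grades are integers 1–5 from ≥ 1 experts per image. The reference standard
diagnosis (RSD) is the strict-majority grade; ties are flagged and resolved
by a deterministic rule (default round-half-up of the mean) — a human
panel's adjudication session cannot be reproduced in software, so the flag
keeps tie-broken rows auditable. The continuous regression target is the
per-image mean grade. The 5-level scale collapses to the conventional
3-level scale by 1→1, 2→2, {3,4,5}→3. Agreement uses linearly weighted
Cohen's kappa (weights `|i-j|/(L-1)`, population marginals); per-expert MSE
and MAE are taken against the panel mean. Missing grades are allowed and
dropped pairwise.

## Severity model

Feature selection uses neighborhood component analysis (NCA) for regression:
non-negative per-feature weights minimise the leave-one-out soft-neighbour
objective

$$f(w)=\sum_i \sum_{j\neq i} p_{ij}\,|y_i-y_j| + \lambda\sum_r w_r^2,\qquad
p_{ij}=\frac{e^{-d_w(x_i,x_j)}}{\sum_{k\neq i} e^{-d_w(x_i,x_k)}},\qquad
d_w(x_i,x_j)=\sum_r w_r^2\,|x_{ir}-x_{jr}|,$$

by gradient descent from w = 1 with step-halving line search (λ = 1/n, up to
500 iterations; the objective trace is non-increasing by construction).
Features are standardized before both NCA and the regression. The k = 4
highest-weight features feed an ordinary least-squares model whose raw
prediction is the continuous severity index; a copy clamped to [1, 5] is
reported alongside. Evaluation is seeded k-fold (default 5) cross-validation
reporting MSE and MAE against the panel-mean target. A Welch two-sample
t-test utility compares every feature between every pair of severity levels
with conventional significance stars and no multiple-testing correction
(noted in its output attributes). Cohorts below n = 10 skip NCA and fall
back to the canonical F1–F4 quartet.

## The synthetic phantom

The generator renders sine-perturbed vessels radiating from the optic-disc
border: vessel i leaves at an angle 2πi/n + jitter and follows
`center + (r_d + s)·u + A sin(2πs/λ + φ)·n` with an exponentially decaying
width profile; side branches spawn with probability `branch_prob`. Rendering
is distance-based and anti-aliased (coverage `clamp(0.5 + hw - d, 0, 1)`,
truth mask at coverage ≥ 0.5). The image has a bright disc, radial
vignetting, Gaussian noise, and vessels darkest in the green channel, as in
real fundus photographs. The truth bundle records the generating curves with
curvature and tortuosity computed by dense quadrature at generation time,
the exact rendered mask, the vascularized stencil and pixel-counted density,
and the latent severity θ.

Severity maps to morphology affinely, anchored at θ = 1: per unit of θ the
sine amplitude grows by 1.5 px, vessel width by 0.8 px, the main-vessel
count by 0.75 and the branching probability by 0.15 — severity manifests
jointly in tortuosity, dilation and density because the regression features
span all three. Defaults (640×640 px, disc diameter 64 px, 6 main vessels,
amplitude 1.5 px, wavelength 80 px, width 4 px, contrast 0.55, vignette
0.35, noise sd 0.02) depict a mildly abnormal posterior fundus at desk
scale with the disc-to-image proportion of wide-field imaging. The
simulated expert panel grades `theta + N(0, 0.3)` through four personal
cut-points jittered (sd 0.25) around 1.5/2.5/3.5/4.5 — the different-
cut-points mechanism believed to drive real inter-expert disagreement; these
defaults give moderate pairwise kappas and panel-mean/θ correlation ≥ 0.9.

What the phantom does *not* emulate: RetCam optics, ridge lines and other
pathology, artery/vein differences, image-quality failures, or the texture
of the choroid. Passing phantom tests therefore demonstrates correctness of
the measurement chain, not clinical performance.

## Numerical and design notes

* All randomness flows from one integer seed through `derive_seed(seed, tag)`
  (per-purpose offsets below 2³¹); reruns are byte-identical for fixed seed
  and thread configuration.
* Network logits are clamped to ±30 before the sigmoid so saturated
  probabilities bottom out at ~10⁻¹³ instead of denormals, and the C++ entry
  points enable flush-to-zero — denormal-laden GEMMs are orders of magnitude
  slow on common CPUs.
* Problem sizes used by the tests and the acceptance script — 200 training
  patches / 10 epochs for the segmenter, a 50-image rendered cohort and an
  n = 200 feature-level cohort for the severity model, 20 NCA selection
  runs — were chosen as the smallest sizes at which the checked properties
  are stable.
* `tversky_index` returns 1 when prediction and target are both empty;
  `weighted_kappa_linear` returns 1 for two constant, equal raters (zero
  expected disagreement); `bf_score` returns 1 for two empty masks and 0
  when exactly one boundary is empty.
* Ties in feature selection break by feature order; RSD ties are flagged;
  path tracing and patch sampling are row-major deterministic.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
cohort_dir <- file.path(tempdir(), "demo_cohort")
generate_cohort(20, seed = 7, dir = cohort_dir)
res <- run_end_to_end(cohort_dir, file.path(tempdir(), "demo_out"),
                      pipeline_config(seed = 7, model = list(folds = 4)))
res$model$coefficients
res$cv$mse_mean
head(res$predictions)
```

## Known limitations

* SDC tortuosity from binary masks is accurate only in order of magnitude
  below sine amplitudes of ~4 px at the default scale (see above); diameters
  carry a ±0.5 px phase uncertainty on lattice-aligned structures.
* The segmenter is a small CPU-trainable network; it is a faithful
  implementation of the patch/Tversky training recipe, not a
  state-of-the-art vessel segmenter.
* The grading layer models only cut-point heterogeneity and Gaussian
  perception noise; real expert disagreement has structure (image quality,
  fatigue, anchoring) that the simulation does not capture.
* Everything is in pixel units; no metric calibration is attempted.
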