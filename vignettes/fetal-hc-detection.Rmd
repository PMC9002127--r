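---
title: "Measuring fetal head circumference by rotated-ellipse detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring fetal head circumference by rotated-ellipse detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalhc)
```

## The measurement problem

Fetal head circumference (HC) is a standard biometric read from the
trans-thalamic plane of a 2-D ultrasound exam: the skull outline is close to
an ellipse, and HC is the perimeter of that ellipse in millimetres.
Segmentation pipelines get there indirectly — predict a skull region, clean
it up morphologically, extract an edge, fit an ellipse. `fetalhc` instead
treats the task as one-stage *rotated-ellipse detection*: a network looks at
the image once and directly emits the five ellipse parameters
$(c_x, c_y, a, b, \theta)$ plus a confidence, and HC follows in closed form.
There is no post-processing stage anywhere in the path.

Conventions used throughout: image coordinates are 0-based pixel centers
with x right and y down; $a \ge b$ are **semi**-axes in pixels; $\theta \in
[0, 180)$ degrees is the angle between the short axis and the vertical image
direction, which in this frame equals the major-axis-from-horizontal angle
$\psi$ (one function, `theta_to_psi()`, owns that identity). Angles are
stored in degrees and converted to radians only inside trigonometric code.

## Anchor-free encoding of an oriented ellipse

A detection grid at stride $s = 4$ carries four head maps:

* **Center heatmap.** The ground-truth center is splatted as an anisotropic
  Gaussian whose standard deviations adapt to the smallest axis-aligned box
  enclosing the ellipse: $\sigma_a = w/(6s)$, $\sigma_b = h/(6s)$, so the
  $\pm 3\sigma$ support matches the box. The grid cell containing the center
  is clamped to exactly 1, which gives the focal loss a nonempty
  "positive" branch. The heatmap is trained with a penalty-reduced focal
  loss ($\alpha = 2$, $\beta = 4$): pixels near, but not at, a center are
  progressively forgiven.
* **Center offset.** The fractional remainder $(c_x/s - \lfloor c_x/s
  \rfloor, \cdot)$ makes center reconstruction from the integer cell exact;
  the decode inverts it exactly, which the tests assert to $10^{-9}$ px.
* **Semi-axes.** Regressed in input-image pixels (not grid units), so the
  HC formula never needs stride bookkeeping. The head passes through a
  softplus, keeping predictions strictly positive.
* **Angle.** Soft stagewise regression, below.

Offsets, axes and the decoded angle are supervised with smooth L1 at the
ground-truth center cell, averaged over objects. Negative images contribute
only to the heatmap term (with the object count floored at one).

## Soft stagewise regression of the angle

Direct regression of $\theta$ is awkward: a small angular error can change
the rotated overlap a lot, and the target lives on a 180-degree circle. SSR
turns the regression into three nested soft classifications with bin counts
$(S_1, S_2, S_3) = (18, 10, 10)$ over $V = 180$ degrees — widths 10, 1 and
0.1 degrees. Each stage contributes its probability-weighted bin index; a
per-image scale $\Delta_k$ and per-bin shifts $\eta_i^{(k)}$ (both squashed
into $(-1, 1)$ by tanh so bins cannot invert order) let the bins translate
and stretch:

$$\theta = \sum_k \sum_i p_i^{(k)} \,(i + \eta_i^{(k)})\,
\frac{V}{\prod_{j \le k} s_j (1 + \Delta_j)}.$$

The decode is linear in each probability vector, hence differentiable, and
the only angle supervision is smooth L1 on the decoded value — gradients
flow through the decode into the probabilities, shifts and scales. One
design departure is deliberate: the loss uses the minimal *circular*
difference $\min(|\Delta\theta|, 180 - |\Delta\theta|)$, so 179.9° vs 0.1°
costs 0.2°, not 179.8°. The literal linear difference remains available
(`circular_angle = FALSE`) for comparison.

## The KLD coupling loss

Rotated-ellipse IOU has no convenient closed form and is an awkward training
signal. Instead each ellipse is embedded as a 2-D Gaussian via
$\Sigma^{1/2} = R(\psi)\,\mathrm{diag}(a, b)\,R(\psi)^\top$ (so the
one-sigma contour *is* the ellipse and $\det \Sigma^{1/2} = ab$), and the
prediction is penalized by

$$L_{reg} = 1 - \frac{1}{1 + \ln(D_{kl} + 1)}, \qquad
D_{kl} = \mathrm{KL}\!\left(N_p \,\|\, N_t\right),$$

with the natural logarithm. The divergence mixes center, axis and angle
errors in one scalar, so optimizing any one parameter is reweighted by the
others — the practical reason this term helps rotated detection. The total
objective is the unweighted sum of the heatmap, offset, axes, angle and KLD
terms; per-term weights and the `include_axes_in_total` reading are exposed
because the axes term can also be folded into the offset term without
changing what is trained. Ablation flags (`use_ssr`, `use_kld`) reproduce
the three objective variants (smooth-L1 only, +SSR, +SSR+KLD) and the
per-epoch log shows exactly which terms are active.

The KLD gradient with respect to the five decoded parameters is evaluated by
central finite differences (ten cheap 2×2 evaluations per object) and then
chained analytically through the offset, softplus and SSR decode; every
other gradient in the package is fully analytic and verified against
numerical differentiation in the test suite.

## The network

A compact U-shaped encoder–decoder produces the stride-4 maps: a stem plus
four or five stride-2 residual stages, then decoder blocks that bilinearly
upsample, refine with a 3×3 convolution, concatenate the skip feature and
fuse with a 1×1 convolution. Optional multi-head self-attention blocks (with
relative 2-D positional logits) sit after the bottleneck and after every
decoder block; they are shape-preserving, so the flag changes capacity, not
contracts. A `use_deformable` flag exists for configuration parity but
currently falls back to standard convolution with a warning — no deformable
operator ships with the package, and no correctness property depends on it.
Everything (convolution and bilinear resampling kernels in C++, batch norm,
attention, heads, losses) is implemented in the package with hand-derived
backward passes; the test suite checks analytic gradients against numerical
differentiation end to end, in both attention modes.

Two presets are provided. `tiny` (96×96 input, base width 16, depth 4,
~0.27 M parameters) is the desk-scale configuration every test and example
uses; it trains on one CPU in minutes. `paper` mirrors the full-scale
configuration (512×512, base width 64, depth 5, attention on) and is
provided for completeness — it is not exercised at desk scale. Optimisation
is momentum-SGD with the reference settings (learning rate 0.005, momentum
0.9, dropout 0.1, batch size 4 on CPU), plus global-norm gradient clipping
at 5 for stability of the early focal term. The heatmap head bias starts at
a low-confidence prior and the axes head bias at a plausible skull scale
(softplus ≈ 16 px) so the first epochs are not spent escaping a degenerate
initialisation.

## The synthetic phantom generator

Real HC18-style data cannot ship with the package, so the generator is a
first-class module that emulates what matters for this detector: a bright
anti-aliased elliptical skull ring (semi-major axis 14–32 px at 96×96,
aspect ratio 0.6–1, uniform orientation), partial boundary dropout as two
contiguous arcs of the *perimeter* placed half a perimeter apart (acoustic
shadowing at the skull poles), unit-mean multiplicative gamma speckle
(sd 0.3, the standard B-mode approximation), a smooth low-frequency
background field, and a physical pixel size drawn from 0.052–0.6 mm. The
defaults above are the package's fixed study conditions: hard enough that
detection is nontrivial (gap fraction 0.2 erases a fifth of the ring), small
enough that the full pipeline runs on one CPU.

Negative images follow the two constructions used for class balance:
ring removal with surrounding-statistics fill, and random crops accepted
only when their axis-aligned IOU with the ground-truth box is below 0.3.
The augmentation module applies the discrete grids (rotation ±30° step 10°,
scale 0.85–1.15 step 0.05, gamma 0.5–1.5 step 0.1, horizontal flip) with
consistent annotation updates; the rotation handedness is pinned by a
mask-overlay test rather than by assertion, and HC in mm is invariant under
the scale augmentation because the pixel size co-scales.

What passing tests on phantoms do **not** show: robustness to real
ultrasound artefacts (attenuation, point-spread blur, neighbouring
structures that mimic skull arcs), to the HC18 annotation style (expert
ellipses drawn on sometimes-incomplete skulls), or to the domain gap between
phantom speckle and true speckle. The phantom results are a correctness and
plumbing guarantee, not a clinical claim.

## Evaluation

`mae_me()` reports mean absolute and mean signed HC error (prediction minus
ground truth, sample sd by default), `average_precision()` computes
rotated-ellipse AP by greedy score-descending matching against a rasterized
membership-test IOU (threshold 0.5, all-point PR interpolation — both
recorded in the report since neither choice is canonical), and
`bland_altman()` gives the bias and 1.96 sd limits of agreement with the
per-case scatter data. The greedy AP is checked against an
exhaustive-assignment oracle on small instances.

## Numerical choices and degenerate inputs

* Heatmap predictions are clipped to $(\varepsilon, 1 - \varepsilon)$,
  $\varepsilon = 10^{-7}$, before logs.
* A degenerate ellipse ($b = 0$) is rejected by the Gaussian embedding
  (singular covariance); the Ramanujan HC formula still evaluates and is
  within 0.5 % of the true perimeter for $b/a \ge 0.2$.
* The rasterized IOU uses 4 cells per pixel by default; doubling the
  resolution moves values by less than 0.005.
* Decode sorts the two axis channels so $a \ge b$ always holds; training
  supervises the channels unsorted against the sorted ground truth.
* Ties in peak extraction (equal neighbours) favour the earlier cell in
  column-major order; at most one peak per image is returned by default
  since a standard plane contains one head.
* The score threshold 0.3 is a configuration default aligned with the
  negative-crop IOU scale, not a claimed reference value.

## Problem sizes used by the checks

The acceptance-style checks train the tiny preset on 300 phantoms for 6
epochs (batch 4), twice — once with and once without the KLD term — and
evaluate on 50 held-out phantoms; the codec identity runs over 1,000 random
annotations and the SSR round-trip over 10,000 angles. These sizes are the
package's chosen desk-scale study conditions and are stated here so results
are interpretable, and reproducible with `scripts/acceptance.R`.

## Known limitations

* The `paper` preset is untested at scale; no pretrained weights exist.
* Deformable convolution is a fallback, not an implementation.
* The phantom generator is not a physical ultrasound simulator.
* Full-scale benchmark numbers on HC18 require the external dataset and
  GPU-scale training, both outside this package's scope; the optional
  `load_hc18_annotations()` adapter exists for users who have the data.
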