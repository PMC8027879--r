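---
title: "Methods: gland segmentation and morphometry on synthetic meibography phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gland segmentation and morphometry on synthetic meibography phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Infrared meibography images the meibomian glands of the everted eyelid as
bright, roughly vertical strips on a darker tarsal background. Clinical
assessment of meibomian gland dysfunction relies on gland morphology —
how many glands there are, how long and wide they run, and how tortuous
(curved) they are. Manual annotation is slow and observer-dependent, and
classical intensity-thresholding pipelines are fragile against the
artifacts that plague meibography: defocus, specular reflections,
non-uniform illumination, low contrast.

`meibomorph` implements the full analysis chain: a trainable
encoder–decoder segmentation network, a skeleton-based morphometry engine,
and the agreement statistics used to validate such pipelines. Because
clinical meibography datasets are generally private, the package also
ships a synthetic phantom generator whose ground truth is known *exactly*
— both the pixel mask and the analytic morphometry — so every stage can be
validated end to end without patient data.

## The phantom generator

`phantom_config()` + `simulate_phantom()` draw `gland_count` gland strips
with sinusoidal centerlines

$$x(y) = a + A \sin\!\left(\frac{2\pi (y - y_0)}{\lambda} + \phi\right),$$

rendered `2\,\mathrm{hw}+1` pixels wide (each row covers the columns
within `hw` of the pixel nearest the centerline; centering on the nearest
pixel keeps the rendered width identical to the analytic width).
Generation-time packing guarantees a minimum background gap between
neighbouring strips at every row, so the mask always has exactly
`gland_count` connected components — the counting stage's core assumption.

The analytic morphometry (`expected_morphometry()`) never touches the
rendered mask: length is the centerline arc length by adaptive quadrature,
width is $2\,\mathrm{hw}+1$, tortuosity is arc length over the Euclidean
distance between the centerline endpoints.

Artifacts are applied to the image (never the mask) in a fixed order:
horizontal illumination ramp, intensity assignment (glands bright,
background dark, the IR convention), Gaussian defocus blur, saturated
specular discs, additive Gaussian noise, and clipping to 0–255.

Default conditions, chosen once for a 256×256 canvas (the paper-scale
working resolution; there is no physical pixel calibration in
meibography): 12 glands per eyelid, half-widths 2–3 px, amplitudes 1–3 px,
wavelengths 90–140 px, lengths 160–220 px (upper lid) or 100–140 px
(lower lid, clinically shorter), blur σ = 1, two specular spots,
25% illumination ramp, noise σ = 8. The gland geometry ranges were fixed
by a discretization-bias analysis (below), not tuned to test outcomes.

What the phantoms do **not** emulate: gland dropout/atrophy, duct
texture, eyelash occlusion, eyelid boundary curvature, device vignetting.
Passing tests on phantoms therefore demonstrate the correctness of the
measurement and training machinery, not clinical-grade segmentation of
real meibography.

## Segmentation network and objective

`build_unet()` constructs a plain U-Net: `depth` encoder levels of two
3×3 convolutions + ReLU followed by 2×2 max-pooling, a bottleneck,
symmetric decoder levels with nearest-neighbour upsampling and skip
concatenation, and a 1×1 sigmoid head giving a per-pixel gland
probability. There is no deep-learning framework dependency: convolutions
are evaluated as im2col patch matrices times weight matrices (BLAS), and
backpropagation mirrors the forward pass exactly; gradients were verified
against central differences. This keeps training fully deterministic for a
fixed seed — which is what makes the "0% variability / 100% repeatability"
test–retest property a provable contract rather than an empirical claim.

The objective is the sum of two terms, averaged over pixels:

* weighted binary cross-entropy
  $\mathrm{CE} = -\frac{1}{N}\sum_x w(x)\,[g(x)\log p(x) + (1-g(x))\log(1-p(x))]$,
  with $w \equiv 1$ by default. (The published form of this loss omits the
  minus sign and the background term; that literal reading is unbounded
  below and untrainable, so the standard negative log-likelihood is used.)
* squared-denominator soft Dice
  $\mathrm{Dice} = 1 - \frac{2\sum_x p\,g + s}{\sum_x g^2 + \sum_x p^2 + s}$
  with smoothing $s = 1$, which defines the empty-vs-empty case as loss 0.

Total loss = CE + Dice with no extra weighting. Optimization is Adam
(β₁ = 0.9, β₂ = 0.999). Pixel averaging (rather than summing) is a
monotone rescale that makes loss magnitudes resolution-independent without
moving optima.

Tunable parameters and defaults: learning rate 10⁻³ (3·10⁻³ works well
for the small phantom task), batch size 5, 30 epochs, 256×256 input,
binarization threshold 0.5 (the published pipeline does not state one; it
is exposed as config), depth 4, base channels 8. Images are resized
bilinearly to the network size and probability maps resized back, so
morphometry always runs at native resolution; masks use nearest-neighbour
resizing to stay binary. A two-stage transfer protocol is supported as a
`pretrain` config hook (auxiliary image/mask set trained first, optimizer
state carried over); pretrained backbones are accepted only with local
weight files and are never downloaded.

## Morphometry

From a binary mask (`analyze_mask()`):

* **Gland number** — 8-connected components (diagonally touching pixels
  belong to one gland), components under `min_area = 10` px discarded as
  speckle, glands numbered left-to-right by centroid column.
* **Width** — at each row of a gland, the inclusive pixel span
  $X_1 - X_0 + 1$ between the leftmost and rightmost gland pixel, averaged
  over the gland's rows. The inclusive count is used so a one-pixel-wide
  gland has width 1, not 0; rows with interior gaps still use the extreme
  extents.
* **Skeleton** — Zhang–Suen two-subiteration thinning to a one-pixel-wide
  skeleton. If the skeleton branches, the gland axis is the longest
  geodesic between skeleton endpoints on the 8-connected pixel graph
  (axial edges weight 1, diagonal √2), found exactly via shortest-path
  search between all endpoint pairs.
* **Length** — the skeleton path length (sum of 1/√2 steps); the vertical
  extent $Y_{max}-Y_{min}$ is available via `length_mode = "extent"`.
* **Tortuosity** — path length / chord length (Euclidean distance between
  the path's first and last pixel); 1 for straight glands; a chord under
  1 px returns 1 (degenerate guard).

### Discretization behaviour, and why the defaults are what they are

Two systematic biases affect skeleton-based length on a pixel grid:
thinning retracts each end of a strip by roughly its half-width
(a 9-px-wide bar spanning 50 rows thins to a 41-pixel central line), and
the 1/√2 chain metric *over*-estimates the length of smooth oblique
curves by up to ~8% at the worst slope. These act in opposite directions.
At the generator defaults (half-width ≤ 3 px, centerline slope ≤ 0.21,
lengths ≥ 100 px) each bias stays below ~4% and their sum below ~3%,
which is why gland length and tortuosity recover the analytic values
within the 5% test tolerance while gland count and width recover exactly.
A consequence worth knowing: no topological thinning can measure the full
end-to-end extent of a blunt-ended bar, so the measured length of a
straight bar is its row span minus roughly twice the half-width.

## Evaluation statistics

Gland pixels are the positive class. Precision $TP/(TP+FP)$, recall
$TP/(TP+FN)$, F1 $2PR/(P+R)$; any vanishing denominator yields `NA`
(never a silent 0, which would corrupt per-image averages — metrics are
computed per image and then averaged). The Dice coefficient
$2|A\cap B|/(|A|+|B|)$ equals F1 on binary masks and is tested as an
identity. ROC AUC is the rank (Mann–Whitney) statistic with midrank ties,
identical to threshold-sweep trapezoidal integration.

Bland–Altman: differences $d_i$ (manual − automatic), limits of agreement
$\bar d \pm 1.96\,s_d$, 95% CIs from t quantiles with
$SE_{\bar d}=s_d/\sqrt n$ and $SE_{LoA}=s_d\sqrt{3/n}$ (the standard CI
formulas; the source material does not state its own), the fraction of
points inside the limits, and a two-sided paired t-test.

Test–retest: per-image DSC and Cohen's kappa (mean ± sd) on paired masks,
plus the ICC of paired gland counts. ICC defaults to ICC(2,1) — two-way
random effects, absolute agreement, single measurement — because the
clinical repeatability context compares absolute values from two runs;
ICC(3,1) is available where a constant offset should not be penalized.
Identical runs report ICC 1 even when counts are constant (the
zero-variance limit of perfect agreement).

## Problem sizes and numerical choices

* Training-dependent tests and `scripts/acceptance.R` run on 64×64
  phantoms (4 glands, lengths 40–54 px) with a depth-2, 8-channel U-Net,
  30 training and 10 held-out phantoms, ≤ 15 epochs — a deliberately
  small, CPU-friendly instance of the same pipeline. Held-out Dice
  reaches ≈ 0.98.
* Morphometric parameter recovery runs on the full 256×256 generator
  with artifacts disabled, 50 phantoms, alternating eyelid sides.
* Cross-entropy predictions are clipped to $[10^{-7}, 1-10^{-7}]$.
* Max-pooling breaks ties deterministically (first position in the 2×2
  block wins); upsampling is nearest-neighbour; weight init is He-normal,
  seeded.
* Every stochastic step (spec sampling, artifact rendering, weight init,
  shuffling, splits) is driven by an explicit integer seed and restores
  the caller's RNG state.

## Known limitations

* The default plain U-Net is intentionally small; it is not a
  state-of-the-art backbone and no claim is made about clinical images.
* Phantom realism is limited (see above); in particular gland atrophy
  (meiboscore-style dropout grading) is out of scope.
* Skeleton-based length carries the discretization biases described
  above; absolute lengths from different implementations of thinning are
  not directly comparable.
* Bland–Altman helpers assume paired, per-image scalar summaries.
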