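---
title: "S-Net methods: dual-branch encoding, cross-aggregation and Tversky supervision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{S-Net methods: dual-branch encoding, cross-aggregation and Tversky supervision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(snet3d)
```

## The problem

Thin anatomical structures — the atrial wall of the heart, small brain
arteries around one voxel in diameter — sit at the resolution floor of
clinical 3D images. Conventional U-shaped segmentation networks halve the
feature grid at every encoder layer, so a $3^3$ convolution at layer $i$
covers $2^i \times 3^3$ input voxels. By the bottleneck the network reasons
about neighbourhoods dozens of voxels wide, and a one-voxel vessel wall is
averaged away before the decoder can recover it.

S-Net counters this with a second encoder branch that never downsamples.
The two branches see complementary worlds:

* the **downsampling branch** (stride-2 $2^3$ convolutions between layers)
  behaves like a standard residual U-Net encoder: cumulative stride $2^i$,
  receptive field growing geometrically, features increasingly semantic;
* the **resampling branch** ($3^3$, stride-1, padding-1 transitions) keeps
  its grid fixed, so its receptive field grows only by kernel extents —
  arithmetically, not geometrically — and one-voxel detail survives to the
  deepest layer.

At every layer a **multiple cross-aggregation module (MCAM)** exchanges
information residually:

$$F^R_{i+1} = F^R_i + \mathrm{Interp}\!\left(F^D_i + \mathrm{PReLU}(\mathrm{Conv}(F^D_i))\right),
\qquad
F^D_{i+1} = F^D_i + \mathrm{Interp}\!\left(F^R_i + \mathrm{PReLU}(\mathrm{Conv}(F^R_i))\right),$$

where $\mathrm{Conv}$ is a stack of three $3^3$ convolutions each followed
by a PReLU, and $\mathrm{Interp}$ is trilinear resampling to the other
branch's grid. Both updates read the pre-update features. The decoder
upsamples with $2^3$ stride-2 transposed convolutions, concatenates the
same-resolution downsampling-branch features (long skips), applies $3^3$
convolution blocks with additive short skips, and — the third ingredient —
every decoding stage carries its own prediction head ($1\times1\times1$
convolution, trilinear upsampling to input size, sigmoid), so coarse
semantic stages and the full-resolution stage are supervised jointly.

## Loss

Training minimizes, over the four heads,

$$L = \sum_{i=1}^{4} \left(1 - \frac{TP_i + s}{TP_i + \alpha\,FP_i + \beta\,FN_i + s}\right)$$

with soft (probabilistic) confusion counts, $\alpha = 0.3$, $\beta = 0.7$
and a stabiliser $s = 10^{-6}$. The index inside the parentheses is the
Tversky index; $\beta > \alpha$ makes a unit of false negative strictly more
expensive than a unit of false positive, trading precision for recall so
thin walls are not dropped. Two presentation choices are worth making
explicit:

* the original objective is printed as the *sum of the indices* — a
  quantity that is large for good predictions; since the optimiser is
  gradient descent, this package implements the equivalent minimisation
  form $\sum_i (1 - TI_i)$;
* the counts are accumulated from probabilities rather than thresholded
  masks, which keeps the loss differentiable; with hard masks and
  $\alpha = \beta = 1/2$ the index reduces to the Dice coefficient, which is
  the consistency the tests assert.

Empty-foreground patches are defined to score $TI = 1$ for an
all-background prediction (the $0/0$ case is resolved by $s$), so the loss
rewards silence on empty anatomy instead of being undefined.

## Receptive-field accounting

For a single convolution the receptive-field edge is
$d\,(k-1) + 1$ for kernel $k$ and dilation $d$: 3, 7, 9, 11 for $k=3$ at
dilations 1, 3, 4, 5. (The source description lists "$3^3$, $7^3$, $9^3$,
$11^3$" for dilations {2, 3, 4, 5}; the first entry is inconsistent with
the formula, which gives 5 for dilation 2 — `receptive_field()` follows the
formula and this discrepancy is deliberately left visible rather than
silently patched.) Composition accumulates
$(\mathrm{edge}_{\mathrm{stage}}-1)\times\mathrm{cumulative\ stride}$, so
the downsampling branch multiplies each stage's spread by $2^i$ while the
resampling branch, at cumulative stride 1, never does.

`rf_probe()` verifies this empirically: it back-propagates from a single
feature voxel to the input and measures the bounding box of non-zero input
gradient. The probe disables MCAM while measuring, because with
cross-aggregation active every feature intentionally sees the *other*
branch's receptive field as well — that mixing is the architecture's point,
not the branch's intrinsic footprint. The deepest two encoder layers use
the dilated convolutions (padding = dilation keeps "same" size), two pairs
per layer in sequence; a parallel multi-branch arrangement would be equally
consistent with the description, and the sequential form was chosen for
parameter economy.

## What is configurable, and the defaults

| Parameter | Default | Meaning |
|---|---|---|
| `base_width` | 16 | channels at encoder layer 1 (doubling per layer). Channel counts are not printed in the original description; 16/32/64/128 is the standard U-Net convention. |
| `convs_per_block` | 2 | $3^3$ convolutions per encoder/decoder block ("two or three"); the MCAM stack is fixed at three. |
| `dilation_schedule` | (2,2),(3,3),(4,4),(5,5) | (padding, dilation) pairs of the two deepest layers. |
| `dropout_prob` | 0.3 | Bernoulli dropout after every encoding and decoding layer, training only. |
| `resample_scale` | 1.0 | resolution of the resampling branch relative to the input; per-axis target size `max(1, round(scale*size))`. |
| `alpha`, `beta` | 0.3, 0.7 | Tversky false-positive / false-negative weights. |
| `threshold` | 0.5 | binarisation of the full-resolution head (the designated inference output; which head the original work reports is unstated). |
| `learning_rate` | 1e-4 | Adam, batch 2 — the published regimen. |

Decoder stage $k$ emits $C_{4-k}$ channels; the full-resolution stage has
no shallower encoder layer to mirror and keeps $C_1$. Long skips
concatenate the (cross-aggregated) downsampling-branch features of matching
resolution; resampling-branch information reaches the decoder through MCAM
mixing, since concatenation requires equal grids. Trilinear interpolation
uses the corner-aligned convention throughout — any consistent convention
satisfies the cross-aggregation equations, but mixing conventions would
break the identity-interpolation case that the tests pin down. Weights are
fan-in-scaled uniform draws from the seeded generator, PReLU slopes start
at 0.25, and one slope parameter follows each convolution.

## Profiles: published scale and desk scale

The published regimen — $48\times512\times512$ patches, 1,000 epochs,
batch 2, dual 32-GB accelerators — is preserved as
`snet_profile("published")` but is far outside single-CPU reach; it is
never exercised by the test suite. Everything this package demonstrates
runs under `snet_profile("desk")`:

* base width 8, resampling branch at 1/4 resolution (`resample_scale =
  0.25`) — the original description itself prescribes scaling the
  resampling-branch feature size when resources are exhausted, and CPU
  time is the binding resource here;
* $32^3$ patches, batch 2, 60 epochs, one random crop per volume per
  epoch, Adam at $10^{-3}$ (a conventional small-network rate; $10^{-4}$
  with 1,000 epochs is the published pairing, and 60 desk epochs pair
  naturally with the larger step);
* per-volume z-score intensity normalisation before patching (the source
  is silent; recorded here), random in-plane crop offsets whenever the
  patch is smaller than the volume in-plane (also unstated upstream);
* whole-volume inference tiles windows with 50% overlap along every axis
  that exceeds the patch and averages overlapping probabilities with
  uniform weights, so each output voxel is a convex combination of window
  predictions.

The study sizes used by the acceptance tests are: 20 shell phantoms of
$64^3$ voxels (wall 2) with a 75/25 case split, trained for 60 epochs at
the desk profile for each of three seeds; 8 tube phantoms of $48^3$ with
radii decaying to about one voxel, 20 epochs, three seeds, contrasting
`SNet+ML` against the `BN+SL` backbone; and a miniature
generate→train→evaluate pipeline run twice for bitwise determinism. These
sizes are the package's chosen desk-scale study design.

## The phantom generator

`make_shell_phantom()` renders an ellipsoidal band: voxels whose level-set
value $\rho(x)$ (after rotation by z-y-x Euler angles) satisfies
$|\rho(x) - 1| \le t/(2\bar r)$, with $\bar r$ the geometric mean
semi-axis. The band is analytic and orientation-safe; its measured
thickness (twice the maximal inradius from the distance transform) tracks
$t$ to within a voxel, with the caveat that for anisotropic ellipsoids the
physical wall is thicker along the long axis by the ratio of that semi-axis
to $\bar r$. `make_tube_phantom()` grows a recursive capsule tree — radius
$r_0\,\gamma^g$ at generation $g$, branching stopped below 0.5 voxel so
rasterised segments stay 26-connected — with an optional spherical sac for
the aneurysm analogue; capsules are rasterised by the exact
distance-to-segment predicate. Intensities are two-level
(foreground/background means), plus Gaussian noise (sd 0.1 at unit
contrast) and a smooth bias field built from three seeded low-frequency
cosine products (amplitude 0.2, wavelengths 1–2 × a 32-voxel scale) —
roughly a 10:1 contrast-to-noise ratio with mild inhomogeneity, a benign
but non-trivial approximation of contrast-enhanced CT.

What the phantoms deliberately do not model: CT physics (beam hardening,
streaks, motion), anatomy-correlated background texture, annotation noise
(every label is the exact geometric predicate), or multi-class labels.
Passing the desk studies therefore demonstrates that the implementation
learns, cross-aggregates and evaluates correctly on controlled thin
geometry — not that desk-scale training reaches clinical-grade accuracy on
real cardiac CT or 3DRA, which is what the published full-scale regimen
addresses.

## Numerical and degenerate-input choices

* Soft confusion counts, PReLU, sigmoid, dropout masks and the Tversky
  gradient are computed in compiled code; convolutions dispatch between a
  direct register-blocked kernel (large grids, few channels) and an
  im2col/BLAS lowering (the rest). Everything is double precision.
* Dropout masks, crop offsets and initial weights all draw from the single
  session RNG seeded by the training seed; checkpoints store the optimizer
  moments and RNG state, so a resumed run reproduces an uninterrupted one
  bit for bit, and the whole pipeline is a pure function of its master
  seed.
* Percentiles use the linear-interpolation definition; HD95 takes the
  maximum of the two directed 95th percentiles (the metric conventions are
  deferred upstream to a prior publication; pooled-percentile variants can
  differ slightly and this package fixes and documents one convention).
* Empty ground truth makes RVE and sensitivity undefined — reported as
  `NA` with a warning, never silently zero. Empty surfaces are an error
  for HD95/ASSD. A mask pair with both sides empty scores Dice 1 by the
  perfect-agreement convention.
* Training aborts with input statistics if the loss turns non-finite;
  volumes smaller than the patch are padded with background and cropped
  back after inference.

## Known limitations

* The S-shaped interleaving is depicted, not fully specified, upstream;
  the implemented order (block convolutions → MCAM → transition) is one
  consistent reading, as is the sequential placement of the four dilated
  convolutions.
* `resample_scale < 1` trades away exactly the full-resolution property
  the architecture argues for; it is the sanctioned resource-pressure
  fallback, and the receptive-field claims are stated (and probed) on the
  branch's working grid.
* Desk-scale studies use small widths and few epochs; their metric values
  characterise the implementation on phantoms, not the published
  full-scale performance on clinical data.
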