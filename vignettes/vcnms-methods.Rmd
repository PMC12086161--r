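---
title: "Vegetation-cover-aware prompt generation: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vegetation-cover-aware prompt generation: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenprompt)
```

## The problem

Zero-shot instance segmentation of plants in vertical farms chains an
open-set, text-prompted detector with a promptable segmenter. The weak
link is the prompts. Text-prompted detectors produce heavily redundant
candidate boxes on dense plant canopies: a single plant enclosed by
several nested boxes, and several adjacent plants enclosed by one large
"union" box that — because larger boxes tend to carry higher confidence —
often outranks the correct tight boxes. Confidence-plus-IoU suppression
(greedy NMS, Soft-NMS) cannot separate these cases, because nested
duplicates and correct neighbours can have similar confidences and the
union box's IoU against a tight box inside it is *low* (the union is much
larger), so it evades IoU-gated suppression entirely.

This package implements a vegetation-cover-aware alternative, VC-NMS,
plus the point-prompt augmentation that rides on its output, the
evaluation metrics used to judge both, and a synthetic scene generator
that reproduces the relevant pathologies so the whole pipeline runs and
is tested without any pretrained model.

## The model

### Vegetation evidence: ExG, Otsu, NCGI

Vegetation is detected spectrally. The Excess Green index,
`ExG = 2G − R − B` on raw 8-bit channels, is large on green-dominant
pixels, exactly 0 on any gray pixel, and invariant to adding a constant
to all channels — which is why it survives the luminance blotches and
illumination gradients typical of indoor imagery. The ExG map is
binarized once, globally, by Otsu's threshold (classical histogram form:
rescale to `[0, 255]`, 256 bins, maximize between-class variance; ties
resolve to the lowest level). A chromaticity-normalized ExG variant
(`2g − r − b`) is available behind `excess_green(variant =)` for scenes
where multiplicative lighting dominates; the raw form is the default
because it is the canonical index and is threshold-compatible with the
integer histogram. Which variant the original method used is not
derivable from its description; the default is this package's choice.

Each candidate box then gets a raw cover-green count (`NCGI_raw`, the
number of vegetation pixels inside it, half-open pixel convention,
clipped to the image) and a **Normalized Cover Green Index**:

\[
\mathrm{NCGI}(b_i) \;=\; \frac{\mathrm{NCGI_{raw}}(b_i)}
  {\max_{k \in \mathrm{overlap}(b_i)} \mathrm{NCGI_{raw}}(b_k)},
\]

where the overlap set contains `b_i` itself and every box intersecting it
with positive area. Self-inclusion keeps NCGI in `[0, 1]` and guarantees
each overlap cluster contains a box with NCGI 1; whether the original
formulation includes the box itself is ambiguous, and self-inclusion is
the reading under which NCGI behaves as a bounded index.

### Relative IoU

`RIoU(a, b) = |a ∩ b| / min(|a|, |b|)` saturates at 1 for nesting, which
is precisely the configuration plain IoU under-rates. It drives both the
stage-1 penalty gate and the stage-2 decay.

### VC-NMS, stage 1: composite scoring and overlap-count attenuation

Scores are replaced in place by the composite
`s_i ← β·NCGI_i + (1−β)·s_i` (default `β = 0.7`, the batch setting that
balances vegetation cover against detector confidence; the β-sweep
harness reproduces its insensitivity over the mid-range). Boxes are
sorted in non-ascending composite order. Then, for each box `i`, if some
*later-ordered* box `j` satisfies `RIoU(b_i, b_j) ≥ N_t` (default
`N_t = 0.7`) and `i` has **more** overlapping boxes than `j`, the score
is multiplied once by `1 − oven_i / max_oven`, where `oven_i` is `i`'s
overlap count and `max_oven` the scene maximum. A multi-plant union box
overlaps both plants' redundancy clusters, so its `oven` approaches
`max_oven` and the factor approaches 0; tight boxes sit well below the
maximum and are penalized mildly or not at all.

Two points here were genuinely underdetermined and are worth recording:

* **Once per box, not once per pair.** The attenuation is written as a
  single piecewise reassignment of `s_i`; applying it per qualifying
  pair would make the penalty depend on the redundancy count in an
  unstated way. The default applies it at most once per box; the
  per-pair variant is available as
  `vcnms_config(attenuation = "per_pair")` for sensitivity studies.
* **Strict overlap-count comparison.** The defining equation prints the
  gate as `oven_i ≥ oven_j`, but the accompanying description applies
  the penalty when the large box has *more* overlapping boxes than the
  smaller one. These differ materially: under `≥`, every member of a
  uniform redundancy cluster that attains `max_oven` — including the
  correct tight box — is multiplied by `1 − max_oven/max_oven = 0`, and
  the algorithm collapses in scenes without a dominant union box. Under
  strict `>`, only boxes with strictly more overlaps (the union boxes
  the mechanism targets) are penalized. The strict reading is the
  default; the `≥` variant is kept as
  `vcnms_config(oven_gate = "gte")`.

### VC-NMS, stage 2: RIoU-Gaussian greedy selection

Soft-NMS-style selection with RIoU in place of IoU: repeatedly move the
highest-scored box to the final set and multiply every remaining score
by `exp(−RIoU(M, b_i)² / σ)`; stop when no score reaches the retention
threshold. Nested duplicates (RIoU ≈ 1) are decayed by `e^{−1/σ}`
(≈ 0.135 at the default `σ = 0.5`) while adjacent plants (low RIoU) are
barely touched. Neither σ nor the retention threshold is stated by the
source method; the defaults (σ = 0.5, the customary Soft-NMS scale, and
retention = `box_threshold` = 0.1) are this package's documented
choices. Ties anywhere break toward larger area, then lower id, making
the output invariant to input ordering. One consequence worth knowing:
a duplicate with RIoU ≈ 1 whose composite score exceeds
`0.1/e^{−2} ≈ 0.74` survives the decay mathematically — no
implementation can remove it under these parameters — which is why
near-coincident copies of high-NCGI isolated plants are an opt-in
pathology in the synthetic generator rather than a default condition.

### Point prompts: similarity maps and the max-distance criterion

The box with the highest composite value is the reference; its crop's
ExG/Otsu foreground defines a reference mask. The embedder (an interface;
the deterministic mock embedder pools smoothed
`(ExG, R, G, B, x, y)` cell features) embeds the reference and every box
region; the reference vector is the masked mean over foreground grid
cells (mean pooling is the standard one-shot choice; mask-weighted
pooling would be a drop-in alternative). Per-region cosine similarity
maps are computed at grid resolution and bilinearly upsampled to pixel
resolution; the argmax becomes the positive base point, the argmin the
negative base point (ties: smallest row-major index). Enhanced points
maximize Euclidean distance from the already-selected points inside the
region's vegetation foreground (positives) or background (negatives) —
iterated farthest-point sampling when more than one enhancement is
requested. The default 2 positive + 2 negative points is the
configuration found optimal for promptable plant segmentation; the sweep
harness (`run_point_sweep()`) reproduces the comparison on synthetic
scenes. Degenerate inputs fall back deterministically (constant map →
box center/corner; empty foreground → center + argmax; empty background
→ fewer negatives, with a warning).

## Evaluation metrics

Detection: precision, recall, COCO-style AP (101-point interpolated
precision envelope, thresholds 0.5:0.95), averaged Recall@10/100 (the
standard meaning of those columns; the source tables do not define
them), and size-stratified AP. The small stratum uses the stated
diagonal < 32 px; the medium/large split at 96 px diagonal is this
package's documented choice, as is assigning predictions to strata by
their own diagonal (the test suite pins per-stratum AP to
subset-recomputation).

Segmentation: Dice (`2 iou/(1+iou)` identity tested to 1e−12), Expected
Calibration Error (pixels as binary classifiers, confidence
`max(p, 1−p)`, 10 equal-width bins over `[0.5, 1]`, dataset-level pixel
pooling — the binning and pooling are unstated in the source and
documented here as interpretations), the structure measure
(`α = 0.5` object/region balance, original formulation including its
degenerate-GT fallbacks), and the weighted F-measure (`β² = 1`,
original formulation: nearest-foreground error transfer, 7×7 σ=5
Gaussian local averaging with zero padding, distance-decayed background
weights). The nearest-foreground transform is computed exactly by
chunked brute force; fine at the region sizes this package targets, and
the loop-free implementation is pinned against naive per-pixel oracles
in the tests.

## The synthetic study conditions

The generator emulates what matters for the method and nothing more:

* **Scenes** (192×192 px by default): plants are rosettes of 4–8
  overlapping green ellipses (radius 9–14 px) placed on a jittered tray
  grid whose occupied holes form a connected patch — hydroponic racks
  hold plants in regularly spaced holes, and connectedness guarantees
  adjacent pairs, the substrate union-box errors need. The background is
  granular (coarse luminance blotches, to which ExG is invariant, plus
  small chroma noise), with an optional 0.75–1.25 linear illumination
  gradient and red/purple global channel gains mimicking auto-white-
  balance shifts. Plant channel statistics guarantee an ExG margin over
  the background, so Otsu separation is a construction property, not an
  empirical hope. Rendering is integer-valued and fully seeded: scenes
  are byte-identical across runs and platforms.
* **Proposals**: per plant one jittered copy of its tight box (5% edge
  jitter, truncated so IoU ≥ 0.7 with the truth is guaranteed) and one
  strictly nested sub-box (25–45% linear size); union boxes over up to
  three disjoint *adjacent* plant pairs, grown 8–18% (sloppy multi-plant
  detections clip neighbours, which is also what keeps their overlap
  counts high); scores `clip01(0.2 + 0.45·area/max_area + N(0, 0.04))`,
  so union boxes usually top the ranking — the pathology that defeats
  confidence-ranked NMS.
* **Battery**: `synthetic_battery(n, seed)` cycles plant counts over
  5–12 and tints over none/red/purple. The reference battery is 50
  scenes; the heavier mask metrics (Sm, wFm) are reported on the first 8
  scenes of the battery to keep the acceptance run inside a desk-scale
  budget.

What passing on this substrate shows — and what it does not: the scenes
have exact ground truth, guaranteed spectral separability, and simple
connected plants. Real imagery has specular highlights, soil and algae
with nonzero ExG, touching canopies that merge into one component, and
detector noise that is not area-linear. Synthetic results validate the
algorithmic behaviour (which boxes are kept, how prompts are placed, how
metrics score), not field performance.

## Numerical choices and degenerate inputs

* Boxes are real-valued, half-open `[x_min, x_max) × [y_min, y_max)` on
  0-based pixel indices; areas are continuous; a pixel belongs to a box
  iff its index lies in the half-open range. Out-of-bounds boxes are
  clipped before counting.
* "Overlapping" means intersection area strictly > 0 everywhere
  (touching edges do not overlap); the stricter `RIoU ≥ N_t` condition
  applies only inside the stage-1 penalty gate.
* Constant ExG maps yield an all-zero mask plus a warning (pipelines
  degrade; they do not abort). Zero-area boxes count 0 with a warning.
  `max_oven = 0` skips attenuation entirely.
* Otsu ties resolve to the lowest threshold level; argmax/argmin ties in
  similarity maps and distance ties in point selection resolve to the
  smallest row-major index; score ties in every NMS resolve to larger
  area, then lower id.
* Empty ground truth: AP is NaN with a warning; the structure measure
  follows its original fallbacks (`1 − mean(pred)` / `mean(pred)`); the
  weighted F-measure is NaN with a warning.

## Known limitations

* NCGI is a purely spectral prior: non-green plants (red lettuce at
  late stages, flowering crops) and green non-plant surfaces violate it.
* The stage-1 penalty normalizes by the scene-wide `max_oven`, so its
  strength depends on global redundancy structure; scenes whose maximum
  overlap count comes from a correct box (rather than a union box) can
  still see a correct box attenuated below a nested fragment.
* The mock backends are deliberately simple: the embedder is a colour
  pooling device, and the segmenter is a connected-component selector on
  the vegetation mask. They exercise the contracts, not the behaviour,
  of real foundation-model backends; real adapters plug in behind the
  same three-function interface.
* Per-image processing is serial; the harnesses are small enough that
  parallelism is not worth the determinism risk.
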