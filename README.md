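# greenprompt

Vegetation-cover-aware prompt generation for zero-shot plant instance
segmentation.

## The problem

Phenotyping plants in vertical farms needs per-plant instance masks, but
annotating every crop, growth stage and lighting condition is
impractical, which pushes the field toward zero-shot pipelines: an
open-set, text-prompted detector proposes boxes ("single vegetable"),
and a promptable segmenter turns each box — plus a few labelled points —
into a mask. The bottleneck is prompt quality. Text-prompted detectors
flood dense canopies with redundant boxes: several nested boxes around
one plant, and large union boxes spanning adjacent plants that, because
bigger boxes tend to score higher, outrank the correct tight boxes.
Confidence-and-IoU suppression (greedy NMS, Soft-NMS) cannot fix this —
a union box's IoU against a tight box nested inside it is low, so it
escapes suppression while winning on confidence.

`greenprompt` implements, in R, a vegetation-cover-aware alternative and
everything needed to exercise it offline: VC-NMS, similarity-map point
prompts with a max-distance criterion, the detection/segmentation metric
suite, deterministic mock detector/embedder/segmenter backends, and a
seeded synthetic vertical-farm scene generator with exact ground truth.

## The method

With a vegetation mask from Otsu-thresholding the Excess Green index
(ExG = 2G − R − B), each candidate box `b_i` in a set with confidences
`s_i` gets a Normalized Cover Green Index

    NCGI(b_i) = NCGI_raw(b_i) / max_{k ∈ overlap(b_i)} NCGI_raw(b_k)

(green-pixel count normalized over its overlap cluster). VC-NMS then
runs two stages:

1. **Composite scoring + overlap-count attenuation.**
   `s_i ← β·NCGI_i + (1−β)·s_i` with β = 0.7; in non-ascending composite
   order, any box with RIoU ≥ N_t = 0.7 against a later-ordered box and
   strictly more overlapping boxes is multiplied by
   `1 − oven_i / max_oven`. Multi-plant union boxes overlap the most
   boxes, so the factor drives them toward zero.
2. **RIoU-Gaussian selection.** Repeatedly keep the top-scored box and
   decay every remaining score by `exp(−RIoU(M, b_i)²/σ)` (σ = 0.5),
   dropping boxes below the 0.1 retention threshold. RIoU
   (intersection over the *smaller* area) saturates at 1 for nesting, so
   nested duplicates die while adjacent plants survive.

Each kept box then receives point prompts: a positive/negative base
point at the argmax/argmin of a cosine similarity map against the
highest-scoring ("reference") box's pooled foreground features, plus
enhanced points placed by the max-distance criterion inside the region's
ExG/Otsu foreground and background (default 2 positive + 2 negative).

## Worked example

```r
library(greenprompt)

scene     <- generate_scene(scene_config(n_plants = 6, seed = 42))
proposals <- generate_proposals(scene, proposal_config(seed = 42))  # 15 boxes
result    <- vc_nms(scene$image, proposals)
glance(result)
#> # A tibble: 1 × 5
#>   method n_input n_kept n_suppressed mean_kept_score
#>   <chr>    <int>  <int>        <int>           <dbl>
#> 1 vc          15      6            9           0.408
```

Six plants, fifteen proposals (nested boxes, union boxes, area-biased
scores), six kept boxes — one per plant, each carrying its composite
NCGI score. The full pipeline and its scene-level evaluation:

```r
instances <- segment_image(scene$image, scene_backends(scene, proposals))
evaluate_scene_segmentation(instances, scene)
#> # A tibble: 1 × 5
#>     iou  dice     ece    sm   wfm
#>   <dbl> <dbl>   <dbl> <dbl> <dbl>
#> 1 0.826 0.905 0.00738 0.802 0.914
```

The pooled predicted masks overlap the ground truth at Dice 0.905 with
near-zero calibration error. Comparing NMS variants on the identical
proposal set shows why the vegetation prior matters:

```r
run_nms_comparison(list(scene), list(proposals))[, c("method", "ap_50", "ap_50_95", "recall_10")]
#> # A tibble: 4 × 4
#>   method        ap_50 ap_50_95 recall_10
#>   <chr>         <dbl>    <dbl>     <dbl>
#> 1 vc            1        0.706     0.733
#> 2 greedy        0.450    0.332     0.5
#> 3 soft_linear   0.450    0.332     0.5
#> 4 soft_gaussian 0.414    0.303     0.5
```

Confidence-ranked suppression keeps the high-scoring union boxes and
loses half its precision; VC-NMS recovers every plant. `autoplot()`
methods draw scenes, proposals and kept/suppressed boxes; `tidy()` and
`glance()` turn results into analysis-ready tibbles.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/greenprompt.R synth --seed 5 --n-scenes 2 --out scenes/
Rscript inst/cli/greenprompt.R nms --boxes scenes/proposals_001.json \
    --image scenes/scene_001.png --method vc --out kept.json
Rscript inst/cli/greenprompt.R prompts --boxes kept.json \
    --image scenes/scene_001.png --out prompts.json
```

Subcommands: `synth`, `nms`, `prompts`, `segment`, `eval`, `bench-nms`,
`sweep-points`, `sweep-beta`.

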