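---
title: "Weakly supervised bleeding segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised bleeding segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In biportal endoscopic spine surgery the operative field is viewed through an
endoscope under continuous saline irrigation. Even small bleeders rapidly
cloud the field, and there is no accepted objective measure of how much of
the view is obscured by blood. `endobleed` implements a two-stage weakly
supervised pipeline for detecting and quantifying bleeding in endoscopic
frames and videos, together with the multi-rater evaluation protocol needed
to validate such a model when even expert annotators disagree about what
counts as "bleeding".

The central difficulty is that *redness is necessary but not sufficient*:
vessels and exposed cancellous bone are red but are not bleeding. Stage one
therefore trains a segmentation network on cheap, exhaustive **weak labels**
(all red pixels); stage two **fine-tunes** the network on a small curated set
in which red distractors carry all-negative *zero masks*, teaching the model
to suppress them while keeping genuine bleeding.

## Weak labels

A frame is converted to HSV (hue stored in half-degrees, 0–180, so the
printed band bounds fit 8-bit storage; saturation and value 0–255). A pixel
is *red* iff

* hue ∈ [0, 8] ∪ [172, 180] (inclusive; 180 ≡ 0),
* saturation ∈ [90, 255], value ∈ [50, 255],

and belongs to the *field of view* (FOV) iff saturation > 60 and value > 70
(strict), which removes the black lens margin. The weak label is the
intersection of the red and FOV masks; its pixel count divided by the FOV
pixel count is the frame's red-area ratio. Frames with a ratio of at most 1%
are dropped from training ("exceeding 1%" is read strictly; the bound is a
parameter). Saturation of an achromatic pixel is defined as 0, and mask PNGs
store only 0/255, with a tolerant read mode (>127 ⇒ positive) for lossy
files.

## The segmentation network

The published pipeline uses an off-the-shelf deep segmentation architecture
(a nested dense-skip encoder–decoder with a 34-layer residual encoder,
randomly initialised). This package authors its network from first
principles in compiled code: a nested-skip convolutional encoder–decoder
with two encoder levels, a bottleneck, nearest-neighbour upsampling, and the
dense top-level intermediate node characteristic of nested-skip (U-Net++
style) designs, emitting a one-channel logit map at input resolution. The
analytic gradients are verified against finite differences in the test
suite.

Two profiles are first-class:

| parameter | paper profile | test profile |
|---|---|---|
| input size | 512 × 512 | 128 × 128 |
| channel widths | 32/64/128 | 4/8/16 |
| learning rate (Adam) | 1e-4 | 1e-3 |
| batch size | 4 | 4 |
| base early-stop patience | 20 (val. loss) | 4 |
| fine-tune patience | 10 (val. Dice) | 4 |

The test profile shrinks scale only — every formula (loss, thresholds,
stopping rule, augmentation) is identical. The larger step size compensates
for the much smaller parameter count; with it the test-profile network
converges in ten to twenty epochs on a desktop CPU. Training minimises
binary cross-entropy with logits, computed in the numerically stable form
`max(z,0) − z·t + log(1+exp(−|z|))`, and early stopping counts an epoch as
improving only when the monitored quantity moves by more than
`improvement_epsilon` (1e-4; the source material says only "no
improvement"). Predictions binarise `sigmoid(logit)` at a *strict* 0.5: a
logit of exactly zero is negative, fixing the measure-zero boundary for
determinism.

Fine-tuning resumes from the base checkpoint and monitors the mean Dice over
a held-out monitoring set (IoU is logged alongside; the aggregation rule is
the package's choice since the source names both metrics without one). The
monitoring set must be source-disjoint from the curated set — shared source
ids are refused — and the package enforces a three-way split
(curated / monitoring / test) because the published description leaves the
overlap between the fine-tuning monitor and the final test set ambiguous.
Zero-mask samples enter the loss unweighted.

## Synthetic scenes

Because no surgical footage is distributable, the generator builds scenes
with the statistical structure the pipeline assumes:

* a bright circular surgical field on a near-black margin (< 50/255);
* bleeding *plumes*: a sum of Gaussian blobs thresholded at the exact field
  quantile that yields the requested FOV area fraction (quantile
  thresholding replaces iterative bisection — it hits the target count
  exactly and is deterministic), giving diffuse irregular boundaries like
  irrigated blood;
* *vessels*: quadratic Bézier polylines 2–4 px wide;
* *bone*: a speckled ellipse, mimicking cancellous bone;
* colours: all three red components are sampled strictly inside the red HSV
  bands (with margins absorbing 8-bit quantisation), tissue strictly outside
  them but inside the FOV thresholds.

By construction the weak label equals the union
bleeding ∪ vessel ∪ bone on hard-edged scenes (Dice ≥ 0.99 over seeds), so
the HSV stage has an exact oracle, and the truth masks are pairwise disjoint
and FOV-contained. Videos share one seeded geometry and move only the plume
threshold, so per-frame truth areas follow the growth schedule and masks are
nested. Simulated annotators perturb the truth with dilation/erosion,
boundary jitter (blurred mask plus a smooth noise field re-thresholded at
0.5, confined to the boundary band so empty and solid masks are stable), and
random dropping of small components; expected Dice against truth decreases
monotonically in the jitter scale, which the tests verify by Monte Carlo.

What the generator does **not** emulate: irrigation optics, motion blur,
specular highlights, instruments, old clotted (non-red) blood, and the
gradual colour gradients of real tissue. Passing tests therefore demonstrate
that the pipeline's machinery is correct and that the two-stage effect
(distractor suppression with preserved bleeding Dice) is real at desk scale;
they do not certify clinical performance.

## Evaluation protocol

Evaluation mirrors a five-rater protocol: pairwise mean Dice/IoU matrices
over the evaluation images; exhaustive selection of the `k = 3` most
mutually consistent raters (maximising mean within-subset pairwise Dice,
ties broken lexicographically by rater id); the per-image *GT agreement* is
the mean of the panel's three pairwise Dice values. Image-wise detection is
positive iff at least one positive pixel lies inside the FOV (a minimum-area
override exists, default 0), tallied over every (image, rater) pair into a
2×2 table with accuracy/sensitivity/specificity/PPV/NPV. Confidence
intervals default to Wilson because the published table's printed intervals
match the Wilson score interval, not the exact method the statistics section
names; Clopper–Pearson is available via `method = "clopper_pearson"`.

Dice/IoU summaries are restricted to GT-positive images (both-empty pairs
score 1 for bookkeeping but never enter area summaries). Agreement strata
are cumulative (≥0.70 ⊇ ≥0.80 ⊇ ≥0.90; the highest threshold is a config
value since the source prints both 0.89 and 0.90); bleeding-area strata
split GT-positive records at 20% with the boundary assigned to the low
group. Correlation uses Spearman's ρ with average ranks and the two-tailed
t-approximation, gated by Shapiro–Wilk; pooled pixel-wise precision–recall
uses step interpolation for average precision. Reported tables round half-up
to two decimals. For per-rater diagnostics, both a fixed top-3 consensus and
a leave-one-out consensus are defensible; the package computes metrics
against whatever mask collection it is given, so either convention can be
assembled.

## Video quantification

Frame-by-frame inference writes a timeline with both denominators: the
bleeding-area ratio over *all* frame pixels (the default, matching the
published definition) and over the FOV pixel count (offered because the
ratio "within the endoscopic field" is the clinically interpreted quantity);
both columns are always present. Composite review frames show footage,
overlay (semi-transparent fill confined to predicted pixels) and a running
ratio plot. Videos are numbered-frame directories or in-memory frame lists;
a throughput utility reports fps and per-frame latency (hardware-bound,
never an acceptance quantity).

## Problem sizes and numerical choices

The end-to-end experiments (`two_stage_experiment()`, the test suite, the
acceptance script) use the test profile with 96 base scenes from 12 sources
(85/15 source-level split — the base-model validation split is not described
in the source, so the package mirrors the leakage rule and splits by source,
seeded), 30 bleeding + 45 zero-mask curated samples, 12 monitoring scenes
and 40 evaluation scenes, with three fixed seeds and majority voting for the
stochastic claims. Augmentation defaults: horizontal flip p = 0.5,
brightness and saturation jitter ±20% (unstated in the source; moderate
photometric robustness that keeps typical reds inside the HSV bands).
Frame sampling takes timestamps k/rate mapped to the nearest native frame
(the source states only the rate). Degenerate inputs are first-class errors:
all-black frames (empty FOV), empty evaluation FOV masks, leaking source
ids, all-zero confusion tables, constant correlation inputs.

## Known limitations

* The paper-profile network is structurally faithful but far smaller than a
  34-layer residual encoder; no framework-grade deep learning stack is used
  anywhere, which bounds achievable capacity.
* Synthetic raters share one noise family; real annotator disagreement is
  richer (systematic semantic differences, not just boundary noise).
* MP4 containers are not read or written; videos are frame directories.
* Real-data quantities (e.g. a median Dice of 0.79 on surgical frames) are
  out of reach of synthetic scenes by design and are not claimed.
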