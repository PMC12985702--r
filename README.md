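# endobleed

Weakly supervised detection and quantification of intraoperative bleeding in
endoscopic surgical video.

## The problem

In biportal endoscopic spine surgery the field is viewed through an endoscope
under continuous saline irrigation, and even minor bleeding rapidly obscures
it. There is no objective measure of how much of the view is lost to blood.
The catch for any colour-based detector is that *red is not bleeding*:
vessels and exposed cancellous bone are red too.

`endobleed` implements a two-stage pipeline for surgeons and surgical-AI
researchers:

1. **Weak labels.** Every frame is thresholded in HSV space — a pixel is red
   iff hue ∈ [0, 8] ∪ [172, 180] (half-degrees), saturation ∈ [90, 255] and
   value ∈ [50, 255] — intersected with a field-of-view mask (saturation > 60,
   value > 70) that removes the black lens margin. Frames whose red-area
   ratio within the field exceeds 1% become training pairs.
2. **Base model.** A nested-skip convolutional encoder–decoder (one-channel
   logit map at input resolution, binary cross-entropy with logits, Adam,
   early stopping on validation loss) learns to segment *all* red regions.
3. **Fine-tuning.** The base model is resumed on a small curated set where
   images of definite bleeding carry red masks and images whose red content
   is a distractor (vessel, cancellous bone) carry all-negative *zero masks*,
   with early stopping on the mean Dice
   (D = 2|A∩B| / (|A|+|B|)) against a held-out monitoring set. The model
   keeps its sensitivity to bleeding while suppressing distractors.

Around the model, the package provides a seeded synthetic endoscopic scene
generator with per-component truth masks and simulated annotators, a
multi-rater evaluation suite (pairwise Dice/IoU agreement, exhaustive
consensus-panel selection, Wilson and Clopper–Pearson intervals, agreement
and bleeding-area stratification, Spearman correlation, pooled pixel-wise
average precision), and frame-by-frame video quantification that plots the
bleeding-area ratio over time.

## Worked example

Train both stages on synthetic scenes at the CPU-scale test profile
(128 × 128 inputs) and measure the fine-tuning effect:

```r
library(endobleed)
run <- two_stage_experiment(seed = 1)
cat(sprintf("base dice %.3f  FP %.0f -> %.0f (-%.0f%%)  bleeding dice %.3f -> %.3f\n",
            run$base_dice_holdout, run$fp_area_base, run$fp_area_finetuned,
            100 * run$fp_reduction, run$bleeding_dice_base,
            run$bleeding_dice_finetuned))
#> base dice 0.992  FP 566 -> 57 (-90%)  bleeding dice 0.941 -> 0.970
```

Read: the base model reproduces held-out weak labels almost perfectly
(Dice 0.992), but like any colour detector it also fires on vessels and bone
(566 false-positive pixels per distractor-only scene). Fine-tuning with zero
masks removes 90% of that false-positive area while the Dice on genuine
bleeding scenes *improves* from 0.941 to 0.970 — the two-stage design works.

The evaluation suite reproduces printed-table arithmetic exactly. From a
confusion table of 129 TP / 25 TN / 17 FP / 9 FN over 180 image–rater
evaluations:

```r
detection_metrics(confusion_counts(129, 25, 17, 9))[, c("value", "lo", "hi")]
#>                 value        lo        hi
#> accuracy    0.8555556 0.7967698 0.8994823
#> sensitivity 0.9347826 0.8807023 0.9653127
#> specificity 0.5952381 0.4449431 0.7295714
#> ppv         0.8835616 0.8214386 0.9260181
#> npv         0.7352941 0.5688286 0.8539881
```

i.e. accuracy 0.86, sensitivity 0.93 (95% Wilson CI 0.88–0.97), specificity
0.60 (0.44–0.73), PPV 0.88, NPV 0.74 at two decimals.

Video quantification with a 20-frame synthetic growth video:

```r
vid <- make_video(scene_params(image_size = 128, plume_area_frac = 0.05, seed = 7),
                  n_frames = 20, growth = 0.02)
res <- infer_video(run$finetuned_ckpt, vid)
head(res$timeline, 3)
#>   frame time_s      ratio ratio_full  ratio_fov
#> 1     1    0.0 0.03198242 0.03198242 0.05025415
#> 2     2    0.5 0.04382324 0.04382324 0.06885969
#> 3     3    1.0 0.05517578 0.05517578 0.08669800
```

`ratio_full` divides predicted bleeding pixels by all frame pixels,
`ratio_fov` by the field-of-view pixel count; `render_composite()` writes
review frames (footage | overlay | running ratio plot).

A thin CLI wraps the staged pipeline
(`synth | label | filter | split | train | curate | finetune | evaluate | video | all`):

```sh
Rscript inst/cli/endobleed all --profile test --seed 1 --out run1
```

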