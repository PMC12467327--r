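# ascseg — slice-recurrent aorta segmentation for poorly contrast-enhanced CT

`ascseg` implements **automatic spatial contrast (ASC)** enhancement for
segmenting the aorta in CT volumes whose blood pool is poorly or not
contrast-enhanced (mean aortic intensity in [100, 250] HU instead of the
well-enhanced > 250 HU). Standard 2D segmentation networks work well on
optimally contrasted scans but degrade sharply when contrast is weak; ASC
exploits the anatomy — the aortic cross-section shifts only slightly
between adjacent axial slices — to brighten, on each slice, exactly the
region where the previous slice's prediction found the aorta.

It is aimed at medical-image-analysis researchers who want a complete,
CPU-testable reference pipeline: volume I/O, contrast-level
classification, a seeded synthetic phantom generator, 2.5D block
construction, the enhancement gate itself, a compact trainable
encoder–decoder, Dice/IoU evaluation, and complexity/ablation reporting.

## The method

Slices are processed in overlapping blocks of *n* consecutive slices
(default *n* = 4). The first slice is segmented from its raw intensities
by a shared 2D sub-model. For each subsequent slice *x*, the previous
slice's predicted probability map is partitioned into *ks* × *ks* kernels
(default 16 × 16) and turned into an enhancement map

    e_m(kernel) = EF   if mean probability over the kernel > ε
                = 1.0  otherwise,

and the slice is enhanced by element-wise multiplication before
segmentation:

    x' = x ⊙ e_m .

EF > 1 is the enhancement factor (1.1 for well-contrasted Level 1 data,
1.4 for poorly contrasted Level 2) and ε (default 0.5) is the kernel
evidence threshold. After *n* − 1 such steps the last slice's prediction
is the block's output. The gate is hard (two-valued), parameter-free and
non-differentiable: the wrapped model has exactly the same trainable
parameter count as the bare sub-model, and the extra cost is O(N) per
slice against the sub-model's O(N·B²) — a fraction 1/B² (1/4096 at
B = 64).

Evaluation uses the Dice similarity coefficient and IoU,

    DSC = 2·TP / (2·TP + FP + FN),   IoU = TP / (TP + FP + FN),

pooled over evaluated slices, plus difference maps
(black/white/blue/red = TN/TP/FN/FP) and the Dice false-positive
sensitivity ∂DSC/∂FP = −2·TP/(2·TP + FP + FN)².

## Worked example

Train on three synthetic poorly-contrasted phantoms and evaluate on a
held-out one (a couple of minutes on one CPU core):

```r
library(ascseg)

train <- lapply(1:3, function(i)
  generate_phantom(phantom_spec(level = 2, seed = 100 + i)))
test <- generate_phantom(phantom_spec(level = 2, seed = 199))
classify_level(test$volume, test$mask)
#> [1] "2"

fit <- asc_fit(lapply(train, `[[`, "volume"), lapply(train, `[[`, "mask"),
               block_size = 4,
               asc = asc_config(kernel_size = 16, factor = 1.4),
               segmenter = reference_unet(ref_unet_config(channel_width = 8,
                                                          depth = 2), seed = 1),
               control = train_control(epochs = 20, learning_rate = 3e-3,
                                       batch_size = 2, seed = 1))
fit
#> Slice-recurrent CT segmentation model
#>   sub-model: reference_unet, 29,626 trainable parameters
#>   enhancement: kernel 16, epsilon 0.5, factor 1.4
#>   trained on 15 blocks of 4 slices for 20 epochs; final loss 0.003166

pred <- predict(fit, test$volume)
pred
#> Inference result 'phantom_L2_s199' (block mode): 5 slice predictions, 15 enhancement steps

evaluate_predictions(pred, test$mask)$metrics
#> DSC 0.8495 | IoU 0.7384  (TP 618, FP 0, FN 219, TN 19643; N = 20480)
```

The five predictions are the targets of the five overlapping 4-slice
blocks of the 8-slice test volume (S − n + 1 blocks, n − 1 = 3
enhancement steps each). A held-out DSC of 0.85 with zero false positives
means the model recovered the drifting vessel cross-section from
low-contrast slices; training the identically seeded model without
enhancement (`asc = NULL`) gives a direct baseline comparison.

A thin command-line front end over the same functions ships at
`inst/scripts/asc-seg` (subcommands `simulate`, `train`, `infer`, `eval`).

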