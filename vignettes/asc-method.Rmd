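---
title: "Automatic spatial contrast for low-contrast CT segmentation: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic spatial contrast for low-contrast CT segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Contrast agent cannot always be administered before a CT scan, and
without it the aortic blood pool sits at 100–250 HU — barely
distinguishable from surrounding soft tissue. Purely 2D segmentation
networks, trained to find a bright tube, lose most of their accuracy in
this regime, while fully 3D networks pay a prohibitive memory cost.

`ascseg` implements a middle road: a *slice-recurrent* 2.5D scheme in
which a single shared 2D sub-model is threaded through a block of $n$
consecutive slices, and an anatomical prior — the aortic cross-section
moves only slightly between adjacent slices — is injected as an explicit
multiplicative contrast boost. Given the sub-model's prediction
$V_p$ for slice $k-1$, the prediction is partitioned into
$ks \times ks$ kernels and each kernel is mapped to a constant
multiplier:

$$
e_m(\text{kernel}) =
\begin{cases}
EF & \overline{V_p}(\text{kernel}) > \varepsilon \\
1.0 & \text{otherwise,}
\end{cases}
\qquad
x' = x \odot e_m,
$$

where $x$ is slice $k$'s (window-normalized) intensity image. The
enhanced $x'$ is fed to the same sub-model; after $n-1$ such steps the
last slice's prediction is the block's output. The gate is *hard*
attention: two-valued, piecewise-constant on the kernel grid, and
parameter-free, so the wrapped model has exactly the sub-model's
trainable parameter count and the extra work is $O(N)$ per slice against
the sub-model's $O(NB^2)$ (`asc_cost_fraction(B)` $= 1/B^2$, about
1/4096 at the reference width $B = 64$).

Kernels, rather than per-pixel gating, are the point: enlarging the
enhanced region to kernel granularity tolerates the small inter-slice
displacement of the aorta, so the boost still covers the vessel on the
next slice even when it has drifted.

## Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `kernel_size` | gate granularity, px | 16 | 8/16/32 in the ablation grid |
| `factor` (EF) | multiplier inside enhanced kernels | 1.1 (Level 1), 1.4 (Level 2) | the reference setting per contrast level |
| `epsilon` | kernel mean-probability threshold | 0.5 | majority evidence; never reported in the reference protocol, hence configurable; 1 disables the gate |
| `binarize_first` | threshold $V_p$ at 0.5 before kernel means | `FALSE` | the kernel statistic is ambiguous (soft vs. binary); both are provided |
| block size `n` | slices per 2.5D block | 4 | 2 and 3 supported for ablations |
| `hu_window` | intensity window mapped to [0, 1] | (−100, 600) HU | see below |
| `train_control()` | batch 4, lr 1e-6, 200 epochs, Adam | — | the full-scale reference protocol |

Normalization matters because the gate is multiplicative: on raw HU a
factor > 1 would *darken* negative-HU pixels. The (−100, 600) HU window
spans soft tissue through strongly enhanced blood and makes every input
non-negative. Enhanced intensities may exceed 1 and are deliberately not
clipped — clipping would delete exactly the contrast the gate adds — so
the sub-model contract requires accepting unbounded non-negative inputs.

Ties at the threshold are resolved against enhancement (strict `>`).
When the slice shape is not a kernel multiple, the prediction is
zero-padded bottom/right and the map cropped back, biasing boundary
kernels toward non-enhancement (the conservative direction).

## Level classification

Cases are split by the mean ground-truth-foreground HU: above 250 is
well contrasted ("Level 1"), the closed interval [100, 250] is poorly
contrasted ("Level 2"), and below 100 is excluded. The boundary 250
belongs to Level 2 because Level 1 is defined strictly as "over" 250.
The summary statistic (mean) is a choice — the defining protocol names
only "the CT values at the aorta locations" — and is configurable via
the `statistic` argument of `classify_level()`.

## Training procedure

Blocks overlap with stride 1 (a volume of $S$ slices yields $S-n+1$
blocks; every slice from $n$ onward is exactly one block's target) and
are shuffled *as units* each epoch under a recorded seed; the slice
order inside a block is never altered. The loss is mean per-pixel
two-class cross-entropy on the target slice only;
`supervise_intermediate = TRUE` adds equally weighted terms for slices
$2 \dots n-1$. Neither the loss nor intermediate supervision is
specified by the reference protocol; target-only cross-entropy is the
least-assuming default.

Previous-slice predictions are constants with respect to gradients: the
kernel thresholding is non-differentiable anyway, so no gradient flows
through map construction, and each supervised slice backpropagates
through its own forward pass only. Training is bitwise-reproducible
under a fixed seed on one CPU. Cases shorter than the block size are
skipped with a warning rather than padded.

The default binarization threshold for evaluation is 0.5, i.e. the
argmax of the two softmax classes. Headline DSC/IoU pool TP/FP/FN over
all evaluated slices (micro); unweighted per-slice means are reported
alongside, since the aggregation convention is otherwise unstated.

Two inference modes exist because the evaluation protocol ("compare the
last slice's prediction") and the motivation ("predict a case
sequentially") suggest different loops: `block` mode runs every stride-1
block and predicts slices $n \dots S$; `carry` mode makes one pass,
enhancing each slice by the immediately preceding prediction, and
predicts all $S$ slices. They coincide at $S = n$. `block` is the
default because it matches the evaluation convention.

## The reference sub-model

No deep-learning framework is assumed: the package ships a compact
trainable encoder–decoder written directly in R (im2col convolutions as
BLAS matrix products, hand-written backpropagation, Adam). It is the
canonical UNet design — per level two 3×3 convolutions + ReLU, 2× max
pooling, nearest-neighbour upsampling with skip concatenation, final
1×1 convolution to 2 classes with softmax. Width $B$ (channels after the
first convolution) and depth are configurable; $B = 64$, depth 4
corresponds to the full-scale complexity analysis, while tests and
examples use $B = 8$, depth 2 at 64×64 for CPU speed. Gradients are
verified against central finite differences in the test suite. Any
other model can be plugged in through the segmenter contract
(`seg_forward()` / `param_count()` / `make_segmenter()`); transformer
backbones are deliberately not reimplemented.

FLOPs are counted analytically (multiply–accumulate = 2 FLOPs,
convolutions only), and the per-target-slice figure for a block of $m$
slices is $m$ times the single-slice cost, with the gate's $O(N)$ term
excluded from the headline number and available separately
(`asc_step_flops()`), following the usual reporting convention.

## The synthetic phantom

Real scans of this kind come as NRRD volumes with per-slice ground
truth; the phantom generator reproduces the structural properties the
method actually exploits so that every stage is testable without any
download:

- one or more filled-ellipse vessel cross-sections whose centroids
  drift at most `drift_per_slice` pixels (default 2 at 64×64) between
  adjacent slices, with smoothly random-walking radii — no quantitative
  drift bound is published, so the default is a modeling choice;
- optional per-slice splitting/merging of a vessel into two lobes
  (branching aortic anatomy);
- foreground intensity drawn so the case-level foreground mean falls in
  the requested contrast level's HU range *before* noise (Level 1:
  drawn in [300, 450]; Level 2: [120, 230] — comfortably inside the
  defining intervals so that additive noise cannot flip the
  classification);
- a uniform soft-tissue background (40 HU) with two lung-like −700 HU
  ovals for non-trivial context, and additive zero-mean Gaussian noise
  (default sd 15 HU);
- configurable voxel depth (0.625/1.25/2.5/5.0 mm) and seeded,
  bit-reproducible output.

What the phantom does **not** emulate: anatomically realistic shape,
partial-volume effects, beam hardening, scanner noise spectra, or
neighbouring organs that mimic the aorta. Passing the phantom efficacy
test therefore demonstrates that the recurrent gate mechanism works as
designed — that enhancement driven by the previous slice's prediction
improves low-contrast segmentation in a controlled setting — not that
any particular accuracy will transfer to clinical data.

## Problem sizes used in tests and the acceptance script

Unit tests run on 32×32 and 64×64 phantoms with a $B \in \{2, 4\}$,
depth-2 sub-model and 1–5 epochs; the properties they check (oracle
equivalence, counts, identities, reproducibility) are size-independent.
The efficacy demonstration uses the package's chosen desk-scale study
condition: Level-2 phantoms of 64×64×8, sub-model $B = 8$/depth 2,
blocks of 4, kernel 16, EF 1.4, three training phantoms and one held-out
phantom per seed, three seeds, 20 epochs. At this scale the reference
protocol's learning rate (1e-6) moves nothing; the demonstration uses
learning rate 3e-3 with batch size 2 — applied identically to the
enhanced and baseline arms, whose comparison is the point. The demo is
directional: enhanced mean held-out DSC should match or exceed the
identically seeded baseline's in most seeds; full-scale accuracy
magnitudes are not expected from a desk-scale run.

## Numerical choices and degenerate inputs

- Kernel means are computed in double precision; map values are exactly
  `1.0` or `EF`, and pixels under `1.0` are returned bit-identical.
- `DSC`/`IoU` on two empty masks are defined as 1.0 (perfect agreement
  on absence); empty vs. non-empty is 0.0. The raw formulas are 0/0
  there.
- Confusion counts are exact integers; the identity
  $DSC = 2\,IoU/(1+IoU)$ holds to machine precision and is
  property-tested.
- Max-pool backward routes gradient to the first maximum on ties.
- Adam uses standard bias correction ($\beta_1 = 0.9$,
  $\beta_2 = 0.999$, $\epsilon = 10^{-8}$).
- Volumes are stored `(slice, row, col)`, 1-based; both NRRD and NIfTI
  axis orders are normalized to this layout on read, and spacings are
  written at full float precision.

## Known limitations

- The enhancement factor is a fixed scalar per contrast level; adaptive
  or learnable factors are out of scope.
- Soft-attention variants and two-network localization/segmentation
  pipelines are deliberately not implemented.
- The reference sub-model is a CPU-scale implementation: practical for
  64–128 px phantoms and correctness verification, not for 512×512
  clinical training runs.
- The NRRD reader covers the subset of the format the package and its
  source datasets use (3-D payloads, raw/gzip/ascii encodings), not the
  full specification (no detached headers, no block types).
- Error accumulation over long carry-mode runs is unmitigated: a wrong
  early prediction can mis-steer enhancement of later slices; block
  mode bounds this to $n-1$ steps.
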