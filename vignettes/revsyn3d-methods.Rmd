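---
title: "Bidirectional cross-modality synthesis and multimodal diagnosis: models and design"
author: "revsyn3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional cross-modality synthesis and multimodal diagnosis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multimodal neuroimaging improves the diagnosis of Alzheimer's disease:
structural T1-MRI shows atrophy, FDG-PET shows hypometabolism, and the two
carry complementary information. In practice many subjects have MRI but no
PET (cost, radioactive tracer), and discarding incomplete cases shrinks the
training set. This package implements the alternative: *synthesize* the
missing modality from the present one with a bidirectional generative
model, then feed real-plus-synthetic pairs to a multimodal classifier.

Three components make up the pipeline:

1. a **reversible GAN** whose single generator maps both MRI→PET and
   PET→MRI through a weight-shared invertible core;
2. a **four-layer 3D CNN** that classifies a two-channel (MRI, PET) volume;
3. a **paired-modality phantom generator** that provides desk-scale data
   with a known ground-truth mapping, since the real cohort data
   (access-controlled clinical imaging) cannot ship with a package.

## The synthesis model

The generator is `dec ∘ core ∘ enc`. Encoders (one per domain) lift a
1-channel volume into a `width`-channel feature space with a 3×3×3
convolution, instance normalisation and ReLU. Decoders project back with a
1×1×1 convolution and tanh. Between them sits the invertible core: a stack
of additive-coupling blocks. Each block splits the channels into halves
and applies

    y1 = x1 + R1(x2)
    y2 = x2 + R2(y1)

with the exact algebraic inverse `x2 = y2 − R2(y1)`, `x1 = y1 − R1(x2)`.
R1 and R2 are small two-convolution subnetworks (instance norm + ReLU
between the convolutions, final convolution unactivated); they need not be
invertible themselves. Because the inverse reuses the same weights, the
A→B direction (`coreForward`) and the B→A direction (`coreInverse`) are
one parameter set: training either trains both. Two such blocks are used
by default.

Two PatchGAN discriminators (three stride-2 convolution stages, instance
norm, leaky ReLU, patch-map output) judge local realism in each domain.
The training objective is

    L = L_GAN(G, D1) + L_GAN(G^-1, D2) + lambda * L_cyc(G, G^-1)

with least-squares adversarial terms (real→1, fake→0; the generator
targets 1) and an L1 cycle term over both round trips. The adversarial
form and `lambda` are not dictated by the formulation; we use the
least-squares convention of the PatchGAN/CycleGAN lineage and
`lambda = 10`, both configurable via `lossWeights()` / `trainConfig()`.

Data on `[0, 1]` enters the model as `2x − 1` and leaves as `(y + 1)/2`,
because the decoders end in tanh; otherwise real targets would be
unreachable.

### Invertibility and memory

`coreInverse(coreForward(x))` recovers `x` to numerical precision
(≈1e−15 in double precision, well below 1e−4 in single precision). A
practical corollary is the memory contract of reversible nets: every
intermediate activation of the core can be *recomputed* from its output by
running the couplings backwards, so a deep core does not need to store
activations — the property that makes reversible generators attractive for
large 3D volumes. A test verifies recomputed activations match stored
ones.

### Training procedure

Per iteration: D1 and D2 take one least-squares step each on
real-vs-synthetic volumes (synthetic volumes detached), then the generator
takes one step on the full objective against the freshly updated
discriminators. Adam uses learning rate 2e−4 and betas (0.5, 0.999), the
GAN convention. All initialisation and batch sampling derive from
`trainConfig(seed=)`; CPU runs are bit-reproducible, and checkpoints
reloaded from disk predict bit-identically.

## The diagnosis CNN

Four convolution layers with cubic kernels 1, 5, 9, 5 and channels
4, 32, 64, 64; instance normalisation (not batch norm), ReLU and 2×2×2 max
pooling after each; then fully connected layers of widths 512 and 2 and a
softmax. The 1×1×1 first kernel deliberately avoids early spatial
downsampling. Convolutions are same-padded, so the printed kernel sizes
set receptive fields, not spatial shapes; pooling alone downsamples (16×
overall, which is why input extents must be divisible by 16). Modalities
are fused at the channel level: a paired sample becomes a two-channel 4D
tensor. Feature maps here are channel-last (`X × Y × Z × C`), the
column-major-friendly layout; the published channel-first notation
`2 × 96 × 96 × 48` describes the same object.

Classifier training choices that were ours to make: Adam at 3e−4 with
betas (0.9, 0.999); minibatches of 8 drawn class-balanced (this keeps the
softmax prior centred and stabilises calibration on small cohorts); the
final FC layer initialised to zero so logits start at chance and early
updates fit the discriminative direction rather than a class bias; the
best-on-validation parameters returned (validation accuracy, loss breaking
ties).

### Splits and cross-validation

Splits are at **subject** level — a subject's repeat images travel
together, since image-level splits would leak anatomy across parts — and
class-stratified by interleaving, so small test parts contain both
classes. The default ratio is 7:2:1 (train:validation:test) with
largest-remainder apportionment (10 subjects give exactly 7/2/1).
"10-fold cross-validation" is realised as 10 repeated seeded 7:2:1 splits
with test-set evaluation — the reading that reconciles a fixed split ratio
with fold-based evaluation; fold `k` uses seed `seed + k − 1`. Aggregates
are means and standard deviations of ACC/SEN/SPE/AUC over folds.

### The imputation experiment

`runImputationExperiment()` compares, on one cohort and identical splits:
`real` (all paired data), `missing_k` (modality B removed for k% of
subjects and that channel zero-filled — zero-fill keeps sample counts
equal across conditions; how missing channels entered the published
classifier is unstated), `mixed_k` (the removed k% imputed by the
generator) and `all_synthetic` (every B replaced by G(A)). Missingness is
subject-level. Because the sample container anchors on modality A, B→A
imputation is provided as the full-replacement arm only
(`synthesizeMissing(..., "b_to_a", overwrite_all = TRUE)`), which is what
the synthetic-MRI experiments need.

## The phantom generator

`makePhantomPair()` emulates the *structure* of a paired MRI/PET cohort,
not brain anatomy:

- a smooth tissue texture inside an ellipsoidal "brain" (Gaussian random
  field, values in [0.15, 0.62]), shared by both modalities of a subject
  and across that subject's repeat visits;
- a bright **skull shell** present only in modality A (intensity 0.9) —
  so the B→A direction cannot identify the skull from B, the engineered
  analogue of the observation that skull structure is hard to map from
  PET;
- modality B is the **power-law map** `t^gamma` (default `gamma = 2`) of
  the tissue over the brain mask and zero elsewhere — a smooth nonlinear
  intensity relationship the synthesis model has to learn, with
  `groundTruthMap()` as the exact oracle;
- a **class effect**: for the disease label the hippocampus-like blob in A
  shrinks by `effect_size` and the ROI region of B dims by the same
  fraction (atrophy showing in structure and metabolism at once). The
  dimming is exactly multiplicative, so the noise-free ROI mean of B for
  the disease class equals `(1 − effect_size)` times the control value —
  a testable calibration;
- additive Gaussian acquisition noise on B (sd `noise_sd`, truncated to
  [0, 1]), independent across repeat acquisitions, which
  `averageRepeats()` reduces ≈ n-fold.

Defaults: `effect_size = 0.3`, `noise_sd = 0.05`, `skull_intensity = 0.9`,
`mapping_gamma = 2` — a moderately noisy, moderately separable cohort.
Everything is reproducible from `(seed, subject_seed, label,
image_index)`; the label changes no random draws, so matched
control/disease pairs share anatomy.

What the phantom does *not* emulate: real anatomy and registration error,
PET kinetics and scanner point-spread, site effects, age confounds, and
the far weaker class effects of real cohorts. Passing tests therefore
demonstrate that the algorithms are implemented correctly and behave as
designed under known ground truth — not that they would reach any
particular accuracy on clinical data.

## Preprocessing rules

`clipLongTail()` caps long-tailed structural intensities at 1024;
`rescaleMinMax()` applies `target_hi·(x−min)/(max−min)` (constant volumes
are a degenerate-input error); `toUnitRange()` is the same map onto
[0, 1]; `cropROI()` extracts a 96×96×48 box (default) whose first voxel is
`center − floor(size/2)` — indices are 1-based in this implementation,
half-open box geometry unchanged; out-of-bounds crops error by default
(silent padding hides registration bugs) with an opt-in zero-padding mode.
`resizeVolume()` is separable third-order spline interpolation on an
endpoint-aligned grid (221×257×221 → 110×128×110 for full-image work);
constants resize exactly, and mild cubic overshoot is possible. Whether
the functional modality is also clipped before rescaling is left to the
caller — clipping is a separate, optional step per modality.

## Metrics

RMSE; PSNR = `10·log10(range²/MSE)` (infinite on identical volumes;
`data_range` defaults to 1 on unit-scaled volumes and is recorded in every
report); SSIM over 3D neighbourhoods with the standard stabilisers
`C1=(0.01r)²`, `C2=(0.03r)²` — default a 7×7×7 uniform window with
unbiased local variances (small-volume friendly), Gaussian 11-point
optional; only fully interior windows contribute. Deviation maps are
voxelwise absolute differences, min-max rendered to [0, 255] for display.
Classification reports give the confusion table at threshold 0.5 (softmax
argmax for two classes), ACC/SEN/SPE, and AUC by pairwise concordance with
ties counted 1/2 (cross-checked against an independent ROC implementation
in the tests).

## Numerical engine

No deep-learning framework is used: convolutions, pooling, instance
normalisation and Adam are implemented in the package (C++ kernels behind
an R layer). The 3×3×3 stride-1 convolution — the generator's workhorse —
is a direct vectorised kernel; other kernels go through im2col and BLAS
GEMM. Training runs in single precision (round-trip errors well below the
1e−4 float tolerance, irrelevant beside SGD noise); metrics and exactness
checks use the double-precision path.
Instance normalisation uses per-call statistics only (running averages
would break exact inversion) with eps 1e−5. All randomness flows from
user-visible seeds through R's RNG; training is single-threaded-deterministic
and checkpoint round trips are bit-exact.

## Problem sizes used in the shipped experiments

The package's own experiments (tests and `scripts/acceptance.R`) run at
desk scale, chosen once: synthesis trains on 64 noise-free 32×32×16 pairs
for 200 iterations at batch 4 with core width 16 and hidden width 2,
evaluated on 16 held-out pairs; classifier experiments use 16×16×16
phantoms, 40 subjects for separability (effect 0.5) and 20 subjects for
the imputation comparison, with a 0.6/0.1/0.3 split ratio (the larger test
share gives stable fold metrics at these cohort sizes; the 7:2:1 default
remains for full-scale use). The published full-scale setting
(221×257×221 volumes, hundreds of subjects, GPU epochs) is out of scope by
design.

## Known limitations

- The GAN objective has no paired supervised term, so synthesis quality
  rests on the discriminators and cycle consistency; at desk scale the
  learned mapping is crude (though clearly better than the copy-input
  baseline).
- The sample container requires modality A; "A missing" cohorts cannot be
  represented.
- Instance normalisation makes every network output invariant to global
  affine intensity changes of its input; phantoms are generated on [0, 1]
  so this is harmless here, but real-data pipelines should still apply the
  documented rescaling.
- The CNN's fully connected width (512) is fixed while its input width
  depends on volume shape; very small inputs leave only 64 flattened
  features, which bounds capacity at 16×16×16 scale.
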