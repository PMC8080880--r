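# revsyn3d

Bidirectional cross-modality synthesis of 3D brain volumes with a
reversible GAN, and multimodal Alzheimer's-style diagnosis with a compact
3D CNN — including imputation of a missing modality.

## The problem

Structural MRI and FDG-PET carry complementary information about
neurodegeneration, but paired data is scarce: PET is expensive and
involves a radioactive tracer, so many subjects have only MRI. Discarding
incomplete cases shrinks training sets and hurts diagnostic models. This
package implements a synthesis-then-classify pipeline:

1. **Synthesis.** A generative model `G` maps modality A (structural,
   T1-MRI-like) to modality B (functional, FDG-PET-like) *and back* with a
   single parameter set. The generator is `decoder ∘ core ∘ encoder`
   where the core is a stack of additive-coupling blocks

   ```
   y1 = x1 + R1(x2)          x2 = y2 − R2(y1)
   y2 = x2 + R2(y1)          x1 = y1 − R1(x2)
   ```

   whose inverse is exact algebra over the same weights: training A→B
   trains B→A. Two PatchGAN discriminators (one per domain) drive the
   least-squares adversarial loss, combined with an L1 cycle-consistency
   term:

   ```
   L = L_GAN(G, D1) + L_GAN(G⁻¹, D2) + λ·L_cyc(G, G⁻¹)
   ```

2. **Diagnosis.** A four-layer 3D CNN (cubic kernels 1, 5, 9, 5; channels
   4, 32, 64, 64; instance norm; max pooling; FC 512 → 2 → softmax) takes
   the two modalities stacked as channels and outputs two-class
   probabilities. Metrics: ACC, SEN, SPE, AUC under repeated subject-level
   cross-validation.

3. **Imputation experiments.** Cohorts with a missing modality are
   compared under: all-real data, zero-filled missing data, and
   generator-imputed data.

Because the clinical data such methods are built for is access-controlled,
the package ships a **phantom generator**: paired 3D volumes linked by a
known power-law intensity mapping over a brain mask, a skull shell visible
only in modality A, class-dependent ROI atrophy (in A) and dimming (in B),
and repeat acquisitions with independent noise. Every experiment below
runs on phantoms with known ground truth.

Image quality is scored with RMSE, PSNR and SSIM (3D windows), with
per-region breakdowns (e.g. brain vs skull).

## Worked example

```r
library(revsyn3d)

# a paired two-class phantom cohort: 8 subjects per class, 32x32x16 voxels
cfg <- phantomConfig(shape = c(32, 32, 16), noise_sd = 0, effect_size = 0,
                     seed = 11)
cohort <- makeCohort(cfg, n_per_class = 8)
getSample(cohort, 1)
#> PairedSample subject=CN0001 label=CN 32x32x16, b: present

# train the bidirectional synthesis model (a few minutes on one CPU)
ck <- trainSynthesis(cohort, trainConfig(iterations = 200, seed = 1),
                     core_width = 16, core_hidden = 2)
tail(ck$history, 2)
#>        gan_ab   gan_ba       cyc    total         d1         d2
#> 199 0.7150229 1.004802 0.3716486 5.436311 0.06421580 0.03776926
#> 200 1.0272434 1.011466 0.3739425 5.778134 0.05389529 0.06215370

# synthesize modality B from A on a held-out pair and score it
test <- makePhantomPair(phantomConfig(shape = c(32, 32, 16), noise_sd = 0,
                                      effect_size = 0, seed = 99), "CN", 1)
fb <- fromModelRange(generateAtoB(toModelRange(volData(test@a)), ck$model))
rep <- evaluateSynthesis(list(list(real = volData(test@b),
                                   synthetic = array(fb, dim = c(32, 32, 16)))))
rep
#> ImageQualityReport (1 pairs, data range 1)
#>   RMSE 0.0820   PSNR 21.72 dB   SSIM 0.1839
psnr(test@b, test@a)   # copy-input baseline the generator must beat
#> [1] 10.68041
```

The loss history shows the cycle term shrinking while the adversarial
terms hover near their least-squares equilibrium; the synthetic B beats
copying A by ~11 dB of PSNR on a held-out subject (SSIM stays modest at
this tiny desk scale — the mapping is learned, not pixel-perfect). The
inverse direction runs through the very same core:

```r
fa <- fromModelRange(generateBtoA(toModelRange(volData(test@b)), ck$model))
```

Classification on phantoms with a strong class effect:

```r
co <- makeCohort(phantomConfig(shape = c(16, 16, 16), noise_sd = 0.05,
                               effect_size = 0.5, seed = 101),
                 n_per_class = 20)
cv <- crossValidate(co, classifierSpec(),
                    splitSpec(ratios = c(0.6, 0.1, 0.3), n_folds = 2),
                    classifierTrainConfig(iterations = 60))
cv$aggregate
#>   metric mean sd
#> 1    acc    1  0
#> 2    sen    1  0
#> 3    spe    1  0
#> 4    auc    1  0
```

A command-line wrapper over the same functions lives at
`inst/cli/revsyn3d.R` (`phantom-gen`, `preprocess`, `train-syn`,
`synthesize`, `eval-syn`, `train-clf`, `impute-experiment`); all commands
are byte-reproducible given `--seed`.

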