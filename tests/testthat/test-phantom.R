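test_that("phantom pairs are reproducible and bounded in [0,1]", {
  cfg <- tinyCfg(noise_sd = 0.05)
  p1 <- makePhantomPair(cfg, "CN", subject_seed = 3)
  p2 <- makePhantomPair(cfg, "CN", subject_seed = 3)
  expect_identical(volData(p1@a), volData(p2@a))
  expect_identical(volData(p1@b), volData(p2@b))
  p3 <- makePhantomPair(cfg, "CN", subject_seed = 4)
  expect_false(identical(volData(p1@a), volData(p3@a)))
  for (p in list(p1, p3)) {
    expect_gte(min(volData(p@a)), 0); expect_lte(max(volData(p@a)), 1)
    expect_gte(min(volData(p@b)), 0); expect_lte(max(volData(p@b)), 1)
  }
  expect_true(validObject(p1))
})

test_that("noise-free B is exactly the power-law map of A over the brain", {
  cfg <- tinyCfg(mapping_gamma = 2)
  p <- makePhantomPair(cfg, "CN", subject_seed = 1)
  gt <- groundTruthMap(p@a, p@masks, cfg)
  expect_equal(volData(p@b), volData(gt), tolerance = 1e-12)
  # gamma = 1 reduces to the identity inside the brain mask
  cfg1 <- tinyCfg(mapping_gamma = 1)
  p1 <- makePhantomPair(cfg1, "CN", subject_seed = 1)
  br <- p1@masks$brain
  expect_equal(volData(p1@b)[br], volData(p1@a)[br], tolerance = 1e-12)
  # direct evaluation: 0.5 inside the brain maps to 0.25 at gamma 2
  a <- brainVolume(array(0.5, c(16, 16, 16)))
  g <- groundTruthMap(a, list(brain = array(TRUE, c(16, 16, 16))), cfg)
  expect_equal(g@data[3, 3, 3], 0.25)
  # constant-zero brain maps to zero
  g0 <- groundTruthMap(brainVolume(array(0, c(16, 16, 16))),
                       list(brain = array(TRUE, c(16, 16, 16))), cfg)
  expect_true(all(g0@data == 0))
})

test_that("skull voxels are informative in A and identically zero in B", {
  p <- makePhantomPair(tinyCfg(), "CN", 2)
  sk <- p@masks$skull
  expect_gt(sum(sk), 0)
  expect_true(all(volData(p@b)[sk] == 0))
  expect_true(all(volData(p@a)[sk] > 0.5))
  expect_false(any(p@masks$brain & sk))
})

test_that("the disease effect dims the ROI of B by exactly (1 - effect)", {
  cfg <- tinyCfg(effect_size = 0.5)
  cn <- makePhantomPair(cfg, "CN", subject_seed = 7)
  ad <- makePhantomPair(cfg, "AD", subject_seed = 7)
  roi <- cn@masks$roi
  expect_equal(mean(volData(ad@b)[roi]), 0.5 * mean(volData(cn@b)[roi]),
               tolerance = 1e-12)
  # monotone: noise-free ROI mean strictly decreases in effect_size
  means <- sapply(c(0, 0.15, 0.3, 0.5), function(e) {
    p <- makePhantomPair(tinyCfg(effect_size = e), "AD", subject_seed = 7)
    mean(volData(p@b)[p@masks$roi])
  })
  expect_true(all(diff(means) < 0))
  # the A-side blob shrinks: AD has less blob mass in the ROI than CN
  expect_lt(mean(volData(ad@a)[roi]), mean(volData(cn@a)[roi]))
})

test_that("cohorts are balanced, subject-structured and reproducible", {
  cfg <- tinyCfg()
  co <- makeCohort(cfg, n_per_class = 2)
  expect_equal(nSamples(co), 4L)
  expect_equal(as.vector(table(sampleLabels(co))), c(2L, 2L))
  expect_equal(anyDuplicated(subjectIds(co)), 0L)
  # repeat visits share a subject id but not acquisition noise
  co2 <- makeCohort(tinyCfg(noise_sd = 0.05), 1, images_per_subject = 2)
  expect_equal(nSamples(co2), 4L)
  expect_equal(sum(duplicated(subjectIds(co2))), 2L)
  s1 <- getSample(co2, 1); s2 <- getSample(co2, 2)
  expect_identical(volData(s1@a), volData(s2@a))
  expect_false(identical(volData(s1@b), volData(s2@b)))
  # noise-free cohorts regenerate identically
  r1 <- makeCohort(cfg, 1)
  r2 <- makeCohort(cfg, 1)
  expect_identical(volData(getSample(r1, 1)@b), volData(getSample(r2, 1)@b))
})

test_that("averaging 16 repeats cuts acquisition variance about 16-fold", {
  cfg1 <- tinyCfg(noise_sd = 0.05, n_repeats_B = 1)
  cfg16 <- tinyCfg(noise_sd = 0.05, n_repeats_B = 16)
  gen <- function(cfg, r) volData(makePhantomPair(cfg, "CN", 1,
                                                  image_index = r)@b)
  reps1 <- sapply(1:20, gen, cfg = cfg1)
  reps16 <- sapply(1:20, gen, cfg = cfg16)
  # restrict to mid-range voxels where [0,1] truncation is negligible
  clean <- volData(makePhantomPair(tinyCfg(), "CN", 1)@b)
  sel <- clean > 0.2 & clean < 0.8
  v1 <- mean(apply(reps1[sel, ], 1, var))
  v16 <- mean(apply(reps16[sel, ], 1, var))
  expect_gt(v1 / v16, 12)
  expect_lt(v1 / v16, 21)
})

test_that("modality dropping is subject-level, seeded and exact in count", {
  co <- makeCohort(tinyCfg(), n_per_class = 5, images_per_subject = 2)
  expect_identical(dropModality(co, 0), co)
  d1 <- dropModality(co, 1)
  expect_true(all(sapply(d1@samples, function(s) is.null(s@b))))
  dh <- dropModality(co, 0.5, seed = 3)
  missing_subj <- unique(subjectIds(dh)[sapply(dh@samples,
                                               function(s) is.null(s@b))])
  expect_length(missing_subj, 5L)
  # no subject is partially dropped
  for (id in missing_subj) {
    idx <- which(subjectIds(dh) == id)
    expect_true(all(sapply(dh@samples[idx], function(s) is.null(s@b))))
  }
  dh2 <- dropModality(co, 0.5, seed = 3)
  expect_identical(sapply(dh@samples, function(s) is.null(s@b)),
                   sapply(dh2@samples, function(s) is.null(s@b)))
})

test_that("cohort round trip through NIfTI + manifest preserves structure", {
  co <- makeCohort(tinyCfg(noise_sd = 0.02), n_per_class = 2)
  co <- dropModality(co, 0.25, seed = 1)
  dir <- tempfile()
  writeCohort(co, dir)
  rd <- readCohort(dir)
  expect_equal(nSamples(rd), nSamples(co))
  expect_equal(subjectIds(rd), subjectIds(co))
  expect_equal(sampleLabels(rd), sampleLabels(co))
  expect_equal(sapply(rd@samples, function(s) is.null(s@b)),
               sapply(co@samples, function(s) is.null(s@b)))
  i <- which(!sapply(co@samples, function(s) is.null(s@b)))[1]
  expect_equal(volData(getSample(rd, i)@b), volData(getSample(co, i)@b),
               tolerance = 1e-6)   # float32 on disk
  expect_equal(getSample(rd, 1)@roiCenter, getSample(co, 1)@roiCenter)
  unlink(dir, recursive = TRUE)
})
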