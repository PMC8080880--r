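test_that("modality fusion stacks channels stably", {
  a <- randVol(c(8, 8, 16), seed = 1)
  b <- randVol(c(8, 8, 16), seed = 2)
  t4 <- fuseModalities(a, b)
  expect_identical(dim(t4), c(8L, 8L, 16L, 2L))
  expect_identical(t4[, , , 1], volData(a))
  expect_identical(t4[, , , 2], volData(b))
  expect_error(fuseModalities(a, randVol(c(4, 4, 4))), "shape mismatch")
})

test_that("the built classifier realises the printed architecture", {
  set.seed(1)
  model <- buildClassifier(classifierSpec(), c(96, 96, 48))
  ii <- introspectClassifier(model)
  expect_identical(ii$conv_kernels, c(1L, 5L, 9L, 5L))
  expect_identical(ii$conv_channels, c(4L, 32L, 64L, 64L))
  expect_identical(ii$fc_sizes, c(512L, 2L))
  expect_identical(ii$norm, "instance")
  expect_identical(ii$in_channels, 2L)
  # no spatial downsampling before the first convolution: every conv has
  # stride 1 and pooling only follows a convolution
  expect_true(all(ii$conv_strides == 1L))
  expect_identical(model$net[[1]]$type, "conv3")
  expect_gt(ii$n_params, 1e6)
  expect_error(buildClassifier(classifierSpec(), c(30, 30, 30)),
               "divisible by 16")
})

test_that("forward passes are softmax-normalised for 1- and 2-channel input", {
  set.seed(2)
  m2 <- buildClassifier(classifierSpec(2L), c(32, 32, 16))
  x2 <- array(runif(32 * 32 * 16 * 2), c(32, 32, 16, 2))
  p <- classifierForward(m2, x2)
  expect_length(p, 2L)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))
  m1 <- buildClassifier(classifierSpec(1L), c(32, 32, 16))
  p1 <- classifierForward(m1, array(runif(32 * 32 * 16), c(32, 32, 16)))
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_error(classifierForward(m1, x2), "channels")
})

test_that("subject-level splits hit the 7/2/1 example and never leak", {
  co <- makeCohort(tinyCfg(), n_per_class = 5, images_per_subject = 2)
  sp <- splitDataset(co, splitSpec(seed = 3))
  n_subj <- function(x) length(unique(subjectIds(x)))
  expect_equal(c(n_subj(sp$train), n_subj(sp$val), n_subj(sp$test)),
               c(7L, 2L, 1L))
  # partition: no subject in two parts, union is the cohort
  ids <- lapply(sp, function(x) unique(subjectIds(x)))
  expect_length(Reduce(intersect, ids), 0L)
  expect_setequal(unlist(ids), unique(subjectIds(co)))
  # repeat images of a subject travel together
  for (part in sp)
    for (id in unique(subjectIds(part)))
      expect_equal(sum(subjectIds(part) == id), 2L)
  # deterministic given the seed
  sp2 <- splitDataset(co, splitSpec(seed = 3))
  expect_identical(lapply(sp, subjectIds), lapply(sp2, subjectIds))
  sp3 <- splitDataset(co, splitSpec(seed = 4))
  expect_false(identical(subjectIds(sp$train), subjectIds(sp3$train)))
  expect_error(splitDataset(new("Cohort", samples = list(),
                                subjectIds = character()), splitSpec()),
               "subjects")
})

test_that("stratified splits keep both classes in every sizeable part", {
  co <- makeCohort(tinyCfg(), n_per_class = 10)
  for (seed in 1:5) {
    sp <- splitDataset(co, splitSpec(ratios = c(0.6, 0.1, 0.3), seed = seed))
    expect_setequal(unique(sampleLabels(sp$train)), c("CN", "AD"))
    expect_setequal(unique(sampleLabels(sp$test)), c("CN", "AD"))
  }
})

test_that("classifier training rejects single-class data and is seeded", {
  co <- makeCohort(tinyCfg(), n_per_class = 3)
  onlyCN <- new("Cohort",
                samples = co@samples[sampleLabels(co) == "CN"],
                subjectIds = subjectIds(co)[sampleLabels(co) == "CN"])
  expect_error(trainClassifier(onlyCN, co, classifierSpec()), "both classes")
  cfg <- classifierTrainConfig(iterations = 2L, seed = 8L)
  m1 <- trainClassifier(co, onlyCN, cfg = cfg)
  m2 <- trainClassifier(co, onlyCN, cfg = cfg)
  expect_identical(m1$params, m2$params)
  expect_equal(nrow(m1$history), 2L)
})

test_that("the CNN separates a strong two-modality phantom effect", {
  cfg <- phantomConfig(shape = c(32, 32, 16), noise_sd = 0.02,
                       effect_size = 0.6, seed = 50)
  co <- makeCohort(cfg, n_per_class = 8)
  sp <- splitDataset(co, splitSpec(ratios = c(0.6, 0.1, 0.3), seed = 2))
  model <- trainClassifier(sp$train, sp$val,
                           cfg = classifierTrainConfig(iterations = 50L,
                                                       seed = 3L))
  # smoothed training loss decreases
  h <- model$history$loss
  expect_lt(mean(tail(h, 10)), mean(head(h, 10)))
  sc <- predictClassifier(model, sp$test)
  rep <- classificationMetrics(sampleLabels(sp$test), sc)
  expect_gte(rep$auc, 0.9)
})

test_that("cross-validation aggregates per-fold reports coherently", {
  cfg <- phantomConfig(shape = c(32, 32, 16), noise_sd = 0.02,
                       effect_size = 0.6, seed = 51)
  co <- makeCohort(cfg, n_per_class = 6)
  cv <- crossValidate(co, classifierSpec(),
                      splitSpec(ratios = c(0.6, 0.1, 0.3), seed = 1,
                                n_folds = 2),
                      classifierTrainConfig(iterations = 20L))
  expect_length(cv$folds, 2L)
  accs <- sapply(cv$folds, function(f) f$report$acc)
  agg <- cv$aggregate
  expect_equal(agg$mean[agg$metric == "acc"], mean(accs))
  expect_gte(agg$mean[agg$metric == "acc"], min(accs))
  expect_lte(agg$mean[agg$metric == "acc"], max(accs))
  expect_error(crossValidate(new("Cohort", samples = co@samples[1:2],
                                 subjectIds = subjectIds(co)[1:2]),
                             classifierSpec(), splitSpec()), "subjects")
})

test_that("imputation conditions build the cohorts they claim", {
  eng <- asNamespace("revsyn3d")
  expect_identical(eng$.parseCondition("missing_50"),
                   list(kind = "missing", fraction = 0.5))
  expect_identical(eng$.parseCondition("mixed_25"),
                   list(kind = "mixed", fraction = 0.25))
  expect_error(eng$.parseCondition("bogus"), "unknown imputation condition")
  co <- makeCohort(phantomConfig(shape = c(16, 16, 16), noise_sd = 0,
                                 effect_size = 0.4, seed = 9), 5)
  ck <- trainSynthesis(co, trainConfig(iterations = 1L, batch_size = 2L),
                       core_width = 4L, core_hidden = 2L)
  dropped <- dropModality(co, 0.5, seed = 99)
  n_missing <- sum(sapply(dropped@samples, function(s) is.null(s@b)))
  expect_equal(n_missing, 5L)   # exactly 50% of 10 subjects
  mixed <- synthesizeMissing(dropped, ck, "a_to_b")
  expect_equal(sum(sapply(mixed@samples, function(s) s@bSynthetic)), 5L)
})
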