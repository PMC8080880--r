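# The four-layer 3D CNN diagnosis model with channel-level modality fusion,
# subject-level data splitting, repeated cross-validation and the
# missing-vs-synthetic imputation experiment harness.
#
# Architecture: four convolution layers with cubic kernels 1, 5, 9, 5 and
# channels 4, 32, 64, 64, each followed by instance norm, ReLU and 2x2x2
# max pooling; then two fully connected layers (512 -> 2) and a softmax.
# The tiny first kernel avoids early spatial downsampling.  Feature maps
# are channel-last: a fused two-modality input has dim (X, Y, Z, 2).

#' Classifier architecture specification
#'
#' @param in_channels 1 (single modality) or 2 (fused modalities).
#' @param conv_kernels cubic kernel edge lengths of the 4 conv layers.
#' @param conv_channels output channels of the 4 conv layers.
#' @param fc_sizes widths of the two fully connected layers; the final
#'   width is the number of classes (2).
#' @return A `ClassifierSpec` list.
#' @export
classifierSpec <- function(in_channels = 2L, conv_kernels = c(1L, 5L, 9L, 5L),
                           conv_channels = c(4L, 32L, 64L, 64L),
                           fc_sizes = c(512L, 2L)) {
  stopifnot(in_channels %in% c(1L, 2L), length(conv_kernels) == 4L,
            length(conv_channels) == 4L, length(fc_sizes) == 2L,
            all(conv_kernels %% 2L == 1L))
  structure(list(in_channels = as.integer(in_channels),
                 conv_kernels = as.integer(conv_kernels),
                 conv_channels = as.integer(conv_channels),
                 fc_sizes = as.integer(fc_sizes), norm = "instance"),
            class = "ClassifierSpec")
}

#' Default training configuration for the diagnosis CNN
#'
#' Adam at learning rate 3e-4 with the usual moment decays, minibatches of
#' 8 and 60 updates; on separable phantoms the model converges well within
#' this budget.
#'
#' @param iterations minibatch updates.
#' @param seed RNG seed.
#' @return A [trainConfig()].
#' @export
classifierTrainConfig <- function(iterations = 60L, seed = 1L)
  trainConfig(learning_rate = 3e-4, adam_betas = c(0.9, 0.999),
              batch_size = 8L, iterations = iterations, seed = seed)

#' Stack two modalities as a two-channel tensor
#'
#' Channel-level fusion of a paired structural/functional volume: channel 1
#' holds `a`, channel 2 holds `b`; unstacking returns the originals.
#'
#' @param a,b volumes ([BrainVolume-class] or 3D arrays) of identical shape.
#' @return A 4D array of dim `(X, Y, Z, 2)`.
#' @export
fuseModalities <- function(a, b) {
  ra <- .metricArr(a); rb <- .metricArr(b)
  .checkSameShape(ra, rb)
  out <- array(0, dim = c(dim(ra), 2L))
  out[, , , 1L] <- ra
  out[, , , 2L] <- rb
  out
}

#' Build the diagnosis CNN
#'
#' Parameters are drawn from the current RNG stream; the fully connected
#' input width is derived from `input_shape` after the four pooling stages,
#' so each spatial extent must be divisible by 16.
#'
#' @param spec a [classifierSpec()].
#' @param input_shape spatial input shape, default `c(96, 96, 48)`.
#' @return A `ClassifierModel` list with `net`, `params`, `spec`.
#' @export
buildClassifier <- function(spec = classifierSpec(),
                            input_shape = c(96L, 96L, 48L)) {
  stopifnot(inherits(spec, "ClassifierSpec"))
  input_shape <- as.integer(input_shape)
  if (any(input_shape %% 16L != 0L))
    stop("input_shape components must be divisible by 16 (four pool stages)")
  cin <- spec$in_channels
  net <- list()
  for (i in 1:4) {
    net <- c(net, list(nnConv3(cin, spec$conv_channels[i],
                               k = spec$conv_kernels[i]),
                       nnINorm(), nnReLU(), nnPool2()))
    cin <- spec$conv_channels[i]
  }
  nflat <- prod(input_shape %/% 16L) * cin
  net <- c(net, list(nnFlatten(), nnFC(nflat, spec$fc_sizes[1]), nnReLU(),
                     nnFC(spec$fc_sizes[1], spec$fc_sizes[2])))
  params <- nnInit(net)
  # zero-start the final layer: logits begin at chance, so early training
  # fits the discriminative direction rather than chasing a class bias
  params[[length(params)]]$w[] <- 0
  params[[length(params)]]$b[] <- 0
  structure(list(spec = spec, net = net, params = params,
                 input_shape = input_shape),
            class = "ClassifierModel")
}

#' Introspect the built classifier
#'
#' Reports the realised architecture: per-layer kernel sizes and channel
#' counts, normalisation, pooling, fully connected widths and the total
#' trainable parameter count.
#'
#' @param model a [buildClassifier()] model.
#' @return A list describing the architecture.
#' @export
introspectClassifier <- function(model) {
  stopifnot(inherits(model, "ClassifierModel"))
  convs <- Filter(function(l) l$type == "conv3", model$net)
  fcs <- Filter(function(l) l$type == "fc", model$net)
  list(conv_kernels = vapply(convs, `[[`, integer(1), "k"),
       conv_channels = vapply(convs, `[[`, integer(1), "cout"),
       conv_strides = vapply(convs, `[[`, integer(1), "stride"),
       norm = model$spec$norm,
       pool = "2x2x2 max after every conv",
       fc_sizes = vapply(fcs, `[[`, integer(1), "nout"),
       in_channels = model$spec$in_channels,
       n_params = paramCount(model$params))
}

.softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Class probabilities for one input tensor
#'
#' @param model a `ClassifierModel`.
#' @param x input tensor `(X, Y, Z, C)` matching the model's channels, or a
#'   3D array for single-modality models.
#' @param single use the single-precision convolution path.
#' @return Probability vector `(p_CN, p_AD)` summing to 1.
#' @export
classifierForward <- function(model, x, single = TRUE) {
  x <- .asTensorC(x, model$spec$in_channels)
  .softmax(nnForward(model$net, model$params, x, single)$out)
}

.asTensorC <- function(x, channels) {
  if (is(x, "BrainVolume")) x <- x@data
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  if (dim(x)[4L] != channels)
    stop(sprintf("input has %d channels, model expects %d", dim(x)[4L],
                 channels))
  x
}

# sample -> input tensor; a missing modality-B channel is zero-filled
.sampleTensor <- function(s, in_channels) {
  if (in_channels == 1L) {
    x <- s@a@data
    dim(x) <- c(dim(x), 1L)
    x
  } else {
    b <- if (is.null(s@b)) array(0, dim = dim(s@a@data)) else s@b@data
    fuseModalities(s@a@data, b)
  }
}

.labelIndex <- function(label) if (label == "AD") 2L else 1L

#' Split specification for subject-level partitions
#'
#' @param ratios train/validation/test fractions summing to 1, default
#'   `(0.7, 0.2, 0.1)`.
#' @param seed base RNG seed.
#' @param n_folds number of repeated splits for cross-validation.
#' @return A `SplitSpec` list.
#' @export
splitSpec <- function(ratios = c(0.7, 0.2, 0.1), seed = 1L, n_folds = 10L) {
  stopifnot(length(ratios) == 3L, all(ratios >= 0),
            abs(sum(ratios) - 1) < 1e-9, n_folds >= 1L)
  structure(list(ratios = ratios, seed = as.integer(seed),
                 n_folds = as.integer(n_folds)),
            class = "SplitSpec")
}

# largest-remainder apportionment of n into parts ~ ratios
.apportion <- function(n, ratios) {
  raw <- n * ratios
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Subject-level train/validation/test split
#'
#' Partitions subjects (never individual samples, so repeat images of one
#' subject cannot leak across parts), stratified by class through
#' interleaving, deterministically from `s$seed`.
#'
#' @param cohort a [Cohort-class].
#' @param s a [splitSpec()].
#' @return `list(train =, val =, test =)` of [Cohort-class] objects.
#' @export
splitDataset <- function(cohort, s = splitSpec()) {
  stopifnot(is(cohort, "Cohort"), inherits(s, "SplitSpec"))
  subj <- unique(cohort@subjectIds)
  n_parts <- sum(s$ratios > 0)
  if (length(subj) < n_parts)
    stop(sprintf("only %d subjects for %d split parts", length(subj), n_parts))
  subj_label <- vapply(subj, function(id)
    cohort@samples[[match(id, cohort@subjectIds)]]@label, character(1))
  shuffled <- .withSeed(s$seed, {
    by_class <- split(subj, subj_label)
    by_class <- lapply(by_class, sample)
    # interleave classes so small parts stay stratified
    mx <- max(lengths(by_class))
    inter <- unlist(lapply(seq_len(mx), function(i)
      unlist(lapply(by_class, function(v) if (i <= length(v)) v[i]))),
      use.names = FALSE)
    inter
  })
  counts <- .apportion(length(subj), s$ratios)
  assign_part <- rep(c("train", "val", "test"), counts)
  parts <- split(shuffled, factor(assign_part, levels = c("train", "val",
                                                          "test")))
  sub <- function(ids) {
    keep <- cohort@subjectIds %in% ids
    new("Cohort", samples = cohort@samples[keep],
        subjectIds = cohort@subjectIds[keep])
  }
  list(train = sub(parts$train), val = sub(parts$val), test = sub(parts$test))
}

#' Train the diagnosis CNN
#'
#' Cross-entropy training with Adam on subject-level train data; the
#' parameters with the best validation accuracy (validation loss breaking
#' ties) are returned.  Deterministic on CPU given `cfg$seed`.
#'
#' @param train,val [Cohort-class] training and validation sets (`val` may
#'   be empty, in which case the final parameters are returned).
#' @param spec a [classifierSpec()].
#' @param cfg a [trainConfig()]; `iterations` counts minibatch updates.
#' @param verbose print validation accuracy at each evaluation.
#' @return A `ClassifierModel` with an added `history` element.
#' @export
trainClassifier <- function(train, val, spec = classifierSpec(),
                            cfg = classifierTrainConfig(),
                            verbose = FALSE) {
  stopifnot(is(train, "Cohort"))
  labs <- sampleLabels(train)
  if (length(unique(labs)) < 2L)
    stop("training set must contain both classes")
  .withSeed(cfg$seed, {
    model <- buildClassifier(spec, dim(train@samples[[1]]@a@data))
    opt <- adamInit(model$params)
    xs <- lapply(train@samples, .sampleTensor, in_channels = spec$in_channels)
    ys <- vapply(train@samples, function(s) .labelIndex(s@label), integer(1))
    n <- length(xs)
    i_pos <- which(ys == 2L); i_neg <- which(ys == 1L)
    half <- max(1L, cfg$batch_size %/% 2L)
    eval_every <- max(1L, ceiling(n / cfg$batch_size))
    best <- list(acc = -1, loss = Inf, params = model$params)
    hist <- data.frame(step = integer(), loss = numeric())
    for (step in seq_len(cfg$iterations)) {
      # class-balanced minibatches keep the softmax prior centred
      idx <- c(sample(i_pos, min(half, length(i_pos)),
                      replace = length(i_pos) < half),
               sample(i_neg, min(half, length(i_neg)),
                      replace = length(i_neg) < half))
      grads <- NULL
      loss <- 0
      for (i in idx) {
        fw <- nnForward(model$net, model$params, xs[[i]], TRUE)
        p <- .softmax(fw$out)
        loss <- loss - log(max(p[ys[i]], 1e-12))
        dz <- p
        dz[ys[i]] <- dz[ys[i]] - 1
        bw <- nnBackward(model$net, model$params, fw$caches, dz, TRUE)
        grads <- gradsAdd(grads, bw$grads)
      }
      grads <- gradsScale(grads, 1 / length(idx))
      r <- adamStep(model$params, grads, opt, cfg$learning_rate,
                    cfg$adam_betas)
      model$params <- r$params; opt <- r$state
      hist <- rbind(hist, data.frame(step = step, loss = loss / length(idx)))
      if (nSamples(val) > 0L &&
          (step %% eval_every == 0L || step == cfg$iterations)) {
        ev <- .evalClassifier(model, val)
        if (ev$acc > best$acc ||
            (ev$acc == best$acc && ev$loss < best$loss)) {
          best <- list(acc = ev$acc, loss = ev$loss, params = model$params)
        }
        if (verbose)
          message(sprintf("step %3d  train loss %.4f  val acc %.3f", step,
                          loss / length(idx), ev$acc))
      }
    }
    if (nSamples(val) > 0L) model$params <- best$params
    model$history <- hist
    model
  })
}

.evalClassifier <- function(model, cohort) {
  sc <- predictClassifier(model, cohort)
  y <- vapply(cohort@samples, function(s) .labelIndex(s@label), integer(1))
  acc <- mean((sc >= 0.5) == (y == 2L))
  loss <- -mean(log(pmax(ifelse(y == 2L, sc, 1 - sc), 1e-12)))
  list(acc = acc, loss = loss)
}

#' Positive-class (disease) probability for every sample of a cohort
#'
#' @param model a trained `ClassifierModel`.
#' @param cohort a [Cohort-class].
#' @return Numeric vector of P(AD) scores.
#' @export
predictClassifier <- function(model, cohort) {
  vapply(cohort@samples, function(s)
    classifierForward(model, .sampleTensor(s, model$spec$in_channels))[2L],
    numeric(1))
}

#' Repeated subject-level cross-validation
#'
#' Runs `s$n_folds` repetitions of a seeded subject-level
#' train/validation/test split (fold-varied seeds), trains on each training
#' part and evaluates ACC/SEN/SPE/AUC on the held-out test part.
#'
#' @param cohort a [Cohort-class].
#' @param spec a [classifierSpec()].
#' @param s a [splitSpec()]; fold `k` splits with seed `s$seed + k - 1`.
#' @param cfg a [trainConfig()] for the per-fold training runs.
#' @return `list(folds =, aggregate =)`: per-fold `ClassificationReport`s
#'   with scores, and a mean/sd summary data frame.
#' @export
crossValidate <- function(cohort, spec = classifierSpec(), s = splitSpec(),
                          cfg = classifierTrainConfig()) {
  n_subj <- length(unique(cohort@subjectIds))
  if (n_subj < sum(s$ratios > 0))
    stop("not enough subjects for cross-validation")
  folds <- lapply(seq_len(s$n_folds), function(k) {
    sk <- s; sk$seed <- s$seed + k - 1L
    parts <- splitDataset(cohort, sk)
    ck <- cfg; ck$seed <- cfg$seed + 1000L * k
    model <- trainClassifier(parts$train, parts$val, spec, ck)
    scores <- predictClassifier(model, parts$test)
    labels <- sampleLabels(parts$test)
    rep <- suppressWarnings(classificationMetrics(labels, scores))
    list(fold = k, report = rep, scores = scores, labels = labels)
  })
  mets <- t(vapply(folds, function(f)
    unlist(f$report[c("acc", "sen", "spe", "auc")]), numeric(4)))
  aggregate <- data.frame(
    metric = colnames(mets),
    mean = colMeans(mets, na.rm = TRUE),
    sd = apply(mets, 2, stats::sd, na.rm = TRUE), row.names = NULL)
  list(folds = folds, aggregate = aggregate)
}

.parseCondition <- function(cond) {
  if (cond == "real") return(list(kind = "real"))
  if (cond == "all_synthetic") return(list(kind = "all_synthetic"))
  m <- regmatches(cond, regexec("^(missing|mixed)_([0-9]+)$", cond))[[1]]
  if (length(m) == 3L)
    return(list(kind = m[2], fraction = as.numeric(m[3]) / 100))
  stop("unknown imputation condition: ", cond)
}

#' Missing-data versus synthetic-data diagnosis experiment
#'
#' Reproduces the structure of the imputation tables: for each condition a
#' cohort variant is built, cross-validated with the multimodal classifier,
#' and summarised as one row of metrics.
#'
#' Conditions: `"real"` (all paired data), `"missing_k"` (modality B
#' removed for k% of subjects and the channel zero-filled),
#' `"mixed_k"` (the removed k% imputed by the generator), and
#' `"all_synthetic"` (every B replaced by `G(a)`).
#'
#' @param cohort fully paired [Cohort-class].
#' @param ckpt a `SynthesisCheckpoint` for the synthetic arms.
#' @param spec a [classifierSpec()].
#' @param s a [splitSpec()].
#' @param cfg a [trainConfig()] for the classifier runs.
#' @param conditions character vector of condition names.
#' @param drop_seed seed of the subject subset whose B is removed.
#' @return A data frame with one row per condition x metric summary plus a
#'   `details` attribute holding the full cross-validation objects.
#' @export
runImputationExperiment <- function(cohort, ckpt, spec = classifierSpec(),
                                    s = splitSpec(),
                                    cfg = classifierTrainConfig(),
                                    conditions = c("real", "missing_50",
                                                   "mixed_50",
                                                   "all_synthetic"),
                                    drop_seed = 99L) {
  stopifnot(is(cohort, "Cohort"))
  details <- list()
  rows <- list()
  for (cond in conditions) {
    pc <- .parseCondition(cond)
    variant <- switch(pc$kind,
      real = cohort,
      missing = dropModality(cohort, pc$fraction, seed = drop_seed),
      mixed = synthesizeMissing(dropModality(cohort, pc$fraction,
                                             seed = drop_seed), ckpt,
                                "a_to_b"),
      all_synthetic = synthesizeMissing(cohort, ckpt, "a_to_b",
                                        overwrite_all = TRUE))
    cv <- crossValidate(variant, spec, s, cfg)
    details[[cond]] <- cv
    agg <- cv$aggregate
    rows[[cond]] <- data.frame(condition = cond,
                               metric = agg$metric, mean = agg$mean,
                               sd = agg$sd)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- details
  out
}
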