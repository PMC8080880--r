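# Adversarial training of the synthesis model, checkpointing, imputation of
# missing modalities, and image-quality evaluation of synthetic volumes.

#' Training configuration
#'
#' @param learning_rate Adam learning rate, default 2e-4.
#' @param adam_betas Adam moment decay pair; default `(0.5, 0.999)`, the
#'   GAN-training convention.
#' @param batch_size samples per update, default 4.
#' @param iterations number of optimisation iterations (one D1/D2/generator
#'   update each), default 200.
#' @param lambda_cyc cycle-consistency weight, default 10.
#' @param seed seed governing initialisation and batch shuffling; CPU runs
#'   are fully reproducible from it.
#' @return A `TrainConfig` list.
#' @export
trainConfig <- function(learning_rate = 2e-4, adam_betas = c(0.5, 0.999),
                        batch_size = 4L, iterations = 200L, lambda_cyc = 10,
                        seed = 1L) {
  stopifnot(learning_rate > 0, iterations >= 1L, batch_size >= 1L,
            all(adam_betas >= 0), all(adam_betas < 1), lambda_cyc >= 0)
  structure(list(learning_rate = learning_rate, adam_betas = adam_betas,
                 batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 lambda_cyc = lambda_cyc, seed = as.integer(seed)),
            class = "TrainConfig")
}

# L1 loss gradient
.l1Grad <- function(x, target) sign(x - target) / length(x)

# one LSGAN discriminator update: real -> 1, fake -> 0
.discStep <- function(m, dname, real, fake, single) {
  grads <- NULL
  loss <- 0
  for (i in seq_along(real)) {
    fr <- nnForward(m$nets[[dname]], m$params[[dname]], real[[i]], single)
    ff <- nnForward(m$nets[[dname]], m$params[[dname]], fake[[i]], single)
    loss <- loss + mean((fr$out - 1)^2) + mean(ff$out^2)
    gr <- nnBackward(m$nets[[dname]], m$params[[dname]], fr$caches,
                     2 * (fr$out - 1) / length(fr$out), single)$grads
    gf <- nnBackward(m$nets[[dname]], m$params[[dname]], ff$caches,
                     2 * ff$out / length(ff$out), single)$grads
    grads <- gradsAdd(grads, gradsAdd(gr, gf))
  }
  list(grads = gradsScale(grads, 1 / length(real)), loss = loss / length(real))
}

#' Train the bidirectional synthesis model
#'
#' Alternating least-squares GAN updates: D1 (domain B) and D2 (domain A)
#' on real versus synthetic volumes, then the shared generator on the
#' combined objective `gan_ab + gan_ba + lambda * cyc`.  Because the core
#' is weight-shared, every generator update trains both mapping directions
#' at once.  Samples missing modality B are excluded.  All randomness
#' (initialisation, batch sampling) derives from `cfg$seed`.
#'
#' @param cohort a [Cohort-class] with at least one fully paired sample.
#' @param cfg a [trainConfig()].
#' @param model optionally a pre-built [synthesisModel()] to continue
#'   training; by default a fresh model is initialised under `cfg$seed`.
#' @param core_hidden hidden width of the coupling subnetworks when a fresh
#'   model is built.
#' @param core_width feature-space width of a fresh model, default 16.
#' @param verbose print the loss every 50 iterations.
#' @return A `SynthesisCheckpoint`: model, config, iteration counter and
#'   per-iteration loss history (`gan_ab`, `gan_ba`, `cyc`, `total`,
#'   `d1`, `d2`).
#' @export
trainSynthesis <- function(cohort, cfg = trainConfig(), model = NULL,
                           core_width = 16L, core_hidden = 8L,
                           verbose = FALSE) {
  stopifnot(is(cohort, "Cohort"), inherits(cfg, "TrainConfig"))
  paired <- Filter(function(s) !is.null(s@b), cohort@samples)
  if (length(paired) == 0L)
    stop("no fully paired samples available for synthesis training")
  .withSeed(cfg$seed, {
    if (is.null(model))
      model <- synthesisModel(core_width = core_width,
                              core_hidden = core_hidden)
    m <- model
    gen_names <- c("enc_a", "enc_b", "dec_a", "dec_b", "core")
    opt_g <- adamInit(m$params[gen_names])
    opt_d1 <- adamInit(m$params$d1)
    opt_d2 <- adamInit(m$params$d2)
    hist <- matrix(NA_real_, cfg$iterations, 6,
                   dimnames = list(NULL, c("gan_ab", "gan_ba", "cyc",
                                           "total", "d1", "d2")))
    tens <- lapply(paired, function(s)
      list(a = toModelRange(.asTensor4(s@a@data)),
           b = toModelRange(.asTensor4(s@b@data))))

    for (it in seq_len(cfg$iterations)) {
      idx <- sample.int(length(tens), min(cfg$batch_size, length(tens)))
      batch <- tens[idx]
      # generator forward passes (fakes reused for the discriminator steps)
      fab <- lapply(batch, function(s) .genForwardFull(m, s$a, "ab"))
      fba <- lapply(batch, function(s) .genForwardFull(m, s$b, "ba"))
      fakes_b <- lapply(fab, `[[`, "out")
      fakes_a <- lapply(fba, `[[`, "out")

      # discriminator updates (synthetic volumes detached)
      s1 <- .discStep(m, "d1", lapply(batch, `[[`, "b"), fakes_b, TRUE)
      r <- adamStep(m$params$d1, s1$grads, opt_d1, cfg$learning_rate,
                    cfg$adam_betas)
      m$params$d1 <- r$params; opt_d1 <- r$state
      s2 <- .discStep(m, "d2", lapply(batch, `[[`, "a"), fakes_a, TRUE)
      r <- adamStep(m$params$d2, s2$grads, opt_d2, cfg$learning_rate,
                    cfg$adam_betas)
      m$params$d2 <- r$params; opt_d2 <- r$state

      # generator update against the freshly updated discriminators
      ggrads <- NULL
      gan_ab <- gan_ba <- cyc <- 0
      for (i in seq_along(batch)) {
        a <- batch[[i]]$a; b <- batch[[i]]$b
        rec_a <- .genForwardFull(m, fab[[i]]$out, "ba")
        rec_b <- .genForwardFull(m, fba[[i]]$out, "ab")
        f1 <- nnForward(m$nets$d1, m$params$d1, fab[[i]]$out, TRUE)
        f2 <- nnForward(m$nets$d2, m$params$d2, fba[[i]]$out, TRUE)
        gan_ab <- gan_ab + mean((f1$out - 1)^2)
        gan_ba <- gan_ba + mean((f2$out - 1)^2)
        cyc <- cyc + mean(abs(rec_a$out - a)) + mean(abs(rec_b$out - b))

        # cycle branches
        bra <- .genBackwardFull(m, rec_a,
                                cfg$lambda_cyc * .l1Grad(rec_a$out, a))
        brb <- .genBackwardFull(m, rec_b,
                                cfg$lambda_cyc * .l1Grad(rec_b$out, b))
        # adversarial branches (through the discriminators, params frozen)
        da <- nnBackward(m$nets$d1, m$params$d1, f1$caches,
                         2 * (f1$out - 1) / length(f1$out), TRUE)$dx
        db <- nnBackward(m$nets$d2, m$params$d2, f2$caches,
                         2 * (f2$out - 1) / length(f2$out), TRUE)$dx
        # first-leg passes receive cycle + adversarial gradients
        bab <- .genBackwardFull(m, fab[[i]], bra$dx + da)
        bba <- .genBackwardFull(m, fba[[i]], brb$dx + db)
        for (g in list(bra$grads, brb$grads, bab$grads, bba$grads))
          ggrads <- .genGradsAdd(ggrads, g)
      }
      nb <- length(batch)
      ggrads <- gradsScale(ggrads, 1 / nb)
      r <- adamStep(m$params[gen_names], ggrads, opt_g, cfg$learning_rate,
                    cfg$adam_betas)
      m$params[gen_names] <- r$params; opt_g <- r$state

      gan_ab <- gan_ab / nb; gan_ba <- gan_ba / nb; cyc <- cyc / nb
      hist[it, ] <- c(gan_ab, gan_ba, cyc,
                      gan_ab + gan_ba + cfg$lambda_cyc * cyc, s1$loss, s2$loss)
      if (verbose && it %% 50L == 0L)
        message(sprintf("iter %4d  total %.4f  cyc %.4f  d1 %.4f  d2 %.4f",
                        it, hist[it, "total"], cyc, s1$loss, s2$loss))
    }
    structure(list(model = m, cfg = cfg, iteration = cfg$iterations,
                   history = as.data.frame(hist)),
              class = "SynthesisCheckpoint")
  })
}

#' Save / load a synthesis checkpoint
#'
#' Reloading reproduces model outputs bit-identically on fixed input.
#'
#' @param ckpt a `SynthesisCheckpoint` from [trainSynthesis()].
#' @param path file path.
#' @return `loadCheckpoint` returns the checkpoint; `saveCheckpoint` the
#'   path, invisibly.
#' @export
saveCheckpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "SynthesisCheckpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ckpt <- readRDS(path)
  stopifnot(inherits(ckpt, "SynthesisCheckpoint"))
  ckpt
}

#' Impute missing modalities with the trained generator
#'
#' For `direction = "a_to_b"`, samples missing modality B get
#' `G(a)` mapped back to `[0, 1]` and are flagged as synthetic; complete
#' samples are untouched.  With `overwrite_all = TRUE` every B volume is
#' replaced by its synthetic counterpart (the "100% synthetic" experiment
#' arm).  `direction = "b_to_a"` with `overwrite_all = TRUE` replaces every
#' A volume by `G^{-1}(b)`; because the container requires modality A to be
#' present, B->A runs only as a full-replacement arm.
#'
#' @param cohort a [Cohort-class].
#' @param ckpt a `SynthesisCheckpoint`.
#' @param direction `"a_to_b"` or `"b_to_a"`.
#' @param overwrite_all replace the target modality for every sample, not
#'   just the missing ones.
#' @return The cohort with synthetic volumes in place, provenance flagged.
#' @export
synthesizeMissing <- function(cohort, ckpt, direction = c("a_to_b", "b_to_a"),
                              overwrite_all = FALSE) {
  stopifnot(is(cohort, "Cohort"), inherits(ckpt, "SynthesisCheckpoint"))
  direction <- match.arg(direction)
  m <- ckpt$model
  for (i in seq_along(cohort@samples)) {
    s <- cohort@samples[[i]]
    if (direction == "a_to_b") {
      if (!is.null(s@b) && !overwrite_all) next
      out <- generateAtoB(toModelRange(s@a@data), m)
      v <- brainVolume(array(fromModelRange(out), dim = dim(s@a@data)),
                       spacing = s@a@spacing, intensityRange = c(0, 1))
      s@b <- v
      s@bSynthetic <- TRUE
    } else {
      if (!overwrite_all)
        stop(paste0("sample ", i, ": modality A is always present in this ",
                    "container; B->A imputation runs only with ",
                    "overwrite_all = TRUE"))
      if (is.null(s@b))
        stop(sprintf("sample %d: source modality B missing, cannot impute A",
                     i))
      out <- generateBtoA(toModelRange(s@b@data), m)
      s@a <- brainVolume(array(fromModelRange(out), dim = dim(s@a@data)),
                         spacing = s@a@spacing, intensityRange = c(0, 1))
      s@aSynthetic <- TRUE
    }
    cohort@samples[[i]] <- s
  }
  cohort
}

#' Image-quality report for synthetic volumes
#'
#' Per-sample and mean RMSE, PSNR and SSIM of synthetic against real
#' volumes, with an optional per-region breakdown (e.g. brain vs skull) of
#' RMSE/PSNR/SSIM to probe which structures the mapping recovers.
#'
#' @param pairs list of `list(real =, synthetic =)` [BrainVolume-class]
#'   pairs (or plain arrays).
#' @param masks optional named list of logical region masks.
#' @param data_range dynamic range used for PSNR/SSIM, default 1 (unit-scaled
#'   volumes).
#' @return An `ImageQualityReport` list.
#' @export
evaluateSynthesis <- function(pairs, masks = NULL, data_range = 1) {
  if (!is.list(pairs) || length(pairs) == 0L)
    stop("pairs must be a non-empty list of real/synthetic volume pairs")
  getArr <- function(x) if (is(x, "BrainVolume")) x@data else x
  per <- lapply(pairs, function(p) {
    r <- getArr(p$real); s <- getArr(p$synthetic)
    if (!identical(dim(r), dim(s)))
      stop("shape mismatch between real and synthetic volume")
    c(rmse = rmse(r, s), psnr = psnr(r, s, data_range),
      ssim = ssim3d(r, s, data_range))
  })
  per <- do.call(rbind, per)
  rep <- list(per_sample = as.data.frame(per),
              rmse = mean(per[, "rmse"]), psnr = mean(per[, "psnr"]),
              ssim = mean(per[, "ssim"]), data_range = data_range)
  if (!is.null(masks)) {
    rep$per_region <- lapply(masks, function(mk) {
      vals <- lapply(pairs, function(p) {
        r <- getArr(p$real); s <- getArr(p$synthetic)
        ms <- mean((r[mk] - s[mk])^2)
        sm <- ssim3d(r, s, data_range, return_map = TRUE)
        c(rmse = sqrt(ms),
          psnr = if (ms == 0) Inf else 10 * log10(data_range^2 / ms),
          ssim = .maskedMapMean(sm, mk))
      })
      colMeans(do.call(rbind, vals))
    })
  }
  structure(rep, class = "ImageQualityReport")
}

#' @export
print.ImageQualityReport <- function(x, ...) {
  cat(sprintf("ImageQualityReport (%d pairs, data range %g)\n",
              nrow(x$per_sample), x$data_range))
  cat(sprintf("  RMSE %.4f   PSNR %.2f dB   SSIM %.4f\n", x$rmse, x$psnr,
              x$ssim))
  if (!is.null(x$per_region))
    for (nm in names(x$per_region)) {
      v <- x$per_region[[nm]]
      cat(sprintf("  [%s] RMSE %.4f  PSNR %.2f dB  SSIM %.4f\n", nm,
                  v["rmse"], v["psnr"], v["ssim"]))
    }
  invisible(x)
}
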