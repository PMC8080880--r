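# Paired-modality 3D phantom generator.  Emulates the structure of a paired
# T1-MRI / FDG-PET cohort: a smooth "brain" texture shared by both
# modalities, a bright skull shell present only in the structural modality,
# a ground-truth power-law intensity mapping from A to B over brain tissue,
# and a class-dependent effect that shrinks a hippocampus-like blob in A
# while dimming the corresponding region in B -- so the disease signature is
# carried by both modalities at once, like hippocampal atrophy.

# run expr with a private RNG seeded at `seed`, restoring the caller's stream
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

.mixSeed <- function(...) {
  v <- c(...)
  s <- 0
  for (x in v) s <- (s * 48271 + (as.double(x) %% 65536) * 631 + 17) %% 2147483629
  as.integer(s)
}

#' Phantom generator configuration
#'
#' Fixes the geometry and statistical structure of the paired phantoms.
#' Defaults describe the cohort the package's experiments are run on:
#' moderate acquisition noise, a class effect of 0.3, and a quadratic
#' ground-truth intensity mapping between modalities.
#'
#' @param shape integer triple, voxel grid (components >= 16).  96 x 96 x 48
#'   matches the hippocampal ROI crop; 32 x 32 x 16 is the desk-scale size.
#' @param noise_sd standard deviation of additive Gaussian acquisition noise
#'   on modality B (truncated to `[0, 1]`).
#' @param effect_size in `[0, 1]`: fractional shrinkage of the ROI blob in A
#'   and fractional intensity dimming of the ROI region in B for the
#'   disease class.
#' @param skull_intensity intensity of the skull shell in A (absent in B).
#' @param mapping_gamma exponent of the ground-truth A to B power-law map.
#' @param n_repeats_B number of noisy B acquisitions averaged per sample.
#' @param b_extra_sd amplitude of a smooth B-specific random component
#'   outside the ROI (complementary information); default 0 keeps the
#'   noise-free mapping exact.
#' @param seed base seed; all generation is reproducible from it.
#' @return A `PhantomConfig` list.
#' @export
phantomConfig <- function(shape = c(96L, 96L, 48L), noise_sd = 0.05,
                          effect_size = 0.3, skull_intensity = 0.9,
                          mapping_gamma = 2, n_repeats_B = 1L,
                          b_extra_sd = 0, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 16L), noise_sd >= 0,
            effect_size >= 0, effect_size <= 1, skull_intensity > 0,
            mapping_gamma > 0, n_repeats_B >= 1L, b_extra_sd >= 0)
  structure(list(shape = shape, noise_sd = noise_sd,
                 effect_size = effect_size,
                 skull_intensity = skull_intensity,
                 mapping_gamma = mapping_gamma,
                 n_repeats_B = as.integer(n_repeats_B),
                 b_extra_sd = b_extra_sd, seed = as.integer(seed)),
            class = "PhantomConfig")
}

# periodic Gaussian smoothing via FFT, separable transfer function
.smooth3 <- function(x, sigma) {
  d <- dim(x)
  h <- lapply(d, function(n) {
    f <- c(0:floor(n / 2), seq_len(ceiling(n / 2) - 1) - ceiling(n / 2))[1:n] / n
    exp(-2 * pi^2 * sigma^2 * f^2)
  })
  H <- outer(outer(h[[1]], h[[2]]), h[[3]])
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / prod(d)
}

# fixed phantom geometry derived from the grid shape
.phantomGeometry <- function(shape) {
  ctr <- (shape + 1) / 2
  ax <- lapply(1:3, function(i) (seq_len(shape[i]) - ctr[i]) / (shape[i] / 2))
  rho2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  rho <- sqrt(rho2)
  brain <- rho <= 0.68
  skull <- rho >= 0.74 & rho <= 0.84
  roi_center <- as.integer(round(ctr + c(0.22, 0.12, 0.10) * shape / 2))
  r0 <- 0.16 * min(shape)
  ii <- lapply(1:3, function(i) seq_len(shape[i]) - roi_center[i])
  rr2 <- outer(outer(ii[[1]]^2, ii[[2]]^2, `+`), ii[[3]]^2, `+`)
  roi <- rr2 <= (1.6 * r0)^2
  list(brain = brain, skull = skull, roi = roi, roi_center = roi_center,
       r0 = r0, rr2 = rr2)
}

.bump <- function(rr2, r0) exp(-rr2 / (2 * (r0 / 1.5)^2))

# label-independent tissue texture on [0.15, 0.62] inside the brain
.phantomTexture <- function(cfg) {
  noise <- array(stats::rnorm(prod(cfg$shape)), dim = cfg$shape)
  sm <- .smooth3(noise, sigma = max(cfg$shape) / 24)
  z <- (sm - mean(sm)) / stats::sd(sm)
  pmin(pmax(0.385 + 0.075 * z, 0.15), 0.62)
}

#' Generate one paired phantom sample
#'
#' Modality A carries tissue texture, a bright skull shell and an ROI blob
#' whose radius shrinks by `effect_size` for the "AD" label; modality B is
#' the power-law map of the (non-atrophied) tissue over the brain mask,
#' zero over the skull, dimmed by `effect_size` over the ROI for "AD", with
#' truncated Gaussian acquisition noise averaged over `n_repeats_B`
#' acquisitions.  Both volumes lie in `[0, 1]` and are fully determined by
#' `(cfg$seed, subject_seed, label, image_index)`.
#'
#' @param cfg a [phantomConfig()].
#' @param label `"CN"` (control) or `"AD"` (disease).
#' @param subject_seed integer distinguishing subjects.
#' @param image_index repeat-visit index for subjects with several images;
#'   anatomy is shared across visits, acquisition noise is not.
#' @return A [PairedSample-class] with `brain`, `skull` and `roi` masks.
#' @export
makePhantomPair <- function(cfg, label = c("CN", "AD"), subject_seed = 1L,
                            image_index = 1L) {
  stopifnot(inherits(cfg, "PhantomConfig"))
  label <- match.arg(label)
  geo <- .phantomGeometry(cfg$shape)
  tex <- .withSeed(.mixSeed(cfg$seed, subject_seed), .phantomTexture(cfg))
  e <- if (label == "AD") cfg$effect_size else 0

  bump_lab <- .bump(geo$rr2, geo$r0 * (1 - e))
  a_dat <- (tex + 0.3 * bump_lab) * geo$brain + cfg$skull_intensity * geo$skull
  a_dat <- pmin(pmax(a_dat, 0), 1)

  bump_base <- .bump(geo$rr2, geo$r0)
  b_clean <- ((tex + 0.3 * bump_base)^cfg$mapping_gamma) * geo$brain
  b_clean <- b_clean * (1 - e * geo$roi)

  acq <- .withSeed(.mixSeed(cfg$seed, subject_seed, 7919L * image_index), {
    extra <- if (cfg$b_extra_sd > 0) {
      sm <- .smooth3(array(stats::rnorm(prod(cfg$shape)), dim = cfg$shape),
                     sigma = max(cfg$shape) / 24)
      cfg$b_extra_sd * (sm / stats::sd(sm)) * geo$brain * (1 - geo$roi)
    } else 0
    lapply(seq_len(cfg$n_repeats_B), function(r) {
      n <- if (cfg$noise_sd > 0)
        array(stats::rnorm(prod(cfg$shape), sd = cfg$noise_sd),
              dim = cfg$shape)
      else 0
      brainVolume(pmin(pmax(b_clean + extra + n, 0), 1))
    })
  })
  b <- averageRepeats(acq)
  b@intensityRange <- c(0, 1)
  a <- brainVolume(a_dat, intensityRange = c(0, 1))
  new("PairedSample", a = a, b = b, label = label,
      roiCenter = geo$roi_center,
      masks = list(brain = geo$brain, skull = geo$skull, roi = geo$roi),
      subjectId = sprintf("%s%04d", label, subject_seed), bSynthetic = FALSE)
}

#' Noise-free ground-truth mapping from modality A to modality B
#'
#' The oracle the synthesis network has to learn: a power-law transform of
#' A over the brain mask and zero elsewhere (in particular over the skull,
#' which is therefore unrecoverable from B).
#'
#' @param a a [BrainVolume-class] on `[0, 1]`.
#' @param masks named list with at least a `brain` logical array.
#' @param cfg a [phantomConfig()] supplying `mapping_gamma`.
#' @return The noise-free B volume.
#' @export
groundTruthMap <- function(a, masks, cfg) {
  stopifnot(is(a, "BrainVolume"), is.logical(masks$brain))
  b <- (pmax(a@data, 0)^cfg$mapping_gamma) * masks$brain
  brainVolume(b, spacing = a@spacing, intensityRange = c(0, 1))
}

#' Generate a balanced two-class phantom cohort
#'
#' @param cfg a [phantomConfig()].
#' @param n_per_class subjects per class.
#' @param repeats_B noisy B acquisitions averaged per sample (overrides
#'   `cfg$n_repeats_B`).
#' @param images_per_subject repeat visits per subject; anatomy is shared
#'   within a subject, acquisition noise is independent.
#' @return A [Cohort-class] of `2 * n_per_class * images_per_subject`
#'   samples with unique subject identifiers per subject.
#' @export
makeCohort <- function(cfg, n_per_class, repeats_B = cfg$n_repeats_B,
                       images_per_subject = 1L) {
  stopifnot(n_per_class >= 1L, images_per_subject >= 1L)
  cfg$n_repeats_B <- as.integer(repeats_B)
  samples <- list()
  ids <- character()
  k <- 0L
  for (lab in c("CN", "AD"))
    for (s in seq_len(n_per_class)) {
      k <- k + 1L
      for (img in seq_len(images_per_subject)) {
        smp <- makePhantomPair(cfg, lab, subject_seed = k, image_index = img)
        samples[[length(samples) + 1L]] <- smp
        ids <- c(ids, smp@subjectId)
      }
    }
  new("Cohort", samples = samples, subjectIds = ids)
}

#' Remove modality B for a random subset of subjects
#'
#' Missingness is applied at the subject level: either all of a subject's
#' samples lose modality B or none do, mirroring clinical missingness and
#' preventing leakage across data splits.
#'
#' @param cohort a [Cohort-class].
#' @param fraction fraction of subjects to strip, in `[0, 1]`.
#' @param seed RNG seed for the subject subset.
#' @return The cohort with `round(fraction * n_subjects)` subjects missing B.
#' @export
dropModality <- function(cohort, fraction, seed = 1L) {
  stopifnot(is(cohort, "Cohort"), fraction >= 0, fraction <= 1)
  subj <- unique(cohort@subjectIds)
  k <- round(fraction * length(subj))
  if (k == 0L) return(cohort)
  chosen <- .withSeed(seed, sample(subj, k))
  for (i in seq_along(cohort@samples))
    if (cohort@subjectIds[i] %in% chosen) {
      cohort@samples[[i]]@b <- NULL
      cohort@samples[[i]]@bSynthetic <- FALSE
    }
  cohort
}
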