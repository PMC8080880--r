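# The full synthesis model: per-domain encoders and decoders around the
# shared invertible core, plus two PatchGAN discriminators.  One parameter
# set serves both mapping directions:
#     A -> B : dec_b( coreForward( enc_a(a) ) )
#     B -> A : dec_a( coreInverse( enc_b(b) ) )
# Volumes enter the model in tanh range [-1, 1]; data on [0, 1] is mapped
# with x -> 2x - 1 at entry and (y + 1) / 2 at exit.

.encoderSpec <- function(width) list(nnConv3(1L, width, k = 3L), nnINorm(), nnReLU())
.decoderSpec <- function(width) list(nnConv3(width, 1L, k = 1L), nnTanh())

.discSpec <- function(base = 16L) {
  list(nnConv3(1L, base, k = 3L, stride = 2L, pad = 1L), nnLeakyReLU(),
       nnConv3(base, 2L * base, k = 3L, stride = 2L, pad = 1L), nnINorm(),
       nnLeakyReLU(),
       nnConv3(2L * base, 4L * base, k = 3L, stride = 2L, pad = 1L), nnINorm(),
       nnLeakyReLU(),
       nnConv3(4L * base, 1L, k = 3L, stride = 1L, pad = 1L))
}

.coreFromParams <- function(width, hidden, kernel, core_params) {
  blocks <- lapply(core_params, function(bp) {
    net <- .subnetSpec(width %/% 2L, hidden, kernel)
    structure(list(r1 = list(net = net, params = bp$r1),
                   r2 = list(net = net, params = bp$r2),
                   channels = width %/% 2L), class = "RevBlock")
  })
  structure(list(width = width, blocks = blocks), class = "InvertibleCore")
}

#' Construct the bidirectional synthesis model
#'
#' Encoders lift each modality into a `core_width`-channel feature space
#' (3x3x3 convolution, instance norm, ReLU); the weight-shared invertible
#' core maps between the two feature spaces; decoders project back to image
#' space (1x1x1 convolution followed by tanh).  Two PatchGAN discriminators
#' judge local realism of synthetic volumes in each domain: D1 for domain B,
#' D2 for domain A.  Parameters are drawn from the current RNG stream.
#'
#' @param core_width even feature-space width, default 16.
#' @param core_blocks number of additive-coupling blocks, default 2.
#' @param core_hidden hidden channels of the coupling subnetworks.
#' @param disc_base base channels of the discriminators (doubled at each of
#'   the 3 stride-2 stages).
#' @return A `SynthesisModel` list with `nets` and `params`.
#' @export
synthesisModel <- function(core_width = 16L, core_blocks = 2L,
                           core_hidden = 8L, disc_base = 16L) {
  core_width <- as.integer(core_width)
  if (core_width %% 2L != 0L) stop("core_width must be even")
  core <- invertibleCore(core_width, core_blocks, core_hidden)
  nets <- list(enc_a = .encoderSpec(core_width),
               enc_b = .encoderSpec(core_width),
               dec_a = .decoderSpec(core_width),
               dec_b = .decoderSpec(core_width),
               d1 = .discSpec(disc_base), d2 = .discSpec(disc_base))
  params <- list(enc_a = nnInit(nets$enc_a), enc_b = nnInit(nets$enc_b),
                 dec_a = nnInit(nets$dec_a), dec_b = nnInit(nets$dec_b),
                 core = .coreParams(core),
                 d1 = nnInit(nets$d1), d2 = nnInit(nets$d2))
  structure(list(spec = list(core_width = core_width,
                             core_blocks = as.integer(core_blocks),
                             core_hidden = as.integer(core_hidden),
                             core_kernel = 3L,
                             disc_base = as.integer(disc_base)),
                 nets = nets, params = params),
            class = "SynthesisModel")
}

.modelCore <- function(m)
  .coreFromParams(m$spec$core_width, m$spec$core_hidden, m$spec$core_kernel,
                  m$params$core)

#' @export
print.SynthesisModel <- function(x, ...) {
  gp <- generatorParamCount(x)
  cat(sprintf(paste0("SynthesisModel: core width %d (%d blocks, hidden %d), ",
                     "generator params %d, discriminator base %d\n"),
              x$spec$core_width, x$spec$core_blocks, x$spec$core_hidden,
              gp, x$spec$disc_base))
  invisible(x)
}

#' Parameter count of the (single, shared) generator
#'
#' Both mapping directions together are served by exactly this many
#' parameters: two encoders, two decoders and the shared core.
#'
#' @param m a [synthesisModel()].
#' @return Integer count.
#' @export
generatorParamCount <- function(m) {
  paramCount(m$params[c("enc_a", "enc_b", "dec_a", "dec_b", "core")])
}

.asTensor4 <- function(x) {
  if (is(x, "BrainVolume")) x <- x@data
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected a 3D volume or 4D tensor")
  x
}

#' Map [0,1] data into the tanh model range [-1, 1] (and back)
#' @param x numeric array.
#' @return Rescaled array.
#' @export
toModelRange <- function(x) 2 * x - 1

#' @rdname toModelRange
#' @export
fromModelRange <- function(x) (x + 1) / 2

# generator pass without caches (inference)
.genApply <- function(m, x, direction = c("ab", "ba"), single = TRUE) {
  direction <- match.arg(direction)
  core <- .modelCore(m)
  if (direction == "ab") {
    f <- nnForward(m$nets$enc_a, m$params$enc_a, x, single)$out
    f <- coreForward(f, core, single)
    nnForward(m$nets$dec_b, m$params$dec_b, f, single)$out
  } else {
    f <- nnForward(m$nets$enc_b, m$params$enc_b, x, single)$out
    f <- coreInverse(f, core, single)
    nnForward(m$nets$dec_a, m$params$dec_a, f, single)$out
  }
}

#' Synthesize modality B from modality A
#'
#' `dec_b(coreForward(enc_a(a)))`; output lies strictly inside `(-1, 1)`.
#'
#' @param a 3D array (or `(X,Y,Z,1)` tensor) in model range `[-1, 1]`.
#' @param m a [synthesisModel()].
#' @param single use the single-precision convolution path.
#' @return Tensor of the same spatial shape.
#' @export
generateAtoB <- function(a, m, single = TRUE)
  .genApply(m, .asTensor4(a), "ab", single)

#' Synthesize modality A from modality B
#'
#' `dec_a(coreInverse(enc_b(b)))`, running the very same core parameters
#' backwards.
#'
#' @param b 3D array (or `(X,Y,Z,1)` tensor) in model range `[-1, 1]`.
#' @inheritParams generateAtoB
#' @return Tensor of the same spatial shape.
#' @export
generateBtoA <- function(b, m, single = TRUE)
  .genApply(m, .asTensor4(b), "ba", single)

#' Patch-level realism scores
#'
#' Applies one PatchGAN discriminator; the result is a spatial grid of
#' scores, each judging a local patch of the input (three stride-2 stages:
#' a 96 x 96 x 48 input yields a 12 x 12 x 6 score grid).
#'
#' @param x 3D array or `(X,Y,Z,1)` tensor in model range.
#' @param m a [synthesisModel()].
#' @param which `"d1"` (domain B) or `"d2"` (domain A).
#' @param single use the single-precision convolution path.
#' @return A 3D array of patch scores.
#' @export
discriminate <- function(x, m, which = c("d1", "d2"), single = TRUE) {
  which <- match.arg(which)
  out <- nnForward(m$nets[[which]], m$params[[which]], .asTensor4(x), single)$out
  array(out, dim = dim(out)[1:3])
}

#' Loss weights of the synthesis objective
#' @param lambda_cyc nonnegative weight of the cycle-consistency term.
#' @return A `LossWeights` list.
#' @export
lossWeights <- function(lambda_cyc = 10) {
  stopifnot(lambda_cyc >= 0)
  list(lambda_cyc = lambda_cyc)
}

#' Generator objective with per-term breakdown
#'
#' Computes the least-squares adversarial terms for both mapping directions
#' and the L1 cycle-consistency term on a paired batch:
#' `total = gan_ab + gan_ba + lambda * cyc` (exact arithmetic identity).
#' `gan_ab` scores `G(a)` against D1's real target, `gan_ba` scores the
#' inverse direction against D2, and `cyc` is the mean absolute error of
#' both round trips `a -> b -> a` and `b -> a -> b`.
#'
#' @param real_a,real_b paired tensors in model range `[-1, 1]` (3D arrays
#'   or lists of them for a batch).
#' @param m a [synthesisModel()].
#' @param w a [lossWeights()].
#' @param single use the single-precision convolution path.
#' @return A `LossBreakdown` list: `gan_ab`, `gan_ba`, `cyc`, `total`.
#' @export
computeLosses <- function(real_a, real_b, m, w = lossWeights(), single = TRUE) {
  if (!is.list(real_a)) real_a <- list(real_a)
  if (!is.list(real_b)) real_b <- list(real_b)
  stopifnot(length(real_a) == length(real_b))
  gan_ab <- gan_ba <- cyc <- 0
  for (i in seq_along(real_a)) {
    a <- .asTensor4(real_a[[i]]); b <- .asTensor4(real_b[[i]])
    fake_b <- .genApply(m, a, "ab", single)
    fake_a <- .genApply(m, b, "ba", single)
    rec_a <- .genApply(m, fake_b, "ba", single)
    rec_b <- .genApply(m, fake_a, "ab", single)
    s1 <- nnForward(m$nets$d1, m$params$d1, fake_b, single)$out
    s2 <- nnForward(m$nets$d2, m$params$d2, fake_a, single)$out
    gan_ab <- gan_ab + mean((s1 - 1)^2)
    gan_ba <- gan_ba + mean((s2 - 1)^2)
    cyc <- cyc + mean(abs(rec_a - a)) + mean(abs(rec_b - b))
  }
  n <- length(real_a)
  gan_ab <- gan_ab / n; gan_ba <- gan_ba / n; cyc <- cyc / n
  list(gan_ab = gan_ab, gan_ba = gan_ba, cyc = cyc,
       total = gan_ab + gan_ba + w$lambda_cyc * cyc)
}

# ---- generator forward/backward with caches (training) ---------------------

.genForwardFull <- function(m, x, direction, single = TRUE) {
  core <- .modelCore(m)
  if (direction == "ab") {
    e <- nnForward(m$nets$enc_a, m$params$enc_a, x, single)
    cf <- .coreForwardFull(e$out, core, single)
    d <- nnForward(m$nets$dec_b, m$params$dec_b, cf$out, single)
  } else {
    e <- nnForward(m$nets$enc_b, m$params$enc_b, x, single)
    cf <- .coreInverseFull(e$out, core, single)
    d <- nnForward(m$nets$dec_a, m$params$dec_a, cf$out, single)
  }
  list(out = d$out, e = e, cf = cf, d = d, direction = direction)
}

# returns grads in generator-params structure plus gradient wrt the input
.genBackwardFull <- function(m, fwd, dout, single = TRUE) {
  core <- .modelCore(m)
  dir <- fwd$direction
  dec_name <- if (dir == "ab") "dec_b" else "dec_a"
  enc_name <- if (dir == "ab") "enc_a" else "enc_b"
  bd <- nnBackward(m$nets[[dec_name]], m$params[[dec_name]], fwd$d$caches,
                   dout, single)
  bc <- if (dir == "ab") .coreForwardBackward(bd$dx, core, fwd$cf$caches, single)
        else .coreInverseBackward(bd$dx, core, fwd$cf$caches, single)
  be <- nnBackward(m$nets[[enc_name]], m$params[[enc_name]], fwd$e$caches,
                   bc$dx, single)
  grads <- list(enc_a = NULL, enc_b = NULL, dec_a = NULL, dec_b = NULL,
                core = bc$grads)
  grads[[enc_name]] <- be$grads
  grads[[dec_name]] <- bd$grads
  list(dx = be$dx, grads = grads)
}

.genGradsAdd <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) if (!is.null(b[[nm]])) a[[nm]] <- gradsAdd(a[[nm]], b[[nm]])
  a
}
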