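make_small_model <- function(seed = 21) {
  set.seed(seed)
  synthesisModel(core_width = 8L, core_hidden = 4L, disc_base = 4L)
}

test_that("generator outputs preserve shape and stay inside the tanh range", {
  m <- make_small_model()
  set.seed(1)
  a <- array(runif(16 * 16 * 8, -1, 1), c(16, 16, 8))
  fb <- generateAtoB(a, m)
  expect_identical(dim(fb), c(16L, 16L, 8L, 1L))
  expect_true(all(abs(fb) < 1))
  fa <- generateBtoA(a, m)
  expect_identical(dim(fa), c(16L, 16L, 8L, 1L))
  expect_true(all(abs(fa) < 1))
  # deterministic given fixed parameters and input
  expect_identical(fb, generateAtoB(a, m))
  expect_error(generateAtoB(array(0, c(2, 2)), m), "3D volume or 4D tensor")
})

test_that("both mapping directions are served by one parameter set", {
  m <- make_small_model()
  # combined parameter count of the two directions equals one generator
  expect_equal(paramCount(m$params[c("enc_a", "dec_b")]) +
                 paramCount(m$params[c("enc_b", "dec_a")]) +
                 paramCount(m$params["core"]),
               generatorParamCount(m))
  # perturbing a core weight changes BOTH directions' outputs
  set.seed(2)
  a <- array(runif(16 * 16 * 8, -1, 1), c(16, 16, 8))
  fb0 <- generateAtoB(a, m); fa0 <- generateBtoA(a, m)
  m$params$core[[1]]$r1[[1]]$w[1] <- m$params$core[[1]]$r1[[1]]$w[1] + 0.3
  expect_gt(max(abs(generateAtoB(a, m) - fb0)), 0)
  expect_gt(max(abs(generateBtoA(a, m) - fa0)), 0)
})

test_that("an identity-configured generator round-trips its input", {
  # encoders reduced to mirrored +/- centre taps (so ReLU after instance
  # norm loses no information), decoders to small linear read-outs inside
  # tanh's linear region, zero subnetworks: the generator becomes an
  # (instance-normalised) identity and the cycle closes
  set.seed(3)
  m <- synthesisModel(core_width = 2L, core_hidden = 2L, disc_base = 4L)
  for (ed in c("enc_a", "enc_b")) {
    m$params[[ed]][[1]]$w <- matrix(0, 27, 2)
    m$params[[ed]][[1]]$w[14, 1] <- 1     # centre tap, +x
    m$params[[ed]][[1]]$w[14, 2] <- -1    # centre tap, -x
    m$params[[ed]][[1]]$b[] <- 0
  }
  for (dd in c("dec_a", "dec_b")) {
    m$params[[dd]][[1]]$w <- matrix(c(0.02, -0.02), 2, 1)
    m$params[[dd]][[1]]$b[] <- 0
  }
  m$params$core <- rapply(m$params$core, function(x) x * 0, how = "replace")
  x <- array(rnorm(8 * 8 * 8, sd = 0.3), c(8, 8, 8, 1))
  y <- generateAtoB(x, m, single = FALSE)
  # instance norm is scale-invariant, so the round trip reproduces y
  xr <- generateBtoA(y, m, single = FALSE)
  yr <- generateAtoB(xr, m, single = FALSE)
  # tolerance reflects the instance-norm eps at the small read-out scale
  expect_equal(yr, y, tolerance = 2e-2)
  # and y itself is the normalised input in tanh's linear region
  xhat <- (x - mean(x)) / sqrt(mean((x - mean(x))^2) + 1e-5)
  expect_equal(as.vector(y), as.vector(tanh(0.02 * xhat)), tolerance = 1e-4)
})

test_that("the discriminator yields patch score grids of the right extent", {
  m <- make_small_model()
  set.seed(4)
  x <- array(runif(32 * 32 * 16, -1, 1), c(32, 32, 16))
  s <- discriminate(x, m, "d1")
  expect_identical(dim(s), c(4L, 4L, 2L))   # three stride-2 stages
  expect_identical(s, discriminate(x, m, "d1"))
  # 96 x 96 x 48 input -> 12 x 12 x 6 score grid (stride arithmetic)
  big <- array(runif(96 * 96 * 48, -1, 1), c(96, 96, 48))
  expect_identical(dim(discriminate(big, m, "d2")), c(12L, 12L, 6L))
})

test_that("the loss breakdown obeys total = gan_ab + gan_ba + lambda*cyc", {
  m <- make_small_model()
  set.seed(5)
  a <- array(runif(16 * 16 * 8, -1, 1), c(16, 16, 8))
  b <- array(runif(16 * 16 * 8, -1, 1), c(16, 16, 8))
  for (lam in c(0, 1, 10)) {
    lb <- computeLosses(a, b, m, lossWeights(lam))
    expect_identical(lb$total, lb$gan_ab + lb$gan_ba + lam * lb$cyc)
  }
  l0 <- computeLosses(a, b, m, lossWeights(0))
  expect_identical(l0$total, l0$gan_ab + l0$gan_ba)
  # doubling lambda moves the total by exactly cyc * lambda
  l1 <- computeLosses(a, b, m, lossWeights(10))
  l2 <- computeLosses(a, b, m, lossWeights(20))
  expect_equal(l2$total - l1$total, 10 * l1$cyc, tolerance = 1e-12)
  expect_gte(l1$cyc, 0)
})

test_that("updating the A->B direction changes B->A behaviour (shared core)", {
  eng <- asNamespace("revsyn3d")
  m <- make_small_model(seed = 33)
  set.seed(6)
  a <- array(runif(16 * 16 * 8, -1, 1), c(16, 16, 8, 1))
  b <- array(runif(16 * 16 * 8, -1, 1), c(16, 16, 8, 1))
  fa_before <- generateBtoA(b, m)
  # one optimiser step on the A->B adversarial loss only
  fw <- eng$.genForwardFull(m, a, "ab")
  f1 <- nnForward(m$nets$d1, m$params$d1, fw$out, TRUE)
  dfake <- nnBackward(m$nets$d1, m$params$d1, f1$caches,
                      2 * (f1$out - 1) / length(f1$out), TRUE)$dx
  gb <- eng$.genBackwardFull(m, fw, dfake)
  gen_names <- c("enc_a", "enc_b", "dec_a", "dec_b", "core")
  opt <- eng$adamInit(m$params[gen_names])
  r <- eng$adamStep(m$params[gen_names], gb$grads, opt, 2e-4)
  m$params[gen_names] <- r$params
  fa_after <- generateBtoA(b, m)
  expect_gt(max(abs(fa_after - fa_before)), 1e-8)
})
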