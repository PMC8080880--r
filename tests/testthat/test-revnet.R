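test_that("the coupling equations match hand evaluation on the scalar toy", {
  toy <- list(r1 = function(v) 2 * v, r2 = function(v) v)
  fw <- couplingForward(1, 2, toy)
  expect_identical(c(fw$y1, fw$y2), c(5, 7))
  bw <- couplingInverse(fw$y1, fw$y2, toy)
  expect_identical(c(bw$x1, bw$x2), c(1, 2))
})

test_that("zero subnetworks make coupling and core the identity", {
  zero <- list(r1 = function(v) 0 * v, r2 = function(v) 0 * v)
  x1 <- array(rnorm(8), c(2, 2, 2, 1)); x2 <- array(rnorm(8), c(2, 2, 2, 1))
  fw <- couplingForward(x1, x2, zero)
  expect_equal(fw$y1, x1); expect_equal(fw$y2, x2)
  set.seed(1)
  core <- invertibleCore(width = 4, n_blocks = 3, hidden = 2)
  for (i in seq_along(core$blocks))
    for (r in c("r1", "r2"))
      core$blocks[[i]][[r]]$params <- paramsMapZero(core$blocks[[i]][[r]]$params)
  x <- array(rnorm(4 * 4 * 4 * 4), c(4, 4, 4, 4))
  expect_equal(coreForward(x, core, single = FALSE), x)
  expect_equal(coreInverse(x, core, single = FALSE), x)
})

test_that("core inverse is the exact inverse of core forward", {
  set.seed(10)
  core <- invertibleCore(width = 16, n_blocks = 2, hidden = 8)
  for (s in 1:5) {
    set.seed(100 + s)
    x <- array(rnorm(16 * 16 * 8 * 16), c(16, 16, 8, 16))
    # double path: near machine precision
    xr <- coreInverse(coreForward(x, core, single = FALSE), core,
                      single = FALSE)
    expect_lt(max(abs(xr - x)), 1e-8)
    # single path: float32 tolerance
    xr1 <- coreInverse(coreForward(x, core, single = TRUE), core,
                       single = TRUE)
    expect_lt(max(abs(xr1 - x)), 1e-4)
  }
  # depth-1 core equals a single coupling after channel split/concat
  core1 <- invertibleCore(width = 4, n_blocks = 1, hidden = 2)
  x <- array(rnorm(4 * 4 * 4 * 4), c(4, 4, 4, 4))
  y <- coreForward(x, core1, single = FALSE)
  cf <- couplingForward(x[, , , 1:2, drop = FALSE], x[, , , 3:4, drop = FALSE],
                        core1$blocks[[1]], single = FALSE)
  expect_equal(y[, , , 1:2, drop = FALSE], cf$y1)
  expect_equal(y[, , , 3:4, drop = FALSE], cf$y2)
})

test_that("shape and channel-count violations raise errors", {
  expect_error(couplingForward(array(0, c(2, 2, 2, 1)),
                               array(0, c(2, 2, 3, 1)),
                               list(r1 = identity, r2 = identity)),
               "shape mismatch")
  expect_error(invertibleCore(width = 7), "even")
  set.seed(2)
  core <- invertibleCore(width = 4, n_blocks = 1, hidden = 2)
  expect_error(coreForward(array(0, c(4, 4, 4, 3)), core), "channel")
})

test_that("forward and inverse directions share one parameter set", {
  set.seed(3)
  core <- invertibleCore(width = 8, n_blocks = 2, hidden = 4)
  n_one_direction <- coreParamCount(core)
  # a parameter perturbation changes BOTH directions' outputs
  x <- array(rnorm(8 * 8 * 4 * 8), c(8, 8, 4, 8))
  yf0 <- coreForward(x, core, single = FALSE)
  yi0 <- coreInverse(x, core, single = FALSE)
  core$blocks[[1]]$r1$params[[1]]$w[1] <-
    core$blocks[[1]]$r1$params[[1]]$w[1] + 0.5
  expect_gt(max(abs(coreForward(x, core, single = FALSE) - yf0)), 0)
  expect_gt(max(abs(coreInverse(x, core, single = FALSE) - yi0)), 0)
  expect_equal(coreParamCount(core), n_one_direction)
})

test_that("gradients through the inverse touch the same parameters", {
  eng <- asNamespace("revsyn3d")
  set.seed(4)
  core <- invertibleCore(width = 4, n_blocks = 2, hidden = 2)
  x <- array(rnorm(4 * 4 * 4 * 4), c(4, 4, 4, 4))
  ff <- eng$.coreForwardFull(x, core, single = FALSE)
  gf <- eng$.coreForwardBackward(ff$out, core, ff$caches, single = FALSE)
  fi <- eng$.coreInverseFull(x, core, single = FALSE)
  gi <- eng$.coreInverseBackward(fi$out, core, fi$caches, single = FALSE)
  # same nested gradient structure (same parameter identifiers), both
  # directions produce nonzero gradients for the same subnet weights
  expect_identical(rapply(gf$grads, length, how = "unlist"),
                   rapply(gi$grads, length, how = "unlist"))
  expect_gt(max(abs(gf$grads[[1]]$r1[[1]]$w)), 0)
  expect_gt(max(abs(gi$grads[[1]]$r1[[1]]$w)), 0)
})

test_that("activations are reconstructible from outputs (memory contract)", {
  set.seed(5)
  core <- invertibleCore(width = 8, n_blocks = 3, hidden = 4)
  x <- array(rnorm(8 * 8 * 4 * 8), c(8, 8, 4, 8))
  # store intermediate activations during the forward pass
  eng <- asNamespace("revsyn3d")
  s <- eng$.splitChannels(x, 8L)
  stored <- list()
  for (i in seq_along(core$blocks)) {
    r <- couplingForward(s$x1, s$x2, core$blocks[[i]], single = FALSE)
    s <- list(x1 = r$y1, x2 = r$y2)
    stored[[i]] <- s
  }
  # recompute them backwards from the final output alone
  for (i in rev(seq_along(core$blocks))) {
    expect_equal(stored[[i]], s, tolerance = 1e-10)
    r <- couplingInverse(s$x1, s$x2, core$blocks[[i]], single = FALSE)
    s <- list(x1 = r$x1, x2 = r$x2)
  }
  expect_equal(s, eng$.splitChannels(x, 8L), tolerance = 1e-10)
})
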