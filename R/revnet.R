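# Additive-coupling reversible blocks and the weight-shared invertible core.
#
# A coupling block splits the feature channels into halves (x1, x2) and
# applies
#     y1 = x1 + R1(x2)        (inverse: x2 = y2 - R2(y1))
#     y2 = x2 + R2(y1)        (         x1 = y1 - R1(x2))
# where R1 and R2 are small, non-invertible convolutional subnetworks.  The
# inverse is exact algebra, so forward and inverse mappings share one
# parameter set: training either direction trains both.

# R1 / R2: two same-padding convolutions with instance norm + ReLU between
# them, final convolution unactivated (shape-preserving by construction)
.subnetSpec <- function(channels, hidden, kernel = 3L) {
  stopifnot(kernel %% 2L == 1L)
  list(nnConv3(channels, hidden, k = kernel),
       nnINorm(), nnReLU(),
       nnConv3(hidden, channels, k = kernel))
}

.newSubnet <- function(channels, hidden, kernel = 3L) {
  net <- .subnetSpec(channels, hidden, kernel)
  list(net = net, params = nnInit(net))
}

#' Create an additive-coupling reversible block
#'
#' Builds the two convolutional subnetworks R1 and R2 operating on
#' half-width feature grids.  Parameters are drawn from the current RNG
#' stream; call `set.seed()` first for reproducibility.
#'
#' @param channels channels of each half-grid (half the core width).
#' @param hidden hidden channels inside R1/R2.
#' @param kernel odd convolution kernel size, default 3.
#' @return A `RevBlock` list with elements `r1` and `r2`.
#' @export
revBlock <- function(channels, hidden = 8L, kernel = 3L) {
  structure(list(r1 = .newSubnet(channels, hidden, kernel),
                 r2 = .newSubnet(channels, hidden, kernel),
                 channels = as.integer(channels)),
            class = "RevBlock")
}

# apply R (a subnet, or a plain function for toy examples) to a half-grid
.applyR <- function(r, x, single = TRUE) {
  if (is.function(r)) return(r(x))
  nnForward(r$net, r$params, x, single = single)$out
}

.checkHalves <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (is.null(da)) da <- length(a)
  if (is.null(db)) db <- length(b)
  if (!identical(da, db))
    stop(sprintf("half-grid shape mismatch: %s vs %s",
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
}

#' Forward pass of an additive-coupling block
#'
#' Computes `y1 = x1 + R1(x2)` then `y2 = x2 + R2(y1)`.
#'
#' @param x1,x2 half-width feature grids of identical shape (arrays, or
#'   scalars/vectors for toy subnetworks).
#' @param block a [revBlock()], or a list with plain functions `r1`, `r2`.
#' @param single use the single-precision convolution path.
#' @return `list(y1, y2)`.
#' @export
couplingForward <- function(x1, x2, block, single = TRUE) {
  .checkHalves(x1, x2)
  y1 <- x1 + .applyR(block$r1, x2, single)
  y2 <- x2 + .applyR(block$r2, y1, single)
  list(y1 = y1, y2 = y2)
}

#' Inverse pass of an additive-coupling block
#'
#' Exact algebraic inverse of [couplingForward()]: `x2 = y2 - R2(y1)`,
#' then `x1 = y1 - R1(x2)`, using the identical parameters.
#'
#' @param y1,y2 half-width feature grids of identical shape.
#' @inheritParams couplingForward
#' @return `list(x1, x2)`.
#' @export
couplingInverse <- function(y1, y2, block, single = TRUE) {
  .checkHalves(y1, y2)
  x2 <- y2 - .applyR(block$r2, y1, single)
  x1 <- y1 - .applyR(block$r1, x2, single)
  list(x1 = x1, x2 = x2)
}

#' Create the weight-shared invertible core
#'
#' A stack of additive-coupling blocks over an even number of feature
#' channels.  [coreForward()] and [coreInverse()] use the same parameter
#' set, so the core realises both mapping directions with one set of
#' weights.
#'
#' @param width total (even) feature channels; each half-grid has `width/2`.
#' @param n_blocks number of coupling blocks, default 2.
#' @param hidden hidden channels of each R1/R2 subnetwork.
#' @param kernel odd convolution kernel size.
#' @return An `InvertibleCore` list.
#' @export
invertibleCore <- function(width = 16L, n_blocks = 2L, hidden = 8L,
                           kernel = 3L) {
  width <- as.integer(width)
  if (width %% 2L != 0L)
    stop("core width must be even (channels are split into halves)")
  blocks <- lapply(seq_len(n_blocks), function(i)
    revBlock(width %/% 2L, hidden, kernel))
  structure(list(width = width, blocks = blocks), class = "InvertibleCore")
}

# channel-last storage makes the half-grids contiguous memory blocks
.splitChannels <- function(x, width) {
  d <- dim(x)
  if (length(d) != 4L || d[4L] != width)
    stop(sprintf("core expects a %d-channel feature grid, got %s", width,
                 paste(d, collapse = "x")))
  h <- width %/% 2L
  n <- prod(d[1:3]) * h
  x1 <- x[1:n]
  x2 <- x[(n + 1):(2 * n)]
  dim(x1) <- dim(x2) <- c(d[1:3], h)
  list(x1 = x1, x2 = x2)
}

.catChannels <- function(x1, x2) {
  d <- dim(x1)
  out <- c(x1, x2)
  dim(out) <- c(d[1:3], 2L * d[4L])
  out
}

#' Map a feature grid through the invertible core (forward direction)
#'
#' @param x feature grid of dim `(X, Y, Z, width)`.
#' @param core an [invertibleCore()].
#' @param single use the single-precision convolution path.
#' @return Feature grid of identical shape.
#' @export
coreForward <- function(x, core, single = TRUE) {
  s <- .splitChannels(x, core$width)
  for (blk in core$blocks) {
    r <- couplingForward(s$x1, s$x2, blk, single)
    s <- list(x1 = r$y1, x2 = r$y2)
  }
  .catChannels(s$x1, s$x2)
}

#' Map a feature grid through the invertible core (inverse direction)
#'
#' Applies the blocks in reverse order with [couplingInverse()], using the
#' identical parameter set as [coreForward()].
#'
#' @inheritParams coreForward
#' @param y feature grid of dim `(X, Y, Z, width)`.
#' @return Feature grid of identical shape.
#' @export
coreInverse <- function(y, core, single = TRUE) {
  s <- .splitChannels(y, core$width)
  for (blk in rev(core$blocks)) {
    r <- couplingInverse(s$x1, s$x2, blk, single)
    s <- list(x1 = r$x1, x2 = r$x2)
  }
  .catChannels(s$x1, s$x2)
}

#' Total trainable parameter count of a core or block
#'
#' Both mapping directions are served by this one parameter set.
#'
#' @param x an [invertibleCore()] or [revBlock()].
#' @return Integer parameter count.
#' @export
coreParamCount <- function(x) {
  if (inherits(x, "RevBlock"))
    return(paramCount(x$r1$params) + paramCount(x$r2$params))
  sum(vapply(x$blocks, coreParamCount, numeric(1)))
}

# ---- training-time passes with caches and gradients ------------------------

# forward with caches for backprop
.couplingForwardFull <- function(x1, x2, block, single = TRUE) {
  f1 <- nnForward(block$r1$net, block$r1$params, x2, single)
  y1 <- x1 + f1$out
  f2 <- nnForward(block$r2$net, block$r2$params, y1, single)
  y2 <- x2 + f2$out
  list(y1 = y1, y2 = y2, c1 = f1$caches, c2 = f2$caches)
}

# backprop through the forward coupling
.couplingBackward <- function(dy1, dy2, block, cache, single = TRUE) {
  b2 <- nnBackward(block$r2$net, block$r2$params, cache$c2, dy2, single)
  d_y1 <- dy1 + b2$dx
  dx2 <- dy2
  b1 <- nnBackward(block$r1$net, block$r1$params, cache$c1, d_y1, single)
  dx1 <- d_y1
  dx2 <- dx2 + b1$dx
  list(dx1 = dx1, dx2 = dx2, g1 = b1$grads, g2 = b2$grads)
}

# inverse pass with caches
.couplingInverseFull <- function(y1, y2, block, single = TRUE) {
  f2 <- nnForward(block$r2$net, block$r2$params, y1, single)
  x2 <- y2 - f2$out
  f1 <- nnForward(block$r1$net, block$r1$params, x2, single)
  x1 <- y1 - f1$out
  list(x1 = x1, x2 = x2, c1 = f1$caches, c2 = f2$caches)
}

# backprop through the inverse coupling (gradients wrt y1, y2 and params)
.couplingInverseBackward <- function(dx1, dx2, block, cache, single = TRUE) {
  b1 <- nnBackward(block$r1$net, block$r1$params, cache$c1, dx1, single)
  d_x2 <- dx2 - b1$dx
  b2 <- nnBackward(block$r2$net, block$r2$params, cache$c2, d_x2, single)
  dy1 <- dx1 - b2$dx
  dy2 <- d_x2
  list(dy1 = dy1, dy2 = dy2,
       g1 = gradsScale(b1$grads, -1), g2 = gradsScale(b2$grads, -1))
}

.coreForwardFull <- function(x, core, single = TRUE) {
  s <- .splitChannels(x, core$width)
  caches <- vector("list", length(core$blocks))
  for (i in seq_along(core$blocks)) {
    r <- .couplingForwardFull(s$x1, s$x2, core$blocks[[i]], single)
    caches[[i]] <- r[c("c1", "c2")]
    s <- list(x1 = r$y1, x2 = r$y2)
  }
  list(out = .catChannels(s$x1, s$x2), caches = caches)
}

.coreForwardBackward <- function(dout, core, caches, single = TRUE) {
  s <- .splitChannels(dout, core$width)
  grads <- vector("list", length(core$blocks))
  for (i in rev(seq_along(core$blocks))) {
    r <- .couplingBackward(s$x1, s$x2, core$blocks[[i]], caches[[i]], single)
    grads[[i]] <- list(r1 = r$g1, r2 = r$g2)
    s <- list(x1 = r$dx1, x2 = r$dx2)
  }
  list(dx = .catChannels(s$x1, s$x2), grads = grads)
}

.coreInverseFull <- function(y, core, single = TRUE) {
  s <- .splitChannels(y, core$width)
  n <- length(core$blocks)
  caches <- vector("list", n)
  for (i in rev(seq_len(n))) {
    r <- .couplingInverseFull(s$x1, s$x2, core$blocks[[i]], single)
    caches[[i]] <- r[c("c1", "c2")]
    s <- list(x1 = r$x1, x2 = r$x2)
  }
  list(out = .catChannels(s$x1, s$x2), caches = caches)
}

.coreInverseBackward <- function(dout, core, caches, single = TRUE) {
  s <- .splitChannels(dout, core$width)
  n <- length(core$blocks)
  grads <- vector("list", n)
  for (i in seq_len(n)) {
    r <- .couplingInverseBackward(s$x1, s$x2, core$blocks[[i]], caches[[i]],
                                  single)
    grads[[i]] <- list(r1 = r$g1, r2 = r$g2)
    s <- list(x1 = r$dy1, x2 = r$dy2)
  }
  list(dx = .catChannels(s$x1, s$x2), grads = grads)
}

# core parameters as a plain nested list (for Adam / accumulation)
.coreParams <- function(core)
  lapply(core$blocks, function(b) list(r1 = b$r1$params, r2 = b$r2$params))

.coreSetParams <- function(core, params) {
  for (i in seq_along(core$blocks)) {
    core$blocks[[i]]$r1$params <- params[[i]]$r1
    core$blocks[[i]]$r2$params <- params[[i]]$r2
  }
  core
}
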