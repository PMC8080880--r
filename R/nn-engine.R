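# Minimal sequential-network engine used by the synthesis generator, the
# PatchGAN discriminators and the diagnosis CNN.  Networks are described as
# lists of layer specs; parameters live in a parallel list so that gradient
# accumulation, weight sharing (the invertible core) and Adam updates are
# plain list operations.  Convolutions call the BLAS-backed C++ kernels;
# everything else is vectorised R.
#
# A feature map is an R array of dim (X, Y, Z, C).  All layers are
# deterministic; instance normalisation uses per-call statistics only, which
# keeps the additive-coupling blocks exactly invertible.

.IN_EPS <- 1e-5

nnConv3 <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L) {
  list(type = "conv3", cin = as.integer(cin), cout = as.integer(cout),
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad))
}
nnINorm <- function() list(type = "inorm")
nnReLU <- function() list(type = "relu")
nnLeakyReLU <- function(alpha = 0.2) list(type = "lrelu", alpha = alpha)
nnTanh <- function() list(type = "tanh")
nnPool2 <- function() list(type = "pool2")
nnFlatten <- function() list(type = "flatten")
nnFC <- function(nin, nout) {
  list(type = "fc", nin = as.integer(nin), nout = as.integer(nout))
}

# He-style initialisation drawn from the caller's RNG stream
nnInit <- function(net, gain = 1) {
  lapply(net, function(l) {
    switch(l$type,
      conv3 = {
        fan_in <- l$k^3 * l$cin
        list(w = matrix(stats::rnorm(fan_in * l$cout, sd = gain * sqrt(2 / fan_in)),
                        fan_in, l$cout),
             b = numeric(l$cout))
      },
      fc = list(w = matrix(stats::rnorm(l$nin * l$nout, sd = gain * sqrt(2 / l$nin)),
                           l$nin, l$nout),
                b = numeric(l$nout)),
      NULL)
  })
}

.convForward <- function(l, p, x, single) {
  d <- dim(x)
  stopifnot(length(d) == 4L, d[4L] == l$cin)
  if (!is.double(x)) storage.mode(x) <- "double"
  if (l$k == 3L && l$stride == 1L && l$pad == 1L) {
    y <- cpp_conv3s1_fwd(x, as.integer(d), p$w, p$b, l$cout, single)
    dim(y) <- c(d[1:3], l$cout)
  } else {
    r <- cpp_conv3d_fwd(x, as.integer(d), p$w, p$b, l$cout,
                        l$k, l$stride, l$pad, single)
    y <- r$y
    dim(y) <- r$dim
  }
  y
}

.convBackward <- function(l, p, x, dy, single) {
  d <- dim(x)
  if (!is.double(x)) storage.mode(x) <- "double"
  if (!is.double(dy)) storage.mode(dy) <- "double"
  if (l$k == 3L && l$stride == 1L && l$pad == 1L) {
    r <- cpp_conv3s1_bwd(x, as.integer(d), p$w, l$cout, dy, single)
  } else {
    r <- cpp_conv3d_bwd(x, as.integer(d), p$w, l$cout,
                        l$k, l$stride, l$pad, dy, single)
  }
  dx <- r$dx
  dim(dx) <- d
  dw <- matrix(r$dw, nrow(p$w), ncol(p$w))
  list(dx = dx, grads = list(w = dw, b = r$db))
}

.inormForward <- function(x) {
  d <- dim(x)
  if (!is.double(x)) storage.mode(x) <- "double"
  r <- cpp_inorm_fwd(x, as.integer(d), .IN_EPS)
  y <- r$y
  dim(y) <- d
  list(y = y, inv = r$inv, d = d)
}

.inormBackward <- function(cache, dy) {
  d <- cache$d
  if (!is.double(dy)) storage.mode(dy) <- "double"
  dx <- cpp_inorm_bwd(cache$y2, cache$inv, dy, as.integer(d))
  dim(dx) <- d
  dx
}

# forward pass; caches retain exactly what backward needs
nnForward <- function(net, params, x, single = TRUE) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    l <- net[[i]]
    p <- params[[i]]
    if (l$type == "conv3") {
      caches[[i]] <- list(x = x)
      x <- .convForward(l, p, x, single)
    } else if (l$type == "inorm") {
      r <- .inormForward(x)
      x <- r$y
      caches[[i]] <- list(y2 = x, inv = r$inv, d = r$d)
    } else if (l$type == "relu") {
      mask <- x > 0
      x <- x * mask
      caches[[i]] <- list(mask = mask)
    } else if (l$type == "lrelu") {
      mask <- x > 0
      neg <- x[!mask]
      x[!mask] <- l$alpha * neg
      caches[[i]] <- list(mask = mask)
    } else if (l$type == "tanh") {
      x <- tanh(x)
      caches[[i]] <- list(y = x)
    } else if (l$type == "pool2") {
      d <- dim(x)
      if (!is.double(x)) storage.mode(x) <- "double"
      r <- cpp_maxpool2_fwd(x, as.integer(d))
      caches[[i]] <- list(idx = r$idx, d = d)
      x <- r$y
      dim(x) <- r$dim
    } else if (l$type == "flatten") {
      caches[[i]] <- list(d = dim(x))
      x <- as.double(x)
    } else if (l$type == "fc") {
      caches[[i]] <- list(x = x)
      x <- drop(crossprod(p$w, x)) + p$b
    } else stop("unknown layer type: ", l$type)
  }
  list(out = x, caches = caches)
}

# backward pass: returns gradient wrt input and per-layer parameter grads
nnBackward <- function(net, params, caches, dout, single = TRUE) {
  grads <- vector("list", length(net))
  dy <- dout
  for (i in rev(seq_along(net))) {
    l <- net[[i]]
    p <- params[[i]]
    cc <- caches[[i]]
    if (l$type == "conv3") {
      r <- .convBackward(l, p, cc$x, dy, single)
      grads[[i]] <- r$grads
      dy <- r$dx
    } else if (l$type == "inorm") {
      dy <- .inormBackward(cc, dy)
    } else if (l$type == "relu") {
      dy <- dy * cc$mask
    } else if (l$type == "lrelu") {
      dim(dy) <- dim(cc$mask)
      dy[!cc$mask] <- l$alpha * dy[!cc$mask]
    } else if (l$type == "tanh") {
      dy <- dy * (1 - cc$y^2)
    } else if (l$type == "pool2") {
      if (!is.double(dy)) storage.mode(dy) <- "double"
      dy <- cpp_maxpool2_bwd(cc$idx, dy, as.integer(cc$d))
      dim(dy) <- cc$d
    } else if (l$type == "flatten") {
      dim(dy) <- cc$d
    } else if (l$type == "fc") {
      grads[[i]] <- list(w = outer(cc$x, dy), b = dy)
      dy <- drop(p$w %*% dy)
    }
  }
  list(dx = dy, grads = grads)
}

# ---- recursive helpers over nested parameter lists --------------------------

paramsMap <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) {
      v <- paramsMap(f, a[[i]], if (is.null(b)) NULL else b[[i]])
      if (!is.null(v)) out[[i]] <- v     # NULL leaves stay as placeholders
    }
    out
  } else if (is.null(a)) NULL
  else if (is.null(b)) f(a) else f(a, b)
}

gradsAdd <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  paramsMap(`+`, a, b)
}

gradsScale <- function(g, s) paramsMap(function(x) x * s, g)

# complete a (possibly partial) gradient structure with zeros so that
# optimiser updates can be applied after single-branch backward passes
gradsFill <- function(params, grads) {
  if (is.list(params)) {
    out <- vector("list", length(params))
    names(out) <- names(params)
    for (i in seq_along(params)) {
      v <- gradsFill(params[[i]], if (is.null(grads)) NULL else grads[[i]])
      if (!is.null(v)) out[[i]] <- v
    }
    out
  } else if (is.null(params)) NULL
  else if (is.null(grads)) params * 0
  else grads
}

paramCount <- function(params) {
  sum(rapply(params, length, how = "unlist"))
}

# ---- Adam -------------------------------------------------------------------

adamInit <- function(params) {
  list(m = paramsMap(function(x) x * 0, params),
       v = paramsMap(function(x) x * 0, params),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, betas = c(0.5, 0.999),
                     eps = 1e-8) {
  grads <- gradsFill(params, grads)
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  state$m <- paramsMap(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- paramsMap(function(v, g) b2 * v + (1 - b2) * g * g, state$v, grads)
  c1 <- 1 / (1 - b1^state$t)
  c2 <- 1 / (1 - b2^state$t)
  upd <- paramsMap(function(m, v) lr * (m * c1) / (sqrt(v * c2) + eps),
                   state$m, state$v)
  params <- paramsMap(`-`, params, upd)
  list(params = params, state = state)
}
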