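# Shared fixtures: built in code, no files.

# dyadic-valued random volume (exactly representable in float32)
randVol <- function(d = c(8, 8, 8), seed = 1, spacing = c(1, 1, 1)) {
  set.seed(seed)
  brainVolume(array(sample(0:4096, prod(d), replace = TRUE) / 4, dim = d),
              spacing = spacing)
}

tinyCfg <- function(...) {
  args <- list(...)
  defaults <- list(shape = c(16L, 16L, 16L), noise_sd = 0, effect_size = 0,
                   seed = 42L)
  do.call(phantomConfig, utils::modifyList(defaults, args))
}

# classifier training config small enough for unit tests
tinyClfCfg <- function(iterations = 24L, seed = 1L)
  trainConfig(learning_rate = 1e-3, adam_betas = c(0.9, 0.999),
              batch_size = 4L, iterations = iterations, seed = seed)

# naive SSIM oracle: explicit loops over uniform windows (independent of the
# package's convolution-based path)
ssimBruteForce <- function(r, t, data_range = 1, k = 7L) {
  d <- dim(r)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  vals <- c()
  for (i in seq_len(d[1] - k + 1))
    for (j in seq_len(d[2] - k + 1))
      for (l in seq_len(d[3] - k + 1)) {
        wr <- r[i:(i + k - 1), j:(j + k - 1), l:(l + k - 1)]
        wt <- t[i:(i + k - 1), j:(j + k - 1), l:(l + k - 1)]
        m1 <- mean(wr); m2 <- mean(wt)
        v1 <- stats::var(as.vector(wr)); v2 <- stats::var(as.vector(wt))
        cv <- stats::cov(as.vector(wr), as.vector(wt))
        vals <- c(vals, ((2 * m1 * m2 + C1) * (2 * cv + C2)) /
                    ((m1^2 + m2^2 + C1) * (v1 + v2 + C2)))
      }
  mean(vals)
}

paramsMapZero <- function(p) rapply(p, function(x) x * 0, how = "replace")
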