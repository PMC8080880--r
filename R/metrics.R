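# Volumetric image-quality metrics (RMSE, PSNR, SSIM, deviation maps) and
# two-class classification metrics (ACC, SEN, SPE, AUC).

.metricArr <- function(x) if (is(x, "BrainVolume")) x@data else x

.checkSameShape <- function(r, t) {
  if (!identical(dim(r), dim(t)))
    stop(sprintf("shape mismatch: %s vs %s", paste(dim(r), collapse = "x"),
                 paste(dim(t), collapse = "x")))
}

#' Root mean squared error between two volumes
#' @param ref,test volumes ([BrainVolume-class] or arrays) of equal shape.
#' @return Nonnegative scalar.
#' @export
rmse <- function(ref, test) {
  r <- .metricArr(ref); t <- .metricArr(test)
  .checkSameShape(r, t)
  sqrt(mean((r - t)^2))
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 log10(data_range^2 / MSE)`; `+Inf` when the volumes are identical.
#'
#' @param ref,test volumes of equal shape.
#' @param data_range dynamic range of the data (1 for unit-scaled volumes).
#' @return PSNR in dB.
#' @export
psnr <- function(ref, test, data_range = 1) {
  stopifnot(data_range > 0)
  r <- .metricArr(ref); t <- .metricArr(test)
  .checkSameShape(r, t)
  mse <- mean((r - t)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

.gaussKernel3 <- function(k, sigma) {
  h <- seq_len(k) - (k + 1) / 2
  g <- exp(-h^2 / (2 * sigma^2))
  w <- outer(outer(g, g), g)
  w / sum(w)
}

# weighted local mean of a 3D field via the conv engine (valid region only)
.localMean <- function(x, w, k) {
  d <- dim(x)
  r <- cpp_conv3d_fwd(as.double(x), as.integer(c(d, 1L)),
                      matrix(as.double(w), k^3, 1), 0, 1L, as.integer(k),
                      1L, 0L, FALSE)
  y <- r$y
  dim(y) <- r$dim[1:3]
  y
}

#' Mean structural similarity of two 3D volumes
#'
#' Mean local SSIM over 3D neighbourhoods with the standard stabilising
#' constants `C1 = (0.01 r)^2`, `C2 = (0.03 r)^2`.  The default window is a
#' 7x7x7 uniform box with unbiased local variances; a Gaussian 11-point
#' window (sigma 1.5) is available via `method = "gaussian"`.  Only windows
#' fully inside the volume contribute.
#'
#' @param ref,test volumes of equal shape, at least the window size per axis.
#' @param data_range dynamic range of the data.
#' @param method `"uniform"` (7^3 box) or `"gaussian"` (11-point, sigma 1.5).
#' @param return_map return the local SSIM map (over valid window centres)
#'   instead of its mean.
#' @return Scalar mean SSIM, or the SSIM map array.
#' @export
ssim3d <- function(ref, test, data_range = 1, method = c("uniform", "gaussian"),
                   return_map = FALSE) {
  method <- match.arg(method)
  r <- .metricArr(ref); t <- .metricArr(test)
  .checkSameShape(r, t)
  k <- if (method == "uniform") 7L else 11L
  if (any(dim(r) < k))
    stop(sprintf("volume smaller than the %dx%dx%d SSIM window", k, k, k))
  if (method == "uniform") {
    w <- rep(1 / k^3, k^3)
    cov_norm <- k^3 / (k^3 - 1)       # unbiased sample (co)variance
  } else {
    w <- .gaussKernel3(k, 1.5)
    cov_norm <- 1
  }
  mu1 <- .localMean(r, w, k)
  mu2 <- .localMean(t, w, k)
  s11 <- (.localMean(r * r, w, k) - mu1^2) * cov_norm
  s22 <- (.localMean(t * t, w, k) - mu2^2) * cov_norm
  s12 <- (.localMean(r * t, w, k) - mu1 * mu2) * cov_norm
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  if (return_map) map else mean(map)
}

# average a valid-region map over the central part of a full-size mask
.maskedMapMean <- function(map, mask) {
  off <- (dim(mask) - dim(map)) %/% 2L
  sub <- mask[off[1] + seq_len(dim(map)[1]), off[2] + seq_len(dim(map)[2]),
              off[3] + seq_len(dim(map)[3])]
  if (!any(sub)) return(NA_real_)
  mean(map[sub])
}

#' Voxelwise absolute deviation between two volumes
#'
#' @param ref,test volumes of equal shape.
#' @return A [BrainVolume-class] of nonnegative deviations.
#' @export
deviationMap <- function(ref, test) {
  r <- .metricArr(ref); t <- .metricArr(test)
  .checkSameShape(r, t)
  sp <- if (is(ref, "BrainVolume")) ref@spacing else c(1, 1, 1)
  brainVolume(abs(r - t), spacing = sp)
}

#' Render a deviation map for display
#'
#' Min-max scales the whole slice set to integer `[0, 255]`; identical
#' inputs render as all zero.
#'
#' @param map a deviation map from [deviationMap()].
#' @return Integer array on `[0, 255]`.
#' @export
renderDeviation <- function(map) {
  x <- .metricArr(map)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(array(0L, dim = dim(x)))
  array(as.integer(round(255 * (x - lo) / (hi - lo))), dim = dim(x))
}

#' Write a mid-axial slice of a rendered deviation map as PNG
#'
#' Display-only convenience; requires the `png` package.
#'
#' @param map a deviation map.
#' @param path output path.
#' @param slice axial slice index, default the middle slice.
#' @return `path`, invisibly.
#' @export
writeDeviationPNG <- function(map, path, slice = NULL) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export")
  img <- renderDeviation(map)
  if (is.null(slice)) slice <- ceiling(dim(img)[3] / 2)
  png::writePNG(t(img[, , slice]) / 255, path)
  invisible(path)
}

#' Two-class classification metrics
#'
#' Confusion table at a fixed threshold plus accuracy, sensitivity
#' (true-positive rate), specificity (true-negative rate) and AUC.  AUC is
#' computed by pairwise concordance with ties counted 1/2, equivalent to
#' trapezoidal ROC integration.
#'
#' @param labels class labels: logical, 0/1 numeric, or character/factor
#'   (the `positive` level is the positive class).
#' @param scores numeric scores, higher meaning more positive.
#' @param threshold decision threshold on the score, default 0.5 (softmax
#'   argmax for two classes).
#' @param positive positive-class label for character/factor input.
#' @return A `ClassificationReport` list: `acc`, `sen`, `spe`, `auc`,
#'   `confusion`, `threshold`, `n`.  With a single observed class AUC is
#'   undefined and returned as `NA` with a warning.
#' @export
classificationMetrics <- function(labels, scores, threshold = 0.5,
                                  positive = "AD") {
  stopifnot(length(labels) == length(scores))
  y <- if (is.logical(labels)) as.integer(labels)
       else if (is.numeric(labels)) as.integer(labels)
       else as.integer(as.character(labels) == positive)
  stopifnot(all(y %in% c(0L, 1L)))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L); tn <- sum(pred == 0L & y == 0L)
  fp <- sum(pred == 1L & y == 0L); fn <- sum(pred == 0L & y == 1L)
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  sen <- if (npos > 0) tp / npos else NA_real_
  spe <- if (nneg > 0) tn / nneg else NA_real_
  auc <- if (npos == 0L || nneg == 0L) {
    warning("AUC undefined: labels contain a single class")
    NA_real_
  } else {
    rk <- rank(scores)
    (sum(rk[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
  confusion <- matrix(c(tn, fp, fn, tp), 2, 2,
                      dimnames = list(predicted = c("neg", "pos"),
                                      truth = c("neg", "pos")))
  structure(list(acc = (tp + tn) / length(y), sen = sen, spe = spe,
                 auc = auc, confusion = confusion, threshold = threshold,
                 n = length(y)),
            class = "ClassificationReport")
}

#' @export
print.ClassificationReport <- function(x, ...) {
  cat(sprintf("ClassificationReport (n = %d, threshold %.2f)\n", x$n,
              x$threshold))
  cat(sprintf("  ACC %.4f  SEN %.4f  SPE %.4f  AUC %s\n", x$acc, x$sen,
              x$spe, ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc))))
  invisible(x)
}
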