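# NIfTI volume I/O and the intensity / geometry preprocessing rules applied
# before synthesis and classification.

#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file into a [BrainVolume-class], taking the voxel spacing
#' from the header.  The intensity range is left undeclared.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [BrainVolume-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3D image, got rank %d (%s)", length(d),
                 paste(d, collapse = "x")))
  sp <- RNifti::pixdim(img)[1:3]
  brainVolume(array(as.double(img), dim = d), spacing = sp)
}

#' Write a BrainVolume to a NIfTI-1 file
#'
#' @param v a [BrainVolume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype on-disk datatype, `"float"` (default) or `"double"`.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(v, path, datatype = "float") {
  stopifnot(is(v, "BrainVolume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write volume: no such directory: ", dir)
  img <- RNifti::asNifti(v@data)
  RNifti::pixdim(img) <- v@spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Clip the long intensity tail
#'
#' Structural MR intensities are long-tailed; voxels above `cap` are set to
#' `cap` (default 1024) before min-max rescaling.
#'
#' @param v a [BrainVolume-class].
#' @param cap positive clipping value, default 1024.
#' @return The clipped volume.
#' @export
clipLongTail <- function(v, cap = 1024) {
  stopifnot(is(v, "BrainVolume"), cap > 0)
  v@data <- pmin(v@data, cap)
  v@intensityRange <- c(NA_real_, NA_real_)
  v
}

#' Min-max rescale to [0, target_hi]
#'
#' Applies `target_hi * (x - min) / (max - min)` voxelwise, the standard
#' rescaling to `[0, 1024]`.
#'
#' @param v a [BrainVolume-class] with at least two distinct values.
#' @param target_hi upper bound of the target range, default 1024.
#' @return The rescaled volume with a declared intensity range.
#' @export
rescaleMinMax <- function(v, target_hi = 1024) {
  stopifnot(is(v, "BrainVolume"), target_hi > 0)
  lo <- min(v@data); hi <- max(v@data)
  if (hi <= lo)
    stop("degenerate input: constant volume cannot be min-max rescaled")
  v@data <- target_hi * (v@data - lo) / (hi - lo)
  v@intensityRange <- c(0, target_hi)
  v
}

#' Rescale to the unit interval
#'
#' `(x - min) / (max - min)`, applied just before volumes enter a model.
#'
#' @param v a [BrainVolume-class] with at least two distinct values.
#' @return The volume rescaled to `[0, 1]`.
#' @export
toUnitRange <- function(v) rescaleMinMax(v, target_hi = 1)

#' Crop a region of interest
#'
#' Extracts the box of `roi@size` voxels whose first voxel sits at
#' `center - floor(size / 2)` (1-based).  By default a box that overhangs
#' the volume is an error; with `pad = TRUE` the overhang is zero-filled.
#'
#' @param v a [BrainVolume-class].
#' @param roi an [ROISpec-class].
#' @param pad zero-pad out-of-bounds regions instead of erroring.
#' @return A [BrainVolume-class] of shape `roi@size`.
#' @export
cropROI <- function(v, roi, pad = FALSE) {
  stopifnot(is(v, "BrainVolume"), is(roi, "ROISpec"))
  d <- dim(v@data)
  start <- roi@center - roi@size %/% 2L
  end <- start + roi@size - 1L
  under <- pmax(1L - start, 0L)
  over <- pmax(end - d, 0L)
  if (!pad && any(under > 0L | over > 0L))
    stop(sprintf(paste0("ROI box out of bounds (overhang low [%s], ",
                        "high [%s]); use pad = TRUE to zero-fill"),
                 paste(under, collapse = ","), paste(over, collapse = ",")))
  out <- array(0, dim = as.integer(roi@size))
  src_lo <- pmax(start, 1L)
  src_hi <- pmin(end, d)
  dst_lo <- src_lo - start + 1L
  dst_hi <- src_hi - start + 1L
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    v@data[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  brainVolume(out, spacing = v@spacing)
}

# cubic-spline interpolation matrix mapping a length-n signal onto
# endpoint-aligned positions of length m (linear in the data, so built once
# per axis from unit impulses)
.resampleMatrix <- function(n, m) {
  if (n == 1L) return(matrix(1, m, 1))
  xout <- seq(1, n, length.out = m)
  A <- matrix(0, m, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    A[, j] <- stats::spline(seq_len(n), e, xout = xout, method = "fmm")$y
  }
  A
}

#' Resize a volume with separable cubic-spline interpolation
#'
#' Third-order spline resampling applied axis by axis on an endpoint-aligned
#' grid, the behaviour used to scale full images from 221 x 257 x 221 down
#' to 110 x 128 x 110.  Constant volumes are reproduced exactly; mild
#' interpolation overshoot outside the input range is possible, as with any
#' cubic scheme.
#'
#' @param v a [BrainVolume-class].
#' @param target_shape integer triple of output extents.
#' @return The resized volume.  Spacing is scaled to preserve physical size.
#' @export
resizeVolume <- function(v, target_shape) {
  stopifnot(is(v, "BrainVolume"), length(target_shape) == 3L,
            all(target_shape >= 1))
  target_shape <- as.integer(target_shape)
  d <- dim(v@data)
  x <- v@data
  for (ax in 1:3) {
    n <- dim(x)[ax]
    m <- target_shape[ax]
    if (n == m) next
    A <- .resampleMatrix(n, m)
    perm <- c(ax, setdiff(1:3, ax))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    xp <- A %*% matrix(xp, dp[1], dp[2] * dp[3])
    dim(xp) <- c(m, dp[2], dp[3])
    x <- aperm(xp, order(perm))
  }
  brainVolume(x, spacing = v@spacing * d / target_shape)
}

#' Average repeat acquisitions
#'
#' Voxelwise arithmetic mean of repeated acquisitions of the same volume
#' (as applied to multiple PET frames of one radiography session).
#'
#' @param volumes non-empty list of [BrainVolume-class] objects with
#'   identical shape and spacing.
#' @return The mean volume.
#' @export
averageRepeats <- function(volumes) {
  if (!is.list(volumes) || length(volumes) == 0L)
    stop("averageRepeats needs a non-empty list of volumes")
  d <- dim(volumes[[1]]@data)
  sp <- volumes[[1]]@spacing
  for (v in volumes) {
    stopifnot(is(v, "BrainVolume"))
    if (!identical(dim(v@data), d))
      stop(sprintf("shape mismatch in repeats: %s vs %s",
                   paste(dim(v@data), collapse = "x"),
                   paste(d, collapse = "x")))
    if (!isTRUE(all.equal(v@spacing, sp)))
      stop("spacing mismatch in repeats")
  }
  acc <- Reduce(`+`, lapply(volumes, function(v) v@data))
  brainVolume(acc / length(volumes), spacing = sp)
}
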