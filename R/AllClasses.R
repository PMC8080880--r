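#' @import methods
NULL

#' BrainVolume: a 3D scalar voxel grid with spacing metadata
#'
#' The elementary container of the package: a 3D array of voxel intensities
#' together with the voxel spacing in millimetres and an optional declared
#' intensity range.  Structural (T1-MRI-like) and functional (FDG-PET-like)
#' volumes are both represented this way.
#'
#' @slot data 3D numeric array of voxel intensities.
#' @slot spacing positive numeric triple, mm per voxel along each axis.
#' @slot intensityRange declared (lo, hi) pair, or `c(NA, NA)` when unknown.
#'
#' @exportClass BrainVolume
setClass("BrainVolume",
         representation(data = "array", spacing = "numeric",
                        intensityRange = "numeric"),
         prototype(spacing = c(1, 1, 1),
                   intensityRange = c(NA_real_, NA_real_)))

setValidity("BrainVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, sprintf("volume data must be a 3D array, got rank %d",
                          length(dim(object@data))))
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be a positive triple")
  if (length(object@intensityRange) != 2L)
    msg <- c(msg, "intensityRange must have length 2")
  if (!anyNA(object@intensityRange) && length(dim(object@data)) == 3L) {
    rng <- range(object@data)
    if (rng[1] < object@intensityRange[1] - 1e-9 ||
        rng[2] > object@intensityRange[2] + 1e-9)
      msg <- c(msg, "voxels fall outside the declared intensity range")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BrainVolume
#'
#' @param data 3D numeric array.
#' @param spacing voxel spacing in mm, default 1 mm isotropic.
#' @param intensityRange declared intensity range, or `NULL` for unknown.
#' @return A [BrainVolume-class] object.
#' @export
brainVolume <- function(data, spacing = c(1, 1, 1), intensityRange = NULL) {
  if (is.null(intensityRange)) intensityRange <- c(NA_real_, NA_real_)
  new("BrainVolume", data = data, spacing = as.numeric(spacing),
      intensityRange = as.numeric(intensityRange))
}

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("BrainVolume %d x %d x %d, spacing %s mm\n", d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = " x ")))
  if (!anyNA(object@intensityRange))
    cat(sprintf("  declared range [%g, %g]\n", object@intensityRange[1],
                object@intensityRange[2]))
  cat(sprintf("  observed range [%g, %g]\n", min(object@data),
              max(object@data)))
})

#' ROISpec: a region-of-interest crop box
#'
#' A box of `size` voxels centred on `center` (1-based voxel indices).  The
#' default size is the 96 x 96 x 48 hippocampal crop used throughout the
#' classification experiments.
#'
#' @slot center integer voxel triple (1-based).
#' @slot size integer triple of box extents.
#' @exportClass ROISpec
setClass("ROISpec", representation(center = "integer", size = "integer"),
         prototype(size = c(96L, 96L, 48L)))

setValidity("ROISpec", function(object) {
  if (length(object@center) != 3L) return("center must be a triple")
  if (length(object@size) != 3L || any(object@size <= 0L))
    return("size components must be positive")
  TRUE
})

#' @param center integer voxel triple (1-based).
#' @param size integer triple, default `c(96, 96, 48)`.
#' @rdname ROISpec-class
#' @export
roiSpec <- function(center, size = c(96L, 96L, 48L)) {
  new("ROISpec", center = as.integer(round(center)),
      size = as.integer(round(size)))
}

#' PairedSample: aligned two-modality volumes with a diagnostic label
#'
#' Holds the structural volume `a`, the functional volume `b` (or `NULL`
#' when that modality is missing), the class label, the ROI centre and the
#' region masks produced by the phantom generator (`brain`, `skull`, `roi`).
#'
#' @slot a structural modality, a [BrainVolume-class].
#' @slot b functional modality, a [BrainVolume-class] or `NULL` if missing.
#' @slot label class label, e.g. "CN" or "AD".
#' @slot roiCenter integer voxel triple (1-based).
#' @slot masks named list of logical arrays (may be empty for real data).
#' @slot subjectId subject identifier; several samples may share one.
#' @slot bSynthetic `TRUE` when `b` was imputed by the generator.
#' @slot aSynthetic `TRUE` when `a` was replaced by a synthetic volume.
#' @exportClass PairedSample
setClass("PairedSample",
         representation(a = "BrainVolume", b = "ANY", label = "character",
                        roiCenter = "integer", masks = "list",
                        subjectId = "character", bSynthetic = "logical",
                        aSynthetic = "logical"),
         prototype(b = NULL, masks = list(), bSynthetic = FALSE,
                   aSynthetic = FALSE))

setValidity("PairedSample", function(object) {
  msg <- character()
  if (!is.null(object@b)) {
    if (!is(object@b, "BrainVolume")) return("b must be a BrainVolume or NULL")
    if (!identical(dim(object@a@data), dim(object@b@data)))
      msg <- c(msg, "a and b must have identical shape")
    if (!isTRUE(all.equal(object@a@spacing, object@b@spacing)))
      msg <- c(msg, "a and b must have identical spacing")
  }
  if (length(object@label) != 1L || !nzchar(object@label))
    msg <- c(msg, "label must be a single non-empty string")
  if (length(object@roiCenter) == 3L) {
    d <- dim(object@a@data)
    if (any(object@roiCenter < 1L) || any(object@roiCenter > d))
      msg <- c(msg, "roiCenter must lie inside the volume")
  }
  for (nm in names(object@masks)) {
    m <- object@masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), dim(object@a@data)))
      msg <- c(msg, sprintf("mask '%s' must be a logical array of the volume shape", nm))
  }
  if (all(c("brain", "skull") %in% names(object@masks)) &&
      any(object@masks$brain & object@masks$skull))
    msg <- c(msg, "brain and skull masks must be disjoint")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PairedSample", function(object) {
  d <- dim(object@a@data)
  cat(sprintf("PairedSample subject=%s label=%s %dx%dx%d, b: %s%s\n",
              object@subjectId, object@label, d[1], d[2], d[3],
              if (is.null(object@b)) "missing" else "present",
              if (isTRUE(object@bSynthetic)) " (synthetic)" else ""))
})

#' Cohort: a list of paired samples with subject identifiers
#'
#' @slot samples list of [PairedSample-class] objects.
#' @slot subjectIds character vector, one per sample; a subject may own
#'   several samples (repeat imaging), so values need not be unique.
#' @exportClass Cohort
setClass("Cohort",
         representation(samples = "list", subjectIds = "character"))

setValidity("Cohort", function(object) {
  if (length(object@samples) != length(object@subjectIds))
    return("subjectIds must be the same length as samples")
  ok <- vapply(object@samples, is, logical(1), class2 = "PairedSample")
  if (!all(ok)) return("all samples must be PairedSample objects")
  TRUE
})

setMethod("show", "Cohort", function(object) {
  tab <- table(sampleLabels(object))
  cat(sprintf("Cohort of %d samples from %d subjects (%s)\n",
              length(object@samples), length(unique(object@subjectIds)),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  miss <- sum(vapply(object@samples, function(s) is.null(s@b), logical(1)))
  if (miss > 0) cat(sprintf("  %d samples missing modality B\n", miss))
})

#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @describeIn BrainVolume-class voxel data array
#' @param x a BrainVolume
#' @export
setMethod("volData", "BrainVolume", function(x) x@data)

#' @export
setGeneric("volSpacing", function(x) standardGeneric("volSpacing"))
#' @describeIn BrainVolume-class voxel spacing (mm)
#' @export
setMethod("volSpacing", "BrainVolume", function(x) x@spacing)

#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @describeIn Cohort-class number of samples
#' @param x a Cohort
#' @export
setMethod("nSamples", "Cohort", function(x) length(x@samples))

#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))
#' @describeIn Cohort-class class label of every sample
#' @export
setMethod("sampleLabels", "Cohort", function(x)
  vapply(x@samples, function(s) s@label, character(1)))

#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @describeIn Cohort-class subject identifier of every sample
#' @export
setMethod("subjectIds", "Cohort", function(x) x@subjectIds)

#' @export
setGeneric("getSample", function(x, i) standardGeneric("getSample"))
#' @describeIn Cohort-class extract one PairedSample
#' @param i sample index
#' @export
setMethod("getSample", "Cohort", function(x, i) x@samples[[i]])
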