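# Cohort persistence: a directory of NIfTI pairs plus a CSV manifest with
# columns subject_id, path_a, path_b (NA when missing), label, roi_x/y/z.

#' Write a cohort as NIfTI pairs with a CSV manifest
#'
#' @param cohort a [Cohort-class].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "Cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(cohort@samples), function(i) {
    s <- cohort@samples[[i]]
    pa <- sprintf("s%04d_a.nii.gz", i)
    writeVolume(s@a, file.path(dir, pa))
    pb <- NA_character_
    if (!is.null(s@b)) {
      pb <- sprintf("s%04d_b.nii.gz", i)
      writeVolume(s@b, file.path(dir, pb))
    }
    data.frame(subject_id = cohort@subjectIds[i], path_a = pa, path_b = pb,
               label = s@label, roi_x = s@roiCenter[1],
               roi_y = s@roiCenter[2], roi_z = s@roiCenter[3])
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort from a manifest
#'
#' Region masks are not persisted; samples read back carry empty mask lists.
#'
#' @param manifest path to a `manifest.csv` (or to its directory).
#' @return A [Cohort-class].
#' @export
readCohort <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.csv")
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  dir <- dirname(manifest)
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(tab)), function(i) {
    a <- readVolume(file.path(dir, tab$path_a[i]))
    b <- if (is.na(tab$path_b[i])) NULL
         else readVolume(file.path(dir, tab$path_b[i]))
    new("PairedSample", a = a, b = b, label = tab$label[i],
        roiCenter = as.integer(c(tab$roi_x[i], tab$roi_y[i], tab$roi_z[i])),
        subjectId = tab$subject_id[i])
  })
  new("Cohort", samples = samples, subjectIds = tab$subject_id)
}
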