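#' Construct a contrast map
#'
#' A contrast map is one subject's 3-D grid of contrast t-values (e.g. the
#' speech-vs-silence contrast from a GLM fit), together with an in-brain mask
#' and a voxel-to-world affine. All maps entering one dictionary must share
#' grid shape and affine, since dictionary words are fixed template-space
#' voxel sets.
#'
#' @param values 3-D numeric array of t-contrast values.
#' @param subject_id Subject identifier.
#' @param contrast_name One of `"speech_vs_silence"`, `"noise_vs_silence"`,
#'   `"speech_vs_noise"`.
#' @param mask 3-D logical array of in-brain voxels; defaults to all voxels
#'   with finite values.
#' @param affine 4x4 voxel-to-world transform; defaults to identity.
#' @return An object of class `contrast_map`.
#' @export
contrast_map <- function(values, subject_id, contrast_name = "speech_vs_silence",
                         mask = NULL, affine = diag(4)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop_bowsvm("`values` must be a 3-D array", "bowsvm_config_error")
  }
  contrast_name <- match.arg(contrast_name,
                             c("speech_vs_silence", "noise_vs_silence",
                               "speech_vs_noise"))
  if (is.null(mask)) mask <- array(is.finite(values), dim = dim(values))
  stopifnot(identical(dim(mask), dim(values)))
  if (any(!is.finite(values[mask]))) {
    stop_bowsvm("contrast values must be finite inside the mask",
                "bowsvm_validation_error")
  }
  structure(
    list(values = values, mask = mask, subject_id = as.character(subject_id),
         contrast_name = contrast_name, affine = affine),
    class = "contrast_map"
  )
}

#' @export
print.contrast_map <- function(x, ...) {
  cat("<contrast_map> subject", x$subject_id, "|", x$contrast_name,
      "|", paste(dim(x$values), collapse = "x"), "voxels,",
      sum(x$mask), "in mask\n")
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$affine, b$affine, tolerance = 1e-8))
}

#' Write contrast maps to NIfTI-1 files
#'
#' Writes one `.nii.gz` per subject plus a `manifest.csv` with columns
#' `subject_id,group,labeled`.
#'
#' @param x A `cohort_maps` object (see [generate_cohort_maps()]).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the manifest tibble with a `path` column.
#' @export
write_cohort_maps <- function(x, dir) {
  stopifnot(inherits(x, "cohort_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(x$maps, function(m) {
    p <- file.path(dir, paste0(m$subject_id, "_", m$contrast_name, ".nii.gz"))
    img <- RNifti::asNifti(m$values)
    RNifti::writeNifti(img, p)
    p
  }, character(1))
  manifest <- dplyr::mutate(x$manifest, path = unname(paths))
  readr::write_csv(dplyr::select(manifest, "subject_id", "group", "labeled"),
                   file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read a contrast map from a NIfTI-1 file
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @inheritParams contrast_map
#' @return A `contrast_map`.
#' @export
read_contrast_map <- function(path, subject_id, contrast_name = "speech_vs_silence") {
  img <- RNifti::readNifti(path)
  contrast_map(array(as.numeric(img), dim = dim(img)), subject_id,
               contrast_name, affine = RNifti::xform(img))
}
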