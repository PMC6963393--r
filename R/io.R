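#' Read and write volumes as NIfTI-1
#'
#' Volumes and masks are interchanged as NIfTI (`.nii` / `.nii.gz`) with the
#' voxel spacing carried in the header `pixdim`. Masks are stored as 8-bit
#' 0/1 images; intensity volumes as 32-bit float. Only 3-D images are
#' accepted: a 4-D file is rejected rather than silently squeezed.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a [volume3d].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stopf("expected a 3-D image, '%s' has %d dimension(s)", path, length(d))
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stopf("'%s' has missing or non-positive voxel spacing", path)
  volume3d(array(as.numeric(img), dim = d), spacing = sp)
}

#' @rdname read_volume
#' @param volume a [volume3d]; for `mask = TRUE` its data must be binary.
#' @param mask logical; write as 8-bit 0/1 mask instead of float intensities.
#' @export
write_volume <- function(volume, path, mask = FALSE) {
  stopifnot(inherits(volume, "volume3d"))
  data <- volume$data
  if (mask) {
    data <- array(as.integer(as_mask(data)), dim = dim(data))
  }
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = if (mask) "uint8" else "float")
  invisible(path)
}

#' Read / write a muscle-reference ROI point set (JSON)
#'
#' The on-disk form is a JSON object
#' `{"label": "SCM", "points": [[i, j, k], ...]}` with 0-based integer voxel
#' coordinates.
#'
#' @param path JSON file path.
#' @param grid_shape optional integer length-3 for bounds validation.
#' @return `read_roi` returns an [roi_points] object.
#' @export
read_roi <- function(path, grid_shape = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$points) || length(obj$points) == 0L)
    stopf("ROI file '%s' contains no points", path)
  pts <- obj$points
  if (!is.matrix(pts)) pts <- matrix(unlist(pts), ncol = 3, byrow = TRUE)
  roi_points(pts, label = obj$label %||% "ROI", grid_shape = grid_shape)
}

#' Read a study configuration from YAML
#'
#' Maps a YAML document onto [study_config()]. Recognised top-level keys:
#' `cohort` (fields of [cohort_spec()], with `template` holding
#' [phantom_config()] fields), `levelset` (fields of [levelset_params()]),
#' `thresholds`, `icc_model`, `comparisons` (list of 2-element method-name
#' lists), `alpha`, `manual_arm`, `n_roi_points`, `seed`. Missing keys take
#' the package defaults.
#'
#' @param path YAML file path.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  y <- yaml::read_yaml(path)
  template <- do.call(phantom_config, y$cohort$template %||% list())
  cohort_args <- y$cohort %||% list()
  cohort_args$template <- template
  cohort <- do.call(cohort_spec, cohort_args)
  args <- list(cohort = cohort,
               levelset = do.call(levelset_params, y$levelset %||% list()))
  for (key in c("thresholds", "icc_model", "alpha", "manual_arm",
                "n_roi_points", "seed"))
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  if (!is.null(y$comparisons))
    args$comparisons <- lapply(y$comparisons, unlist)
  do.call(study_config, args)
}

#' @rdname read_roi
#' @param roi an [roi_points] object.
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "roi_points"))
  jsonlite::write_json(
    list(label = roi$label,
         points = unname(apply(roi$points, 1, as.integer, simplify = FALSE))),
    path, auto_unbox = TRUE)
  invisible(path)
}
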