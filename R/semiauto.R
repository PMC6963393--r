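#' Sample the muscle reference intensity
#'
#' Reads the voxel values at the ROI points (typically three points placed in
#' the sternocleidomastoid muscle, SCM) and returns their arithmetic mean,
#' the reference against which the percentage thresholds are expressed.
#'
#' @param volume a [volume3d].
#' @param roi an [roi_points] object.
#' @param n_points required number of points; the reference protocol uses
#'   exactly 3. Set `NULL` to accept any count >= 1.
#' @return A `reference_intensity` object: list with `mean`, `point_values`,
#'   `n_points`.
#' @export
sample_muscle_reference <- function(volume, roi, n_points = 3L) {
  stopifnot(inherits(volume, "volume3d"), inherits(roi, "roi_points"))
  if (!is.null(n_points) && nrow(roi$points) != n_points)
    stopf("reference policy requires exactly %d point(s), ROI has %d",
          n_points, nrow(roi$points))
  vals <- volume$data[roi_linear_index(roi, dim(volume$data))]
  m <- mean(vals)
  if (!is.finite(m) || m <= 0)
    stopf("muscle reference mean must be > 0 (got %g); intensity ratios are undefined", m)
  structure(list(mean = m, point_values = vals, n_points = length(vals)),
            class = "reference_intensity")
}

#' Threshold criterion relative to the muscle reference
#'
#' @param ratio dimensionless multiple of the muscle mean (1.50, 1.75 and
#'   2.00 are the study criteria).
#' @param strict logical; `TRUE` (default) classifies a voxel as IPH iff its
#'   value is strictly greater than `ratio * mean`, matching the ">"
#'   formulation of the criteria. Ties at the exact threshold are excluded.
#' @return A `threshold_criterion` object.
#' @export
threshold_criterion <- function(ratio, strict = TRUE) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0)
    stopf("ratio must be a single positive number")
  structure(list(ratio = ratio, strict = isTRUE(strict)),
            class = "threshold_criterion")
}

#' Plaque qualification by wall thickness
#'
#' A carotid plaque qualifies for analysis when the wall thickness exceeds
#' 2 mm in at least two consecutive slices (strict inequality on both
#' slices).
#'
#' @param wall_thickness_by_slice numeric vector of per-slice wall thickness
#'   in mm, ordered along the slice axis.
#' @param min_thickness mm, default 2.
#' @param min_slices number of consecutive qualifying slices, default 2.
#' @return logical.
#' @export
qualify_plaque <- function(wall_thickness_by_slice, min_thickness = 2,
                           min_slices = 2L) {
  w <- as.numeric(wall_thickness_by_slice)
  if (length(w) == 0L) stopf("wall thickness list must be non-empty")
  if (any(!is.finite(w)) || any(w < 0))
    stopf("wall thickness must be finite and non-negative")
  ok <- w > min_thickness
  if (length(ok) < min_slices) return(FALSE)
  r <- rle(ok)
  any(r$values & r$lengths >= min_slices)
}

#' Candidate IPH voxels by muscle-referenced thresholding
#'
#' Marks every plaque voxel whose intensity exceeds `ratio` times the muscle
#' reference mean. No connectivity or extent filtering is applied at this
#' stage; see [enforce_consecutive_slices()].
#'
#' @param volume a [volume3d].
#' @param plaque_mask binary array, same shape as the volume. The search is
#'   restricted to it: IPH is by definition part of the plaque.
#' @param ref a `reference_intensity` from [sample_muscle_reference()].
#' @param criterion a [threshold_criterion()].
#' @return Logical 3-D array of candidate IPH voxels.
#' @export
threshold_iph <- function(volume, plaque_mask, ref, criterion) {
  stopifnot(inherits(volume, "volume3d"),
            inherits(ref, "reference_intensity"),
            inherits(criterion, "threshold_criterion"))
  plaque_mask <- as_mask(plaque_mask, dims = dim(volume$data), "plaque_mask")
  if (ref$mean <= 0) stopf("reference mean must be > 0")
  thr <- criterion$ratio * ref$mean
  hit <- if (criterion$strict) volume$data > thr else volume$data >= thr
  plaque_mask & hit
}

#' Remove components without the required consecutive-slice support
#'
#' IPH is only accepted where hyperintensity persists over at least
#' `min_slices` consecutive slices. Connected components of the candidate
#' mask (26-connectivity by default) whose slice-index support does not
#' contain `min_slices` consecutive indices are removed; all other voxels are
#' retained. With `scope = "mask"` the rule is instead applied to the
#' thresholded mask as a whole (kept entirely or discarded entirely).
#'
#' @param mask binary 3-D array.
#' @param min_slices minimum run of consecutive occupied slices, >= 1.
#' @param connectivity 26 (default) or 6.
#' @param scope `"component"` (default) or `"mask"`.
#' @return Logical 3-D array; idempotent.
#' @export
enforce_consecutive_slices <- function(mask, min_slices = 2L,
                                       connectivity = c(26, 6),
                                       scope = c("component", "mask")) {
  mask <- as_mask(mask)
  connectivity <- match.arg(as.character(connectivity[1]), c("26", "6"))
  scope <- match.arg(scope)
  min_slices <- as.integer(min_slices)
  if (min_slices < 1L) stopf("min_slices must be >= 1")
  if (!any(mask)) return(mask)

  max_run <- function(slices) {
    occ <- rle(sort(unique(slices)) - seq_along(sort(unique(slices))))
    max(occ$lengths)
  }
  dims <- dim(mask)
  slice_of <- function(lin) ((lin - 1L) %/% (dims[1] * dims[2])) + 1L

  if (scope == "mask") {
    if (max_run(slice_of(which(mask))) >= min_slices) return(mask)
    return(array(FALSE, dims))
  }
  labels <- label_components_cpp(as.logical(mask), as.integer(dims),
                                 as.integer(connectivity))
  labels <- array(labels, dims)
  fg <- which(mask)
  lab <- labels[fg]
  sl <- slice_of(fg)
  keep_lab <- vapply(split(sl, lab), function(s) max_run(s) >= min_slices,
                     logical(1))
  keep_ids <- as.integer(names(keep_lab))[keep_lab]
  out <- array(FALSE, dims)
  out[fg[lab %in% keep_ids]] <- TRUE
  out
}

#' IPH metrics from a binary mask
#'
#' Computes the three study metrics: total IPH volume (voxel count times
#' voxel volume), maximal axial IPH volume (the largest single-slice
#' contribution, per-slice voxel count times voxel volume), and IPH length
#' (occupied slice span, inclusive, times slice thickness). An empty mask
#' yields all zeros.
#'
#' @param mask binary 3-D array.
#' @param spacing numeric (dx, dy, dz) mm.
#' @return An `iph_metrics` object: list with `total_volume_mm3`,
#'   `max_axial_volume_mm3`, `length_mm`, `n_voxels`.
#' @export
compute_metrics <- function(mask, spacing) {
  mask <- as_mask(mask)
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  vv <- prod(spacing)
  n <- sum(mask)
  if (n == 0L) {
    return(structure(list(total_volume_mm3 = 0, max_axial_volume_mm3 = 0,
                          length_mm = 0, n_voxels = 0L),
                     class = "iph_metrics"))
  }
  per_slice <- apply(mask, 3, sum)
  occ <- which(per_slice > 0)
  structure(list(
    total_volume_mm3 = n * vv,
    max_axial_volume_mm3 = max(per_slice) * vv,
    length_mm = (max(occ) - min(occ) + 1) * spacing[3],
    n_voxels = as.integer(n)), class = "iph_metrics")
}

#' Semi-automatic IPH segmentation
#'
#' The full semi-automatic pipeline: muscle reference sampling ->
#' muscle-referenced thresholding within the plaque -> consecutive-slice
#' rule -> metrics. All stage settings are recorded in the result.
#'
#' @inheritParams threshold_iph
#' @param roi an [roi_points] marking the muscle reference points.
#' @param criterion a [threshold_criterion()] or a bare ratio.
#' @param min_slices,connectivity,scope passed to
#'   [enforce_consecutive_slices()].
#' @param n_points passed to [sample_muscle_reference()].
#' @return An `iph_segmentation` object: list with `mask` (logical array),
#'   `metrics` (an `iph_metrics`), `criterion`, `reference`, and the rule
#'   settings.
#' @examples
#' s <- generate_subject(phantom_config(noise = list(sigma = 0),
#'                                      muscle = list(sd = 0),
#'                                      iph = list(intensity_ratio = 2.5)))
#' roi <- sample_roi_points(s$truth$muscle_mask, seed = 7)
#' seg <- segment_iph(s$volume, s$truth$plaque_mask, roi, 1.5)
#' seg$metrics$total_volume_mm3 == s$truth$true_iph_volume
#' @export
segment_iph <- function(volume, plaque_mask, roi, criterion,
                        min_slices = 2L, connectivity = 26,
                        scope = "component", n_points = 3L) {
  if (is.numeric(criterion)) criterion <- threshold_criterion(criterion)
  ref <- sample_muscle_reference(volume, roi, n_points = n_points)
  cand <- threshold_iph(volume, plaque_mask, ref, criterion)
  mask <- enforce_consecutive_slices(cand, min_slices = min_slices,
                                     connectivity = connectivity,
                                     scope = scope)
  structure(list(mask = mask,
                 metrics = compute_metrics(mask, volume$spacing),
                 criterion = criterion, reference = ref,
                 min_slices = as.integer(min_slices),
                 connectivity = connectivity, scope = scope),
            class = "iph_segmentation")
}

#' @export
print.iph_segmentation <- function(x, ...) {
  crit <- if (inherits(x$criterion, "threshold_criterion"))
    sprintf(">%g%% of muscle mean", 100 * x$criterion$ratio) else
      as.character(x$criterion)
  cat(sprintf(
    "<iph_segmentation> %s | total %.3f mm^3, max axial %.3f mm^3, length %.1f mm\n",
    crit, x$metrics$total_volume_mm3, x$metrics$max_axial_volume_mm3,
    x$metrics$length_mm))
  invisible(x)
}
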