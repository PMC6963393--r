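#' Configuration for one synthetic carotid-plaque phantom
#'
#' Describes a tubular vessel wall running along the slice axis, an
#' angular-sector plaque thickening of that wall, an ellipsoidal intraplaque
#' haemorrhage (IPH) embedded in the plaque, and a rectangular muscle block
#' standing in for the sternocleidomastoid reference. All positions and sizes
#' are in millimetres; the grid uses the reconstructed in-plane resolution
#' 0.31 x 0.31 mm and 1 mm slice thickness by default. The IPH intensity is
#' specified as a dimensionless multiple of the configured muscle mean, which
#' is exactly how the thresholding criteria are defined downstream.
#'
#' The geometry primitives (tube, sector, axis-aligned ellipsoid, block) are
#' deliberately simple so that ground-truth voxel counts are exact; anatomical
#' realism is not a goal.
#'
#' @param grid_shape integer (nx, ny, nz) voxels.
#' @param spacing numeric (dx, dy, dz) mm.
#' @param vessel list: `center` (x, y) mm of the centreline,
#'   `lumen_radius` mm, `wall_thickness` mm.
#' @param plaque list: `theta0` and `extent` (degrees) giving the angular
#'   sector, `thickness` mm (radial, measured from the lumen boundary;
#'   default > 2 mm so phantom plaques satisfy the wall-thickness
#'   qualification rule), `slices` 0-based (first, last) slice span.
#' @param iph list: `semi_axes` (a, b, c) mm of the axis-aligned ellipsoid,
#'   `center` (x, y, z) mm (NULL = centre of the plaque sector),
#'   `intensity_ratio` dimensionless multiple of the muscle mean.
#' @param muscle list: `corner` (x, y, z) mm, `size` (sx, sy, sz) mm,
#'   `mean` intensity (arbitrary units), `sd` intra-ROI Gaussian variability.
#' @param intensities list: `background`, `lumen`, `plaque_tissue` (NULL =
#'   muscle mean, i.e. plaque tissue isointense to muscle).
#' @param noise list: `model` ("rician" or "gaussian"), `sigma` (intensity
#'   units; 0 disables).
#' @param seed integer seed controlling muscle variability and noise.
#' @return A validated list of class `phantom_config`.
#' @seealso [generate_subject()], [cohort_spec()]
#' @export
phantom_config <- function(grid_shape = c(64, 64, 16),
                           spacing = c(0.31, 0.31, 1.0),
                           vessel = list(),
                           plaque = list(),
                           iph = list(),
                           muscle = list(),
                           intensities = list(),
                           noise = list(),
                           seed = 1L) {
  vessel <- modifyList(list(center = c(8.5, 8.5), lumen_radius = 3.0,
                            wall_thickness = 1.0), vessel)
  plaque <- modifyList(list(theta0 = -70, extent = 140, thickness = 3.2,
                            slices = c(3L, 14L)), plaque)
  iph <- modifyList(list(semi_axes = c(1.2, 1.2, 2.5), center = NULL,
                         intensity_ratio = 2.0), iph)
  muscle <- modifyList(list(corner = c(14.5, 14.5, 4.0), size = c(4, 4, 8),
                            mean = 100, sd = 5), muscle)
  intensities <- modifyList(list(background = 25, lumen = 15,
                                 plaque_tissue = NULL), intensities)
  noise <- modifyList(list(model = "rician", sigma = 5), noise)

  cfg <- structure(list(grid_shape = as.integer(grid_shape),
                        spacing = as.numeric(spacing),
                        vessel = vessel, plaque = plaque, iph = iph,
                        muscle = muscle, intensities = intensities,
                        noise = noise, seed = as.integer(seed)),
                   class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 1L))
    stopf("grid_shape must be 3 positive integers")
  if (any(cfg$spacing <= 0)) stopf("spacing components must be > 0")
  with(cfg$vessel, {
    if (lumen_radius <= 0 || wall_thickness <= 0)
      stopf("vessel radii/thicknesses must be > 0")
  })
  if (cfg$plaque$thickness <= 0) stopf("plaque thickness must be > 0")
  if (any(cfg$iph$semi_axes <= 0)) stopf("IPH semi-axes must be > 0")
  if (cfg$iph$intensity_ratio <= 0) stopf("intensity_ratio must be > 0")
  if (cfg$muscle$mean <= 0) stopf("muscle mean must be > 0")
  if (cfg$noise$sigma < 0) stopf("noise sigma must be >= 0")
  if (!cfg$noise$model %in% c("rician", "gaussian"))
    stopf("unknown noise model '%s' (use 'rician' or 'gaussian')",
          cfg$noise$model)
  invisible(cfg)
}

# voxel-centre coordinate vectors in mm
.grid_coords <- function(shape, spacing) {
  list(x = (seq_len(shape[1]) - 0.5) * spacing[1],
       y = (seq_len(shape[2]) - 0.5) * spacing[2],
       z = (seq_len(shape[3]) - 0.5) * spacing[3])
}

# Build the ground-truth masks for a config. Returns logical arrays.
.phantom_masks <- function(cfg) {
  sh <- cfg$grid_shape
  co <- .grid_coords(sh, cfg$spacing)
  cx <- cfg$vessel$center[1]; cy <- cfg$vessel$center[2]
  dx2 <- outer((co$x - cx)^2, (co$y - cy)^2, `+`)
  r <- sqrt(dx2)
  theta <- atan2(outer(rep(1, sh[1]), co$y - cy),
                 outer(co$x - cx, rep(1, sh[2]))) * 180 / pi

  r_l <- cfg$vessel$lumen_radius
  r_w <- r_l + cfg$vessel$wall_thickness
  r_p <- r_l + cfg$plaque$thickness
  lumen2d <- r <= r_l
  wall2d <- r > r_l & r <= r_w
  # angular distance to the sector centre, wrap-safe
  mid <- cfg$plaque$theta0 + cfg$plaque$extent / 2
  dtheta <- abs(((theta - mid + 180) %% 360) - 180)
  sector2d <- dtheta <= cfg$plaque$extent / 2
  plaque2d <- sector2d & r > r_l & r <= r_p

  k_span <- cfg$plaque$slices[1]:cfg$plaque$slices[2]   # 0-based
  in_span <- (seq_len(sh[3]) - 1L) %in% k_span

  lumen <- array(FALSE, sh); wall <- array(FALSE, sh); plaque <- array(FALSE, sh)
  for (k in seq_len(sh[3])) {
    lumen[, , k] <- lumen2d
    wall[, , k] <- wall2d
    if (in_span[k]) plaque[, , k] <- plaque2d
  }
  wall <- wall & !plaque

  ctr <- cfg$iph$center
  if (is.null(ctr)) {
    r_mid <- (r_l + r_p) / 2
    z_mid <- (cfg$plaque$slices[1] + cfg$plaque$slices[2] + 1) / 2 *
      cfg$spacing[3]
    ctr <- c(cx + r_mid * cos(mid * pi / 180),
             cy + r_mid * sin(mid * pi / 180), z_mid)
  }
  ax <- cfg$iph$semi_axes
  ex <- ((co$x - ctr[1]) / ax[1])^2
  ey <- ((co$y - ctr[2]) / ax[2])^2
  ez <- ((co$z - ctr[3]) / ax[3])^2
  iph <- outer(outer(ex, ey, `+`), ez, `+`) <= 1

  mc <- cfg$muscle$corner; ms <- cfg$muscle$size
  mx <- co$x > mc[1] & co$x <= mc[1] + ms[1]
  my <- co$y > mc[2] & co$y <= mc[2] + ms[2]
  mz <- co$z > mc[3] & co$z <= mc[3] + ms[3]
  muscle <- outer(outer(mx, my, `&`), mz, `&`)

  if (any(iph & !plaque))
    stopf("invalid geometry: IPH ellipsoid extends outside the plaque region")
  if (any(muscle & (lumen | wall | plaque)))
    stopf("invalid geometry: muscle block overlaps the vessel")
  if (!any(muscle)) stopf("invalid geometry: muscle block contains no voxels")

  list(lumen = lumen, wall = wall, plaque = plaque, iph = iph, muscle = muscle)
}

#' Generate one synthetic subject
#'
#' Composes the noiseless phantom (background, suppressed lumen, vessel
#' wall/plaque tissue, IPH at `intensity_ratio` times the configured muscle
#' mean, muscle voxels drawn around the muscle mean), then applies the
#' configured noise model. Deterministic for a fixed `config$seed`.
#'
#' @param config a [phantom_config()].
#' @return A list with elements `volume` (a [volume3d]) and `truth`, a
#'   `subject_truth` object carrying `plaque_mask`, `iph_mask`, `muscle_mask`
#'   (logical arrays), `true_iph_volume` (mm^3, exactly the IPH voxel count
#'   times the voxel volume), `wall_thickness_by_slice` (mm), the
#'   `intensity_ratio`, and the seed used.
#' @examples
#' s <- generate_subject(phantom_config(noise = list(sigma = 0),
#'                                      muscle = list(sd = 0)))
#' s$truth$true_iph_volume
#' @export
generate_subject <- function(config) {
  validate_phantom_config(config)
  m <- .phantom_masks(config)
  sh <- config$grid_shape
  mu_m <- config$muscle$mean
  tissue <- config$intensities$plaque_tissue %||% mu_m

  img <- array(config$intensities$background, dim = sh)
  img[m$lumen] <- config$intensities$lumen
  img[m$wall | m$plaque] <- tissue
  img[m$iph] <- config$iph$intensity_ratio * mu_m

  img <- with_seed(config$seed, {
    nm <- sum(m$muscle)
    img[m$muscle] <- rnorm(nm, mean = mu_m, sd = config$muscle$sd)
    .apply_noise(img, config$noise$model, config$noise$sigma)
  })

  k_span <- config$plaque$slices[1]:config$plaque$slices[2]
  wt <- ifelse((seq_len(sh[3]) - 1L) %in% k_span,
               config$plaque$thickness, config$vessel$wall_thickness)

  vol <- volume3d(img, spacing = config$spacing)
  truth <- structure(list(
    plaque_mask = m$plaque, iph_mask = m$iph, muscle_mask = m$muscle,
    true_iph_volume = sum(m$iph) * prod(config$spacing),
    wall_thickness_by_slice = wt,
    intensity_ratio = config$iph$intensity_ratio,
    seed = config$seed, config = config), class = "subject_truth")
  list(volume = vol, truth = truth)
}

.apply_noise <- function(img, model, sigma) {
  if (sigma == 0) return(img)
  n <- length(img)
  if (model == "rician") {
    # magnitude of complex Gaussian corruption: sqrt((v + n1)^2 + n2^2)
    array(sqrt((img + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2),
          dim = dim(img))
  } else if (model == "gaussian") {
    img + array(rnorm(n, 0, sigma), dim = dim(img))
  } else stopf("unknown noise model '%s'", model)
}

#' Apply MR magnitude noise to a volume
#'
#' `sigma = 0` returns the input unchanged. The Rician model corrupts each
#' voxel as the magnitude of a complex Gaussian,
#' `sqrt((v + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma^2)`, the standard
#' statistics of magnitude MR images; output is always non-negative. The
#' Gaussian model adds zero-mean noise and is kept for analytically simple
#' checks.
#'
#' @param volume a [volume3d].
#' @param model `"rician"` or `"gaussian"`.
#' @param sigma noise level in intensity units, >= 0.
#' @param seed integer seed.
#' @return A [volume3d] with the same spacing.
#' @export
add_noise <- function(volume, model = c("rician", "gaussian"), sigma,
                      seed = 1L) {
  stopifnot(inherits(volume, "volume3d"))
  model <- match.arg(model)
  if (sigma < 0) stopf("sigma must be >= 0")
  if (sigma == 0) return(volume)
  out <- with_seed(seed, .apply_noise(volume$data, model, sigma))
  volume3d(out, spacing = volume$spacing, origin = volume$origin)
}

#' Specification of a synthetic study cohort
#'
#' Defines how per-subject phantoms vary across the cohort: the IPH contrast
#' ratio is drawn uniformly from `ratio_range` and the IPH ellipsoid
#' semi-axes from `inplane_range` / `axial_range` (in-plane a = b drawn once,
#' axial c separately). Per-subject seeds are derived reproducibly from the
#' master seed, so a cohort is a pure function of its spec.
#'
#' @param n_subjects number of subjects (>= 2; agreement statistics are
#'   undefined for fewer). Default 40, the size of a typical single-centre
#'   carotid-plaque series.
#' @param ratio_range IPH intensity ratio bounds (dimensionless, > 0).
#'   Default `c(1.3, 3.0)` spans sub-threshold to strongly hyperintense IPH.
#' @param inplane_range,axial_range IPH ellipsoid semi-axis bounds in mm.
#' @param template a [phantom_config()] shared by all subjects.
#' @param master_seed integer.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 40L,
                        ratio_range = c(1.3, 3.0),
                        inplane_range = c(0.8, 1.4),
                        axial_range = c(1.5, 4.5),
                        template = phantom_config(),
                        master_seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 2L)
    stopf("n_subjects must be >= 2 (agreement statistics are undefined below that)")
  if (any(ratio_range <= 0)) stopf("ratio_range must be > 0")
  if (diff(ratio_range) < 0 || diff(inplane_range) < 0 || diff(axial_range) < 0)
    stopf("range bounds must be non-decreasing")
  structure(list(n_subjects = n_subjects, ratio_range = ratio_range,
                 inplane_range = inplane_range, axial_range = axial_range,
                 template = template, master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return A list of `n_subjects` elements, each as returned by
#'   [generate_subject()].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  draws <- with_seed(spec$master_seed, list(
    seeds = sample.int(2147483646L, n),
    ratios = runif(n, spec$ratio_range[1], spec$ratio_range[2]),
    inplane = runif(n, spec$inplane_range[1], spec$inplane_range[2]),
    axial = runif(n, spec$axial_range[1], spec$axial_range[2])))
  lapply(seq_len(n), function(i) {
    cfg <- spec$template
    cfg$seed <- draws$seeds[i]
    cfg$iph$intensity_ratio <- draws$ratios[i]
    cfg$iph$semi_axes <- c(draws$inplane[i], draws$inplane[i], draws$axial[i])
    generate_subject(cfg)
  })
}

#' Sample reference ROI points from a mask
#'
#' Draws `n` distinct voxel positions inside a mask, emulating a reader
#' placing reference points in the sternocleidomastoid muscle.
#'
#' @param mask logical 3-D array.
#' @param n number of points (default 3, the reference protocol).
#' @param seed integer.
#' @param label ROI label.
#' @return An [roi_points] object with 0-based coordinates.
#' @export
sample_roi_points <- function(mask, n = 3L, seed = 1L, label = "SCM") {
  mask <- as_mask(mask)
  idx <- which(mask)
  if (length(idx) < n)
    stopf("mask has %d voxel(s), cannot sample %d points", length(idx), n)
  pick <- with_seed(seed, sample(idx, n))
  dims <- dim(mask)
  pick0 <- pick - 1L
  i <- pick0 %% dims[1]
  j <- (pick0 %/% dims[1]) %% dims[2]
  k <- pick0 %/% (dims[1] * dims[2])
  roi_points(cbind(i, j, k), label = label, grid_shape = dims)
}

#' Write a cohort to disk
#'
#' Writes, per subject, the volume and the three ground-truth masks as
#' NIfTI (.nii.gz), the truth parameters as a JSON sidecar, and a cohort
#' manifest CSV (subject id, seed, intensity ratio, true IPH volume mm^3).
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    id <- sprintf("subj%03d", i)
    sp <- s$volume$spacing
    write_volume(s$volume, file.path(dir, paste0(id, "_vol.nii.gz")))
    for (mk in c("plaque", "iph", "muscle")) {
      write_volume(volume3d(array(as.numeric(s$truth[[paste0(mk, "_mask")]]),
                                  dim = dim(s$volume$data)), spacing = sp),
                   file.path(dir, sprintf("%s_%s.nii.gz", id, mk)), mask = TRUE)
    }
    jsonlite::write_json(
      list(subject = id, seed = s$truth$seed,
           intensity_ratio = s$truth$intensity_ratio,
           true_iph_volume_mm3 = s$truth$true_iph_volume),
      file.path(dir, paste0(id, "_truth.json")), auto_unbox = TRUE, digits = NA)
    data.frame(subject = id, seed = s$truth$seed,
               intensity_ratio = s$truth$intensity_ratio,
               true_iph_volume_mm3 = s$truth$true_iph_volume)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
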