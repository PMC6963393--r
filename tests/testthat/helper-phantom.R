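# Shared phantom configurations for the tests.

# fully deterministic phantom: no acquisition noise, no muscle variability
quiet_config <- function(ratio = 2.5, seed = 1L, iph = list(),
                         muscle = list(), ...) {
  phantom_config(noise = list(sigma = 0),
                 muscle = modifyList(list(sd = 0), muscle),
                 iph = modifyList(list(intensity_ratio = ratio), iph),
                 seed = seed, ...)
}

# small random volume + plaque + 3-point ROI for oracle-equivalence checks;
# intensities span the reference thresholds so masks are non-trivial
random_segmentation_case <- function(dims = c(20, 20, 8)) {
  data <- array(runif(prod(dims), 50, 250), dim = dims)
  plaque <- array(runif(prod(dims)) < 0.35, dim = dims)
  # three reference points with values near 100 so ratios bite mid-range
  pts <- cbind(sample(0:(dims[1] - 1), 3), sample(0:(dims[2] - 1), 3),
               sample(0:(dims[3] - 1), 3))
  roi <- roi_points(pts, grid_shape = dims)
  for (r in 1:3) data[pts[r, 1] + 1, pts[r, 2] + 1, pts[r, 3] + 1] <-
    runif(1, 90, 110)
  list(volume = volume3d(data, spacing = c(0.31, 0.31, 1)),
       plaque = plaque, roi = roi)
}
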