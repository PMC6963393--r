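test_that("noiseless composition places exact intensities", {
  s <- generate_subject(quiet_config(ratio = 2.5))
  expect_true(all(s$volume$data[s$truth$iph_mask] == 250))
  tissue <- s$truth$plaque_mask & !s$truth$iph_mask
  expect_true(all(s$volume$data[tissue] == 100))
  expect_true(all(s$volume$data[s$truth$muscle_mask] == 100))
})

test_that("generation is a pure function of the seed", {
  a <- generate_subject(phantom_config(seed = 77))
  b <- generate_subject(phantom_config(seed = 77))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$iph_mask, b$truth$iph_mask)
  c <- generate_subject(phantom_config(seed = 78))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("true IPH volume equals brute-force ellipsoid voxel count x voxel volume", {
  cfg <- quiet_config()
  s <- generate_subject(cfg)
  # independent count: test every voxel centre against the ellipsoid
  sh <- cfg$grid_shape; sp <- cfg$spacing
  ax <- cfg$iph$semi_axes
  r_mid <- cfg$vessel$lumen_radius + cfg$plaque$thickness / 2
  mid <- (cfg$plaque$theta0 + cfg$plaque$extent / 2) * pi / 180
  ctr <- c(cfg$vessel$center[1] + r_mid * cos(mid),
           cfg$vessel$center[2] + r_mid * sin(mid),
           (cfg$plaque$slices[1] + cfg$plaque$slices[2] + 1) / 2 * sp[3])
  K <- 0L
  for (k in seq_len(sh[3])) for (j in seq_len(sh[2])) for (i in seq_len(sh[1])) {
    p <- (c(i, j, k) - 0.5) * sp
    if (sum(((p - ctr) / ax)^2) <= 1) K <- K + 1L
  }
  expect_gt(K, 0)
  expect_identical(sum(s$truth$iph_mask), K)
  expect_equal(s$truth$true_iph_volume, K * prod(sp))
})

test_that("degenerate geometry is rejected with a named constraint", {
  expect_error(generate_subject(quiet_config(iph = list(semi_axes = c(6, 6, 6)))),
               "outside the plaque")
  expect_error(generate_subject(
    quiet_config(muscle = list(corner = c(8, 8, 4)))), "overlaps the vessel")
  expect_error(phantom_config(iph = list(intensity_ratio = -1)),
               "intensity_ratio")
  expect_error(phantom_config(noise = list(model = "poisson")),
               "unknown noise model")
})

test_that("raising the contrast ratio never lowers noiseless IPH intensities", {
  ratios <- c(1.3, 1.7, 2.2, 3.0)
  vols <- lapply(ratios, function(r) generate_subject(quiet_config(ratio = r)))
  for (i in seq_along(ratios)[-1]) {
    m <- vols[[i]]$truth$iph_mask
    expect_true(all(vols[[i]]$volume$data[m] >= vols[[i - 1]]$volume$data[m]))
  }
})

test_that("sigma = 0 noise is the identity and unknown models error", {
  v <- volume3d(array(runif(64, 10, 50), dim = c(4, 4, 4)))
  expect_identical(add_noise(v, "rician", 0), v)
  expect_identical(add_noise(v, "gaussian", 0), v)
  expect_error(add_noise(v, "salt", 1), "arg")
  expect_error(add_noise(v, "rician", -1), "sigma")
})

test_that("rician noise matches the closed-form Rician mean and stays non-negative", {
  A <- 20; sig <- 4
  v <- volume3d(array(A, dim = c(50, 50, 48)))
  noisy <- add_noise(v, "rician", sig, seed = 99)
  expect_true(all(noisy$data >= 0))
  m <- mean(noisy$data)
  se <- sd(noisy$data) / sqrt(length(noisy$data))
  expect_lt(abs(m - oracle_rician_mean(A, sig)), 3 * se)
})

test_that("gaussian noise has the requested variance on a constant image", {
  sig <- 7
  v <- volume3d(array(100, dim = c(40, 40, 40)))
  noisy <- add_noise(v, "gaussian", sig, seed = 5)
  n <- length(noisy$data)
  # chi-square sampling band for the sample variance
  expect_lt(abs(var(as.numeric(noisy$data)) - sig^2), 5 * sig^2 * sqrt(2 / n))
  expect_lt(abs(mean(noisy$data) - 100), 5 * sig / sqrt(n))
})

test_that("cohorts have the requested size and are reproducible", {
  spec <- cohort_spec(n_subjects = 40, master_seed = 3)
  coh <- generate_cohort(spec)
  expect_length(coh, 40)
  coh2 <- generate_cohort(spec)
  expect_identical(lapply(coh, function(s) s$volume$data),
                   lapply(coh2, function(s) s$volume$data))
  ratios <- vapply(coh, function(s) s$truth$intensity_ratio, numeric(1))
  expect_true(all(ratios >= 1.3 & ratios <= 3.0))
  expect_error(cohort_spec(n_subjects = 1), "n_subjects")
})

test_that("a degenerate ratio distribution fixes every subject's contrast", {
  spec <- cohort_spec(n_subjects = 4, ratio_range = c(2.5, 2.5),
                      master_seed = 9)
  coh <- generate_cohort(spec)
  expect_equal(vapply(coh, function(s) s$truth$intensity_ratio, numeric(1)),
               rep(2.5, 4))
})

test_that("sampled muscle ROI points land in the muscle mask", {
  s <- generate_subject(phantom_config(seed = 2))
  roi <- sample_roi_points(s$truth$muscle_mask, n = 3, seed = 10)
  expect_equal(nrow(roi$points), 3)
  for (r in 1:3) {
    p <- roi$points[r, ] + 1
    expect_true(s$truth$muscle_mask[p[1], p[2], p[3]])
  }
})
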