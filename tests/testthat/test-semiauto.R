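test_that("muscle reference is the arithmetic mean of the sampled points", {
  data <- array(1, dim = c(8, 8, 4))
  data[3, 3, 2] <- 100; data[4, 3, 2] <- 110; data[5, 3, 2] <- 120
  v <- volume3d(data)
  roi <- roi_points(rbind(c(2, 2, 1), c(3, 2, 1), c(4, 2, 1)))
  ref <- sample_muscle_reference(v, roi)
  expect_equal(ref$mean, 110)
  expect_equal(sort(ref$point_values), c(100, 110, 120))

  data[, , ] <- 42
  ref2 <- sample_muscle_reference(volume3d(data), roi)
  expect_equal(ref2$mean, 42)
})

test_that("the 3-point reference policy is enforced and relaxable", {
  v <- volume3d(array(50, dim = c(8, 8, 4)))
  roi2 <- roi_points(rbind(c(1, 1, 1), c(2, 2, 2)))
  expect_error(sample_muscle_reference(v, roi2), "exactly 3")
  expect_equal(sample_muscle_reference(v, roi2, n_points = NULL)$mean, 50)
  # non-positive reference mean makes ratios meaningless
  v0 <- volume3d(array(0, dim = c(8, 8, 4)))
  expect_error(sample_muscle_reference(v0, roi2, n_points = NULL), "> 0")
})

test_that("plaque qualification needs > 2 mm in two adjacent slices, strictly", {
  expect_true(qualify_plaque(c(1.8, 2.1, 2.3, 1.9)))
  expect_false(qualify_plaque(c(2.1, 1.9, 2.1, 1.9)))
  expect_false(qualify_plaque(c(2.0, 2.0)))
  expect_true(qualify_plaque(c(2.5, 2.5)))
  expect_false(qualify_plaque(c(2.5)))
  expect_error(qualify_plaque(numeric(0)), "non-empty")
  expect_error(qualify_plaque(c(2, -1)), "non-negative")
})

test_that("thresholding is strict and restricted to the plaque", {
  dims <- c(10, 10, 4)
  data <- array(160, dim = dims)          # 1.6 x reference everywhere
  data[1, 1, 1] <- 100; data[2, 1, 1] <- 100; data[3, 1, 1] <- 100
  v <- volume3d(data)
  roi <- roi_points(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  ref <- sample_muscle_reference(v, roi)
  plaque <- array(FALSE, dims); plaque[4:7, 4:7, 2:3] <- TRUE

  m150 <- threshold_iph(v, plaque, ref, threshold_criterion(1.5))
  expect_identical(m150, plaque)
  expect_false(any(threshold_iph(v, plaque, ref, threshold_criterion(1.75))))
  expect_false(any(threshold_iph(v, plaque, ref, threshold_criterion(2.0))))

  # a voxel exactly at the threshold is excluded under strict comparison
  data[5, 5, 2] <- 150
  v <- volume3d(data)
  expect_false(threshold_iph(v, plaque, ref, threshold_criterion(1.5))[5, 5, 2])
  expect_true(threshold_iph(v, plaque, ref,
                            threshold_criterion(1.5, strict = FALSE))[5, 5, 2])
  expect_error(threshold_iph(v, plaque[, , 1:2], ref, threshold_criterion(1.5)),
               "shape")
})

test_that("consecutive-slice rule removes single-slice components and keeps pairs", {
  dims <- c(8, 8, 6)
  m <- array(FALSE, dims)
  m[2:3, 2:3, 2] <- TRUE                 # one slice only -> removed
  m[6:7, 6:7, 4:5] <- TRUE               # spans slices 4-5 -> kept
  out <- enforce_consecutive_slices(m)
  expect_false(any(out[, , 2]))
  expect_identical(out[6:7, 6:7, 4:5], m[6:7, 6:7, 4:5])
  expect_equal(sum(out), 8)

  # two single-slice components on slices 2 and 4 (not adjacent): both removed
  m2 <- array(FALSE, dims)
  m2[2, 2, 2] <- TRUE; m2[2, 2, 4] <- TRUE
  expect_false(any(enforce_consecutive_slices(m2)))

  expect_error(enforce_consecutive_slices(m, min_slices = 0), "min_slices")
})

test_that("consecutive-slice rule is idempotent and has a whole-mask variant", {
  set.seed(31)
  for (rep in 1:5) {
    m <- array(runif(16 * 16 * 6) < 0.2, dim = c(16, 16, 6))
    once <- enforce_consecutive_slices(m)
    expect_identical(enforce_consecutive_slices(once), once)
  }
  m <- array(FALSE, c(4, 4, 4)); m[1, 1, 2] <- TRUE
  expect_false(any(enforce_consecutive_slices(m, scope = "mask")))
  m[1, 1, 3] <- TRUE
  expect_identical(enforce_consecutive_slices(m, scope = "mask"), m)
})

test_that("component labelling matches the flood-fill oracle", {
  set.seed(32)
  for (rep in 1:5) {
    m <- array(runif(12 * 12 * 5) < 0.3, dim = c(12, 12, 5))
    for (conn in c(26, 6)) {
      lab <- array(iphquant:::label_components_cpp(as.logical(m), dim(m),
                                                   conn), dim(m))
      ref <- oracle_label_components(m, conn)
      # same partition: labels must be a relabelling of the oracle's
      expect_identical(lab > 0, ref > 0)
      expect_equal(max(lab), max(ref))
      key <- paste(lab[m], ref[m])
      expect_equal(length(unique(key)), max(ref))
    }
  }
})

test_that("metrics follow count x voxel volume, per-slice maxima and slice span", {
  dims <- c(6, 6, 5)
  sp <- c(0.31, 0.31, 1.0)
  m <- array(FALSE, dims)
  m[1:5, 1, 3] <- TRUE; m[1, 1, 4] <- TRUE   # 5 voxels slice 3, 1 voxel slice 4
  met <- compute_metrics(m, sp)
  vv <- prod(sp)
  expect_equal(met$total_volume_mm3, 6 * vv)
  expect_equal(met$max_axial_volume_mm3, 5 * vv)
  expect_equal(met$length_mm, 2 * 1.0)

  m10 <- array(FALSE, dims); m10[1:5, 1:2, 2] <- TRUE
  expect_equal(compute_metrics(m10, sp)$total_volume_mm3, 10 * 0.0961)

  empty <- compute_metrics(array(FALSE, dims), sp)
  expect_equal(unlist(empty[c("total_volume_mm3", "max_axial_volume_mm3",
                              "length_mm")]), c(total_volume_mm3 = 0,
                                                max_axial_volume_mm3 = 0,
                                                length_mm = 0))
})

test_that("noiseless phantoms are recovered exactly; thresholds order detection", {
  s <- generate_subject(quiet_config(ratio = 2.5))
  roi <- sample_roi_points(s$truth$muscle_mask, seed = 7)
  for (r in c(1.5, 1.75, 2.0)) {
    seg <- segment_iph(s$volume, s$truth$plaque_mask, roi, r)
    expect_identical(seg$mask, s$truth$iph_mask)
    expect_equal(seg$metrics$total_volume_mm3, s$truth$true_iph_volume)
  }
  s16 <- generate_subject(quiet_config(ratio = 1.6))
  roi <- sample_roi_points(s16$truth$muscle_mask, seed = 7)
  expect_gt(segment_iph(s16$volume, s16$truth$plaque_mask, roi,
                        1.5)$metrics$total_volume_mm3, 0)
  expect_equal(segment_iph(s16$volume, s16$truth$plaque_mask, roi,
                           1.75)$metrics$total_volume_mm3, 0)
  expect_equal(segment_iph(s16$volume, s16$truth$plaque_mask, roi,
                           2.0)$metrics$total_volume_mm3, 0)
})

test_that("full segmentation matches the naive loop oracle bit-exactly", {
  set.seed(33)
  for (rep in 1:6) {
    case <- random_segmentation_case()
    ratio <- sample(c(1.5, 1.75, 2.0), 1)
    seg <- segment_iph(case$volume, case$plaque, case$roi, ratio)
    ora <- oracle_segment_iph(case$volume, case$plaque, case$roi, ratio)
    expect_identical(seg$mask, ora$mask)
    expect_equal(seg$metrics$total_volume_mm3, ora$total_volume_mm3)
    expect_equal(seg$metrics$max_axial_volume_mm3, ora$max_axial_volume_mm3)
    expect_equal(seg$metrics$length_mm, ora$length_mm)
  }
})

test_that("segmentation is invariant to global intensity rescaling", {
  set.seed(34)
  case <- random_segmentation_case()
  seg1 <- segment_iph(case$volume, case$plaque, case$roi, 1.5)
  for (c_scale in c(0.25, 3, 117)) {
    vs <- volume3d(case$volume$data * c_scale, spacing = case$volume$spacing)
    seg2 <- segment_iph(vs, case$plaque, case$roi, 1.5)
    expect_identical(seg2$mask, seg1$mask)
  }
})

test_that("threshold masks are nested and volumes ordered on noisy phantoms", {
  spec <- cohort_spec(n_subjects = 12, master_seed = 35)
  for (s in generate_cohort(spec)) {
    roi <- sample_roi_points(s$truth$muscle_mask, seed = s$truth$seed)
    m150 <- segment_iph(s$volume, s$truth$plaque_mask, roi, 1.5)
    m175 <- segment_iph(s$volume, s$truth$plaque_mask, roi, 1.75)
    m200 <- segment_iph(s$volume, s$truth$plaque_mask, roi, 2.0)
    expect_true(all(m200$mask <= m175$mask))
    expect_true(all(m175$mask <= m150$mask))
    expect_true(m200$metrics$total_volume_mm3 <= m175$metrics$total_volume_mm3)
    expect_true(m175$metrics$total_volume_mm3 <= m150$metrics$total_volume_mm3)
  }
})
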