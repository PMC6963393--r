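#' Configuration for the in-silico agreement study
#'
#' Assembles everything needed to rerun the study design end to end on
#' synthetic data: the cohort, the semi-automatic threshold criteria, the
#' level-set proxy standing in for the manual arm, the ICC model, and the
#' planned one-sided ICC comparisons.
#'
#' @param cohort a [cohort_spec()].
#' @param thresholds numeric vector of muscle-referenced ratios
#'   (default `c(1.5, 1.75, 2.0)`, i.e. the 150%/175%/200% criteria).
#' @param levelset a [levelset_params()].
#' @param icc_model ICC form passed to [icc()].
#' @param comparisons list of length-2 character vectors naming method pairs
#'   to test one-sidedly (H1: first has higher ICC against the manual arm
#'   than the second). Methods are named `"150%"`, `"175%"`, `"200%"` after
#'   their ratios. Default: 150% vs 200% and 175% vs 200%.
#' @param alpha significance level for the adjusted p-values.
#' @param manual_arm `"levelset"` (default) or `"truth"`; the latter uses
#'   the ground-truth IPH volumes as the manual arm, useful for statistical
#'   checks uncontaminated by segmentation error.
#' @param n_roi_points reference points sampled in the muscle, default 3.
#' @param seed master seed; overrides `cohort$master_seed` when not `NULL`.
#' @return A `study_config` object.
#' @export
study_config <- function(cohort = cohort_spec(),
                         thresholds = c(1.5, 1.75, 2.0),
                         levelset = levelset_params(),
                         icc_model = "twoway-agreement",
                         comparisons = list(c("150%", "200%"),
                                            c("175%", "200%")),
                         alpha = 0.05,
                         manual_arm = c("levelset", "truth"),
                         n_roi_points = 3L,
                         seed = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(levelset, "levelset_params"))
  if (length(thresholds) < 1L || any(thresholds <= 0))
    stopf("thresholds must be positive ratios")
  if (length(comparisons) > 0 && length(thresholds) < 2L)
    stopf("at least 2 thresholds are required for comparisons")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  if (!is.null(seed)) cohort$master_seed <- as.integer(seed)
  structure(list(cohort = cohort, thresholds = sort(thresholds,
                                                    decreasing = FALSE),
                 levelset = levelset, icc_model = icc_model,
                 comparisons = comparisons, alpha = alpha,
                 manual_arm = match.arg(manual_arm),
                 n_roi_points = as.integer(n_roi_points)),
            class = "study_config")
}

method_label <- function(ratio) sprintf("%g%%", 100 * ratio)

#' Run the full in-silico agreement study
#'
#' Generates the cohort, checks each subject's plaque qualification, runs
#' the level-set manual proxy and every threshold criterion, and computes
#' the agreement tables: per-method ICC against the manual arm with 95% CI
#' and interpretation band, and the planned one-sided Fisher z comparisons
#' with Bonferroni adjustment over the comparisons actually run.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, writes `metrics.csv`,
#'   `agreement.json`, `comparisons.json`, `plot_data.csv` and the cohort
#'   manifest there.
#' @param write_masks also write per-subject NIfTI masks under `out_dir`.
#' @param verbose print per-stage progress.
#' @return A `study_result`: list with `metrics` (long data frame: subject,
#'   method, total/max-axial volume, length), `icc_table`, `comparison_table`,
#'   `truth` (per-subject ratio and true volume) and `provenance`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      write_masks = FALSE, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  say("generating cohort of %d subjects (seed %d)",
      config$cohort$n_subjects, config$cohort$master_seed)
  cohort <- generate_cohort(config$cohort)
  n <- length(cohort)
  labels <- vapply(config$thresholds, method_label, character(1))

  rows <- vector("list", n)
  manual_vol <- numeric(n)
  masks <- if (write_masks) vector("list", n)
  for (i in seq_len(n)) {
    s <- cohort[[i]]
    id <- sprintf("subj%03d", i)
    if (!qualify_plaque(s$truth$wall_thickness_by_slice))
      stopf("subject %s: plaque does not satisfy the wall-thickness rule", id)
    roi <- sample_roi_points(s$truth$muscle_mask, n = config$n_roi_points,
                             seed = s$truth$seed)
    segs <- list()

    manual <- if (config$manual_arm == "levelset") {
      seg <- segment_levelset(s$volume, s$truth$plaque_mask, config$levelset)
      segs[["manual"]] <- seg
      seg$metrics
    } else {
      compute_metrics(s$truth$iph_mask, s$volume$spacing)
    }
    manual_vol[i] <- manual$total_volume_mm3

    sub_rows <- list(data.frame(subject = id, method = "manual",
                                total_volume_mm3 = manual$total_volume_mm3,
                                max_axial_volume_mm3 = manual$max_axial_volume_mm3,
                                length_mm = manual$length_mm))
    for (t in seq_along(config$thresholds)) {
      seg <- segment_iph(s$volume, s$truth$plaque_mask, roi,
                         config$thresholds[t], n_points = config$n_roi_points)
      segs[[labels[t]]] <- seg
      sub_rows[[t + 1L]] <- data.frame(
        subject = id, method = labels[t],
        total_volume_mm3 = seg$metrics$total_volume_mm3,
        max_axial_volume_mm3 = seg$metrics$max_axial_volume_mm3,
        length_mm = seg$metrics$length_mm)
    }
    rows[[i]] <- do.call(rbind, sub_rows)
    if (write_masks) masks[[i]] <- segs
    say("  %s done (ratio %.2f, true %.2f mm^3)", id,
        s$truth$intensity_ratio, s$truth$true_iph_volume)
  }
  metrics <- do.call(rbind, rows)

  say("computing agreement statistics")
  icc_rows <- lapply(seq_along(labels), function(t) {
    v <- metrics$total_volume_mm3[metrics$method == labels[t]]
    est <- icc(manual_vol, v, model = config$icc_model)
    data.frame(method = labels[t], icc = est$value, ci_low = est$ci_low,
               ci_high = est$ci_high, band = est$band, n = est$n,
               model = est$model)
  })
  icc_table <- do.call(rbind, icc_rows)

  comparison_table <- NULL
  if (length(config$comparisons) > 0) {
    ests <- lapply(labels, function(l) {
      icc(manual_vol, metrics$total_volume_mm3[metrics$method == l],
          model = config$icc_model)
    })
    names(ests) <- labels
    m <- length(config$comparisons)
    comp_rows <- lapply(config$comparisons, function(pair) {
      cmp <- compare_icc(ests[[pair[1]]], ests[[pair[2]]],
                         alternative = "greater")
      data.frame(hypothesis = sprintf("ICC(manual, %s) > ICC(manual, %s)",
                                      pair[1], pair[2]),
                 statistic = cmp$statistic, p_raw = cmp$p_raw,
                 stringsAsFactors = FALSE)
    })
    comparison_table <- do.call(rbind, comp_rows)
    comparison_table$p_adjusted <- bonferroni(comparison_table$p_raw, m = m)
    comparison_table$m <- m
    comparison_table$significant <- comparison_table$p_adjusted < config$alpha
  }

  truth <- data.frame(
    subject = sprintf("subj%03d", seq_len(n)),
    intensity_ratio = vapply(cohort, function(s) s$truth$intensity_ratio,
                             numeric(1)),
    true_iph_volume_mm3 = vapply(cohort, function(s) s$truth$true_iph_volume,
                                 numeric(1)))

  result <- structure(list(
    metrics = metrics, icc_table = icc_table,
    comparison_table = comparison_table, truth = truth,
    provenance = list(
      seed = config$cohort$master_seed,
      n_subjects = n,
      thresholds = config$thresholds,
      icc_model = config$icc_model,
      manual_arm = config$manual_arm,
      alpha = config$alpha,
      package_version = as.character(packageVersion("iphquant")),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))),
    class = "study_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    write.csv(export_comparison_plot_data(result),
              file.path(out_dir, "plot_data.csv"), row.names = FALSE)
    jsonlite::write_json(icc_table, file.path(out_dir, "agreement.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    if (!is.null(comparison_table))
      jsonlite::write_json(comparison_table,
                           file.path(out_dir, "comparisons.json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA)
    write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    if (write_masks) {
      for (i in seq_len(n)) {
        sp <- cohort[[i]]$volume$spacing
        for (nm in names(masks[[i]])) {
          safe <- gsub("%", "pct", nm, fixed = TRUE)
          write_volume(
            volume3d(array(as.numeric(masks[[i]][[nm]]$mask),
                           dim = dim(cohort[[i]]$volume$data)), spacing = sp),
            file.path(out_dir, sprintf("subj%03d_%s.nii.gz", i, safe)),
            mask = TRUE)
        }
      }
    }
  }
  result
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> n = %d subjects, seed %d\n",
              x$provenance$n_subjects, x$provenance$seed))
  cat("\nICC vs manual arm:\n")
  print(x$icc_table, row.names = FALSE)
  if (!is.null(x$comparison_table)) {
    cat("\nPlanned one-sided comparisons (Bonferroni-adjusted):\n")
    print(x$comparison_table[, c("hypothesis", "statistic", "p_adjusted",
                                 "significant")], row.names = FALSE)
  }
  invisible(x)
}

#' Per-subject volume table for plotting
#'
#' Long-format table (one row per subject x method) of total IPH volumes,
#' the data behind a per-patient method-comparison chart.
#'
#' @param result a `study_result` from [run_study()].
#' @return data frame with columns `subject`, `method`, `total_volume_mm3`.
#' @export
export_comparison_plot_data <- function(result) {
  stopifnot(inherits(result, "study_result"))
  out <- result$metrics[, c("subject", "method", "total_volume_mm3")]
  rownames(out) <- NULL
  out
}
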