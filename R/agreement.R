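#' Intraclass correlation coefficient for paired measurements
#'
#' Single-rater ICC between two (or more) measurement methods applied to the
#' same subjects, computed from the two-way subjects-by-methods ANOVA mean
#' squares. Three standard forms are available:
#'
#' * `"twoway-agreement"` (default) — two-way random effects, absolute
#'   agreement, single measurement (ICC(2,1) in the Shrout-Fleiss
#'   nomenclature). Appropriate when the quantity itself (here an IPH volume
#'   in mm^3) must match across methods, so systematic method offsets count
#'   against agreement.
#' * `"twoway-consistency"` — two-way mixed effects, consistency, single
#'   measurement (ICC(3,1)); invariant to adding a constant to one method.
#' * `"oneway"` — one-way random effects (ICC(1,1)).
#'
#' The default 95% confidence interval uses the Fisher z transform with
#' standard error `1/sqrt(n - 3)`; `ci_method = "f"` gives the exact F-based
#' (Shrout-Fleiss) interval instead, with a Satterthwaite approximation for
#' the agreement form.
#'
#' @param values_a,values_b numeric vectors of per-subject measurements by
#'   the two methods (same units, same subject order). Alternatively
#'   `values_a` may be an n x k matrix of k >= 2 methods and `values_b`
#'   omitted.
#' @param model ICC form, see above.
#' @param ci_method `"fisher-z"` (default) or `"f"`.
#' @param conf confidence level, default 0.95.
#' @param ci_floor smallest n for which an interval is reported (default 5);
#'   below it the bounds are `NA` with a warning.
#' @return An `icc_estimate`: list with `value`, `ci_low`, `ci_high`, `n`,
#'   `k`, `model`, `band` (see [interpret_icc()]), `conf`, `ci_method`, and
#'   the ANOVA mean squares in `ms`.
#' @examples
#' set.seed(1)
#' s <- rnorm(20, 50, 10)
#' icc(s + rnorm(20, 0, 3), s + rnorm(20, 0, 3))
#' @export
icc <- function(values_a, values_b = NULL,
                model = c("twoway-agreement", "twoway-consistency", "oneway"),
                ci_method = c("fisher-z", "f"), conf = 0.95, ci_floor = 5L) {
  model <- match.arg(model)
  ci_method <- match.arg(ci_method)
  Y <- if (is.matrix(values_a)) values_a else cbind(values_a, values_b)
  if (ncol(Y) < 2L) stopf("need at least two methods")
  if (any(!is.finite(Y))) stopf("measurements must be finite")
  n <- nrow(Y); k <- ncol(Y)
  if (n < 3L) stopf("need at least 3 subjects, got %d", n)

  ms <- .icc_mean_squares(Y)
  if (is.null(ms)) stopf("zero total variance: ICC undefined")
  msr <- ms[["msr"]]; msc <- ms[["msc"]]
  mse <- ms[["mse"]]; msw <- ms[["msw"]]
  value <- .icc_from_ms(ms, n, k, model)

  ci <- c(NA_real_, NA_real_)
  if (n < ci_floor) {
    warning(sprintf("n = %d below CI floor (%d); interval not reported",
                    n, ci_floor))
  } else if (ci_method == "fisher-z") {
    ci <- fisher_z_ci(value, n, conf)
  } else {
    ci <- .icc_f_ci(value, n, k, msr, msc, mse, msw, model, conf)
  }

  structure(list(value = value, ci_low = ci[1], ci_high = ci[2],
                 n = n, k = k, model = model,
                 band = interpret_icc(max(value, -1)), conf = conf,
                 ci_method = ci_method,
                 ms = c(msr = msr, msc = msc, mse = mse, msw = msw)),
            class = "icc_estimate")
}

# two-way subjects-by-methods ANOVA mean squares; NULL if no variance at all
.icc_mean_squares <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  gm <- mean(Y)
  ss_total <- sum((Y - gm)^2)
  if (ss_total <= 0) return(NULL)
  ss_rows <- k * sum((rowMeans(Y) - gm)^2)
  ss_cols <- n * sum((colMeans(Y) - gm)^2)
  ss_err <- max(ss_total - ss_rows - ss_cols, 0)
  c(msr = ss_rows / (n - 1),
    msc = ss_cols / (k - 1),
    mse = ss_err / ((n - 1) * (k - 1)),
    msw = (ss_cols + ss_err) / (n * (k - 1)))
}

.icc_from_ms <- function(ms, n, k, model) {
  msr <- ms[["msr"]]; msc <- ms[["msc"]]
  mse <- ms[["mse"]]; msw <- ms[["msw"]]
  value <- switch(model,
    "oneway" = (msr - msw) / (msr + (k - 1) * msw),
    "twoway-consistency" = (msr - mse) / (msr + (k - 1) * mse),
    "twoway-agreement" =
      (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse)))
  min(value, 1)
}

# Fisher-z interval for a correlation-type coefficient
fisher_z_ci <- function(r, n, conf = 0.95) {
  if (r >= 1) return(c(1, 1))
  if (n <= 3) return(c(NA_real_, NA_real_))
  # estimates at or below -1 (possible for the agreement form on adversarial
  # small samples) are clamped to the transform's open domain
  r <- max(r, -1 + .Machine$double.eps)
  half <- qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
  z <- fisher_z(r)
  sort(c(fisher_z_inv(z - half), fisher_z_inv(z + half)))
}

# exact F (oneway/consistency) and Satterthwaite (agreement) intervals
.icc_f_ci <- function(r, n, k, msr, msc, mse, msw, model, conf) {
  a <- 1 - conf
  if (model == "oneway") {
    f <- msr / msw
    df2 <- n * (k - 1)
    fl <- f / qf(1 - a / 2, n - 1, df2)
    fu <- f * qf(1 - a / 2, df2, n - 1)
    return(c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1)))
  }
  if (model == "twoway-consistency") {
    f <- msr / mse
    df2 <- (n - 1) * (k - 1)
    fl <- f / qf(1 - a / 2, n - 1, df2)
    fu <- f * qf(1 - a / 2, df2, n - 1)
    return(c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1)))
  }
  # agreement: Satterthwaite degrees of freedom (Shrout-Fleiss / McGraw-Wong)
  fj <- msc / mse
  vn <- (k - 1) * (n - 1) *
    (k * r * fj + n * (1 + (k - 1) * r) - k * r)^2
  vd <- (n - 1) * k^2 * r^2 * fj^2 +
    (n * (1 + (k - 1) * r) - k * r)^2
  v <- vn / vd
  fl <- qf(1 - a / 2, n - 1, v)
  fu <- qf(1 - a / 2, v, n - 1)
  lo <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  c(lo, hi)
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf("ICC (%s, n = %d): %.3f, %d%% CI (%.3f, %.3f) - %s\n",
              x$model, x$n, x$value, round(100 * x$conf),
              x$ci_low, x$ci_high, x$band))
  invisible(x)
}

#' Interpretation band for an ICC value
#'
#' Six-band verbal scale: poor (0), slight (0.01-0.20), fair (0.21-0.40),
#' moderate (0.41-0.60), substantial (0.61-0.80), almost perfect
#' (0.81-1.00). Printed boundaries belong to the band whose interval names
#' them (0.20 is "slight", 0.81 is "almost perfect"); exactly 0 and negative
#' values are "poor".
#'
#' @param value numeric in `[-1, 1]`.
#' @return character band label.
#' @export
interpret_icc <- function(value) {
  if (!is.finite(value) || abs(value) > 1)
    stopf("ICC must lie in [-1, 1], got %g", value)
  if (value <= 0) return("poor")
  if (value <= 0.20) return("slight")
  if (value <= 0.40) return("fair")
  if (value <= 0.60) return("moderate")
  if (value <= 0.80) return("substantial")
  "almost perfect"
}

#' Fisher z transformation and its inverse
#'
#' `fisher_z(rho) = atanh(rho) = 0.5 * log((1 + rho) / (1 - rho))`, the
#' variance-stabilising transform for correlation-type coefficients.
#'
#' @param rho numeric with `|rho| < 1`.
#' @return numeric.
#' @export
fisher_z <- function(rho) {
  if (any(!is.finite(rho)) || any(abs(rho) >= 1))
    stopf("fisher_z requires |rho| < 1")
  0.5 * log((1 + rho) / (1 - rho))
}

#' @rdname fisher_z
#' @param z numeric.
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Compare two intraclass correlation coefficients
#'
#' Normal-theory test of H0: rho_a = rho_b using the difference of
#' Fisher-transformed estimates with standard error
#' `sqrt(1/(n_a - 3) + 1/(n_b - 3))`. The test assumes the two estimates
#' come from independent cohorts; when both share one arm (as when several
#' thresholds are each compared against the same manual segmentation) the
#' estimates are positively dependent and the test is approximate — see
#' [compare_icc_boot()] for a subject-resampling alternative.
#'
#' @param est_a,est_b `icc_estimate` objects (or bare numeric ICC values, in
#'   which case `n_a`/`n_b` must be given).
#' @param alternative `"greater"` (H1: rho_a > rho_b, upper-tail p) or
#'   `"two.sided"`.
#' @param n_a,n_b subject counts when bare values are supplied.
#' @return An `icc_comparison`: list with `statistic` (z scale), `p_raw`,
#'   `alternative`, `n_a`, `n_b`.
#' @export
compare_icc <- function(est_a, est_b, alternative = c("greater", "two.sided"),
                        n_a = NULL, n_b = NULL) {
  alternative <- match.arg(alternative)
  get_rn <- function(est, n, which) {
    if (inherits(est, "icc_estimate")) list(r = est$value, n = est$n)
    else {
      if (is.null(n)) stopf("n_%s required with a bare ICC value", which)
      list(r = est, n = n)
    }
  }
  a <- get_rn(est_a, n_a, "a"); b <- get_rn(est_b, n_b, "b")
  if (a$n <= 3L || b$n <= 3L)
    stopf("need n > 3 in both cohorts for the Fisher z comparison")
  # an ICC of exactly 1 (possible on synthetic data when two methods select
  # identical voxel sets) sits on the boundary of the transform's domain;
  # clamp at machine tolerance so two perfect ICCs compare as equal
  clamp <- function(r) max(min(r, 1 - .Machine$double.eps), -1 + .Machine$double.eps)
  se <- sqrt(1 / (a$n - 3) + 1 / (b$n - 3))
  stat <- (fisher_z(clamp(a$r)) - fisher_z(clamp(b$r))) / se
  p <- switch(alternative,
              greater = pnorm(stat, lower.tail = FALSE),
              two.sided = 2 * pnorm(-abs(stat)))
  structure(list(statistic = stat, p_raw = p, alternative = alternative,
                 n_a = a$n, n_b = b$n), class = "icc_comparison")
}

#' @export
print.icc_comparison <- function(x, ...) {
  cat(sprintf("Fisher z comparison: statistic %.4f, p (%s) = %.4g\n",
              x$statistic, x$alternative, x$p_raw))
  invisible(x)
}

#' Bootstrap comparison of two ICCs sharing one arm
#'
#' Subject-resampling extension for the dependent case: subjects are drawn
#' with replacement, both ICCs against the shared reference arm are
#' recomputed, and the p-value is the bootstrap tail probability that the
#' ICC difference is <= 0 (for `alternative = "greater"`).
#'
#' @param values_ref shared reference measurements (e.g. manual volumes).
#' @param values_a,values_b the two methods compared against the reference.
#' @param n_boot bootstrap replicates.
#' @param alternative `"greater"` or `"two.sided"`.
#' @param model ICC form, as in [icc()].
#' @param seed integer.
#' @return An `icc_comparison` with an extra `n_boot` element; `statistic`
#'   is the observed ICC difference.
#' @export
compare_icc_boot <- function(values_ref, values_a, values_b, n_boot = 2000L,
                             alternative = c("greater", "two.sided"),
                             model = "twoway-agreement", seed = 1L) {
  alternative <- match.arg(alternative)
  n <- length(values_ref)
  stopifnot(length(values_a) == n, length(values_b) == n)
  icc_val <- function(x, y) {
    Y <- cbind(x, y)
    ms <- .icc_mean_squares(Y)
    if (is.null(ms)) return(NA_real_)
    .icc_from_ms(ms, nrow(Y), 2L, model)
  }
  obs <- icc_val(values_ref, values_a) - icc_val(values_ref, values_b)
  diffs <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    icc_val(values_ref[idx], values_a[idx]) -
      icc_val(values_ref[idx], values_b[idx])
  }, numeric(1)))
  diffs <- diffs[is.finite(diffs)]
  p_gt <- mean(diffs <= 0)
  p <- switch(alternative,
              greater = p_gt,
              two.sided = 2 * min(p_gt, mean(diffs >= 0)))
  structure(list(statistic = obs, p_raw = min(p, 1),
                 alternative = alternative, n_a = n, n_b = n,
                 n_boot = length(diffs)), class = "icc_comparison")
}

#' Bonferroni adjustment
#'
#' Each p-value is multiplied by the number of hypotheses `m` and clipped at
#' 1. Equivalent to `p.adjust(p, "bonferroni")` when `m = length(p)`, but
#' `m` is explicit so a subset of a larger family can be adjusted.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param m number of hypotheses, default `length(p_values)`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stopf("p-values must lie in [0, 1]")
  if (m < 1) stopf("m must be >= 1")
  pmin(1, m * p_values)
}
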