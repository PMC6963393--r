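# Independent reference implementations used to validate the package: naive
# loop-based versions of component labelling, the full semi-automatic
# segmentation, and the ICC ANOVA, plus the closed-form Rician mean.

# flood-fill connected-component labelling, plain R loops
oracle_label_components <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  labels <- array(0L, dims)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  cur <- 0L
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2]))
    for (i in seq_len(dims[1])) {
      if (!mask[i, j, k] || labels[i, j, k] > 0L) next
      cur <- cur + 1L
      labels[i, j, k] <- cur
      stack <- list(c(i, j, k))
      while (length(stack) > 0) {
        q <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (r in seq_len(nrow(offs))) {
          p <- q + offs[r, ]
          if (any(p < 1L) || any(p > dims)) next
          if (mask[p[1], p[2], p[3]] && labels[p[1], p[2], p[3]] == 0L) {
            labels[p[1], p[2], p[3]] <- cur
            stack[[length(stack) + 1L]] <- p
          }
        }
      }
    }
  labels
}

# longest run of consecutive integers in a set
oracle_max_run <- function(slices) {
  s <- sort(unique(slices))
  best <- run <- 1L
  if (length(s) == 0) return(0L)
  for (i in seq_along(s)[-1]) {
    run <- if (s[i] == s[i - 1] + 1L) run + 1L else 1L
    best <- max(best, run)
  }
  best
}

# naive semi-automatic segmentation: voxel-by-voxel threshold scan,
# flood-fill components, consecutive-slice rule, loop metrics
oracle_segment_iph <- function(volume, plaque_mask, roi, ratio,
                               min_slices = 2L) {
  dims <- dim(volume$data)
  vals <- numeric(nrow(roi$points))
  for (r in seq_len(nrow(roi$points))) {
    p <- roi$points[r, ] + 1L
    vals[r] <- volume$data[p[1], p[2], p[3]]
  }
  thr <- ratio * mean(vals)
  cand <- array(FALSE, dims)
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2]))
    for (i in seq_len(dims[1]))
      if (plaque_mask[i, j, k] && volume$data[i, j, k] > thr)
        cand[i, j, k] <- TRUE
  labels <- oracle_label_components(cand, 26)
  out <- array(FALSE, dims)
  if (max(labels) > 0) {
    for (lab in seq_len(max(labels))) {
      w <- which(labels == lab, arr.ind = TRUE)
      if (oracle_max_run(w[, 3]) >= min_slices)
        out[labels == lab] <- TRUE
    }
  }
  nvox <- 0L
  per_slice <- integer(dims[3])
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2]))
    for (i in seq_len(dims[1]))
      if (out[i, j, k]) {
        nvox <- nvox + 1L
        per_slice[k] <- per_slice[k] + 1L
      }
  vv <- prod(volume$spacing)
  occ <- which(per_slice > 0)
  list(mask = out,
       total_volume_mm3 = nvox * vv,
       max_axial_volume_mm3 = if (nvox > 0) max(per_slice) * vv else 0,
       length_mm = if (nvox > 0)
         (max(occ) - min(occ) + 1) * volume$spacing[3] else 0)
}

# ICC from explicitly looped sums of squares
oracle_icc <- function(Y, model = "twoway-agreement") {
  n <- nrow(Y); k <- ncol(Y)
  gm <- 0
  for (i in 1:n) for (j in 1:k) gm <- gm + Y[i, j]
  gm <- gm / (n * k)
  rmeans <- numeric(n); cmeans <- numeric(k)
  for (i in 1:n) { for (j in 1:k) rmeans[i] <- rmeans[i] + Y[i, j]
    rmeans[i] <- rmeans[i] / k }
  for (j in 1:k) { for (i in 1:n) cmeans[j] <- cmeans[j] + Y[i, j]
    cmeans[j] <- cmeans[j] / n }
  ss_rows <- 0; for (i in 1:n) ss_rows <- ss_rows + k * (rmeans[i] - gm)^2
  ss_cols <- 0; for (j in 1:k) ss_cols <- ss_cols + n * (cmeans[j] - gm)^2
  ss_err <- 0
  for (i in 1:n) for (j in 1:k)
    ss_err <- ss_err + (Y[i, j] - rmeans[i] - cmeans[j] + gm)^2
  ss_with <- 0
  for (i in 1:n) for (j in 1:k) ss_with <- ss_with + (Y[i, j] - rmeans[i])^2
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  msw <- ss_with / (n * (k - 1))
  switch(model,
    "oneway" = (msr - msw) / (msr + (k - 1) * msw),
    "twoway-consistency" = (msr - mse) / (msr + (k - 1) * mse),
    "twoway-agreement" =
      (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse)))
}

# closed-form mean of a Rician(A, sigma) via the Laguerre polynomial
# L_{1/2}(x) = exp(x/2) * ((1 - x) I0(-x/2) - x I1(-x/2)), x = -A^2/(2 s^2)
oracle_rician_mean <- function(A, sigma) {
  x <- -A^2 / (2 * sigma^2)
  z <- -x / 2
  L <- (1 - x) * besselI(z, 0, expon.scaled = TRUE) -
    x * besselI(z, 1, expon.scaled = TRUE)
  sigma * sqrt(pi / 2) * L
}

# simulate a paired cohort with known true ICC under the two-way
# no-method-effect model: y_ij = s_i + e_ij, var ratio = rho
simulate_paired_cohort <- function(n, rho) {
  s <- rnorm(n, 0, sqrt(rho))
  cbind(s + rnorm(n, 0, sqrt(1 - rho)),
        s + rnorm(n, 0, sqrt(1 - rho)))
}

band_rank <- function(band) {
  match(band, c("poor", "slight", "fair", "moderate", "substantial",
                "almost perfect"))
}
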