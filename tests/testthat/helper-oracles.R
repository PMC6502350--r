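## Independent oracles and small fixture builders used across the suite.

## Normal-equations OLS oracle: slope/coefficient t-values computed from
## first principles, independently of the package's fitting code.
oracle_ols <- function(y, X) {
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  res <- y - X %*% beta
  s2 <- sum(res^2) / (length(y) - ncol(X))
  se <- unname(sqrt(s2 * diag(XtXi)))
  list(beta = as.vector(beta), t = as.vector(beta) / se, se = se)
}

## Textbook paired t: difference mean over its standard error.
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  tval <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = tval, df = n - 1, p = 2 * stats::pt(-abs(tval), n - 1))
}

## Exhaustive-shift cross-correlation oracle on a lag grid.
oracle_best_lag <- function(voxel, trace, tr, lags) {
  n <- length(voxel)
  tq <- (seq_len(n) - 0.5) * tr
  cc <- vapply(lags, function(L) {
    x <- stats::approx(trace$time_s, trace$petco2_mmhg, xout = tq - L, rule = 2)$y
    if (stats::sd(x) == 0) return(-Inf)
    stats::cor(voxel, x)
  }, numeric(1))
  lags[which.max(cc)]
}

## Direct convolution oracle at fine resolution (boxcar * double-gamma),
## computed with an explicit Riemann sum rather than FFT convolution.
oracle_convolved <- function(paradigm, hrf, n_timepoints, tr, dt = 0.1) {
  total <- n_timepoints * tr
  tt <- seq(0, total, by = dt)
  box <- numeric(length(tt))
  for (i in seq_len(nrow(paradigm))) {
    on <- paradigm$onset_s[i]; off <- on + paradigm$duration_s[i]
    box[tt >= on & tt < off] <- 1
  }
  kt <- seq(0, hrf$duration_s, by = dt)
  k <- hrf_double_gamma(kt, hrf)
  conv <- numeric(length(tt))
  for (i in seq_along(tt)) {
    jmax <- min(i, length(k))
    conv[i] <- sum(box[i - seq_len(jmax) + 1] * k[seq_len(jmax)]) * dt
  }
  list(t = tt, y = conv)
}

## Small uniform-truth subject spec: every region shares one CVR/activation
## value, handy for exactness checks.
uniform_spec <- function(cvr = 0.2, dpct = 0.85, cvr_hyper = cvr / 2,
                         dpct_hyper = dpct * 0.65, noise = 0, drift = 0,
                         lag_range = c(0, 0), seed = 1) {
  truth <- default_region_truth()
  truth$true_cvr_normo <- cvr
  truth$true_cvr_hyper <- cvr_hyper
  truth$true_dpct_normo <- dpct
  truth$true_dpct_hyper <- dpct_hyper
  subject_spec(region_truth = truth, noise_sd_pct = noise,
               drift_amplitude_pct = drift, lag_range_seconds = lag_range,
               seed = seed)
}

small_grid <- c(12, 12, 6)

## A short protocol for fast tests: 100 CVR volumes, 60 task volumes.
small_protocol <- function() {
  protocol_spec(n_volumes_cvr = 100, n_volumes_task = 60, clamp_seconds = 50,
                step_seconds = 60, task_block_seconds = 14, n_task_blocks = 3)
}
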