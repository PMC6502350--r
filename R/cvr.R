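#' Analysis mask from tissue probability maps
#'
#' A voxel enters the analysis when its combined grey plus white matter
#' probability (capped at 1) reaches the threshold.
#'
#' @param gm_prob,wm_prob probability volumes in `[0, 1]`, same shape.
#' @param threshold probability threshold in `(0, 1)`; default 0.8.
#' @return logical volume.
#' @export
make_analysis_mask <- function(gm_prob, wm_prob, threshold = 0.8) {
  check_same_dim(gm_prob, wm_prob, "probability volumes")
  if (any(gm_prob < 0 | gm_prob > 1, na.rm = TRUE) ||
      any(wm_prob < 0 | wm_prob > 1, na.rm = TRUE))
    stop("configuration error: probabilities outside [0, 1]", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("configuration error: threshold must lie in (0, 1)", call. = FALSE)
  m <- pmin(gm_prob + wm_prob, 1) >= threshold
  array(m, dim = dim(gm_prob) %||% length(gm_prob))
}

#' Resample a CO2 trace onto the volume acquisition grid
#'
#' Linear interpolation of the trace at the acquisition midpoints
#' `(k + 1/2) * TR`. The trace must span the run up to a tolerance of one
#' TR at either end (within that tolerance the nearest sample is held; no
#' further extrapolation).
#'
#' @param trace a `co2_trace`.
#' @param n_timepoints number of volumes.
#' @param tr repetition time (s).
#' @return numeric regressor of length `n_timepoints` (mmHg).
#' @export
resample_co2 <- function(trace, n_timepoints, tr) {
  stopifnot(nrow(trace) >= 2)
  tq <- (seq_len(n_timepoints) - 0.5) * tr
  lo <- min(trace$time_s); hi <- max(trace$time_s)
  if (min(tq) < lo - tr || max(tq) > hi + tr)
    stop("coverage error: CO2 trace does not span the run (tolerance one TR)",
         call. = FALSE)
  stats::approx(trace$time_s, trace$petco2_mmhg, xout = tq, rule = 2)$y
}

## Regressor shifted by `lag` seconds (positive lag: BOLD follows CO2, so
## the regressor is evaluated `lag` seconds earlier). Start-of-run values
## are clamped to the first trace sample: the run begins on a constant
## baseline clamp, so holding the first value is exact there.
.shifted_regressor <- function(trace, n_timepoints, tr, lag) {
  tq <- (seq_len(n_timepoints) - 0.5) * tr - lag
  stats::approx(trace$time_s, trace$petco2_mmhg, xout = tq, rule = 2)$y
}

#' Estimate the voxel-wise hemodynamic lag between CO2 and BOLD
#'
#' Scans candidate lags on a sub-TR grid and returns the lag maximizing
#' the correlation between the voxel series and the lag-shifted CO2
#' regressor. Ties are broken toward the smallest absolute lag, then
#' toward the negative lag. A lag landing on the window boundary is
#' flagged as saturated; a zero-variance series is flagged and assigned
#' lag 0.
#'
#' @param voxel_pct voxel time series (percent signal or any affine
#'   transform of it).
#' @param co2 either a `co2_trace` or a numeric regressor already sampled
#'   at the TR grid (shifted copies are then interpolated from it).
#' @param tr repetition time (s).
#' @param window half-width of the lag search window (s).
#' @param grid lag search step (s); default 1 s, the CO2 sampling grid.
#' @return list with `lag` (s), `flagged`, `saturated`, `correlation`.
#' @export
estimate_lag <- function(voxel_pct, co2, tr, window = 10, grid = 1) {
  n <- length(voxel_pct)
  if (window > n * tr / 4)
    stop("configuration error: lag window exceeds a quarter of the run", call. = FALSE)
  lags <- seq(-window, window, by = grid)
  ## candidate preference for tie-breaks: |lag| ascending, negative first
  pref <- order(abs(lags), lags)
  if (stats::sd(voxel_pct) == 0)
    return(list(lag = 0, flagged = TRUE, saturated = FALSE, correlation = NA_real_))
  R <- if (inherits(co2, "co2_trace")) {
    vapply(lags, function(L) .shifted_regressor(co2, n, tr, L), numeric(n))
  } else {
    stopifnot(length(co2) == n)
    tq <- (seq_len(n) - 0.5) * tr
    vapply(lags, function(L) stats::approx(tq, co2, xout = tq - L, rule = 2)$y,
           numeric(n))
  }
  cc <- suppressWarnings(as.vector(stats::cor(voxel_pct, R)))
  cc[is.na(cc)] <- -Inf
  ## first maximum in preference order implements the tie-break
  cc_pref <- cc[pref]
  best <- pref[which.max(cc_pref)]
  lag <- lags[best]
  list(lag = lag, flagged = FALSE, saturated = abs(lag) >= window,
       correlation = cc[best])
}

#' Fit the CVR regression for a single voxel
#'
#' Converts the raw voxel series to percent of its baseline-window mean
#' and regresses it (with intercept) on the lag-shifted CO2 regressor by
#' ordinary least squares. The slope is the voxel's CVR in percent signal
#' change per mmHg; the t-value is slope over its standard error (capped
#' at `t_cap` when the fit is numerically exact).
#'
#' @param voxel raw voxel time series (scanner units).
#' @param co2 a `co2_trace` or a numeric regressor at the TR grid.
#' @param tr repetition time (s).
#' @param lag hemodynamic lag (s) to apply to the regressor.
#' @param baseline_window integer indices of the baseline volumes.
#' @param t_cap cap on reported |t|.
#' @return list with `cvr`, `tvalue`, `baseline`, `excluded`.
#' @export
fit_voxel_cvr <- function(voxel, co2, tr, lag = 0, baseline_window, t_cap = 1e6) {
  n <- length(voxel)
  if (length(baseline_window) < 1)
    stop("configuration error: empty baseline window", call. = FALSE)
  b <- mean(voxel[baseline_window])
  if (!is.finite(b) || b == 0)
    return(list(cvr = NA_real_, tvalue = NA_real_, baseline = b, excluded = TRUE))
  pct <- 100 * (voxel / b - 1)
  x <- if (inherits(co2, "co2_trace")) {
    .shifted_regressor(co2, n, tr, lag)
  } else {
    tq <- (seq_len(n) - 0.5) * tr
    stats::approx(tq, co2, xout = tq - lag, rule = 2)$y
  }
  .ols_slope_t(pct, x, t_cap = t_cap)
}

## Closed-form simple OLS with intercept: slope, t, for one response
.ols_slope_t <- function(y, x, t_cap = 1e6) {
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0 || stats::sd(y) == 0)
    return(list(cvr = 0, tvalue = 0, baseline = NA_real_, excluded = FALSE))
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  res <- (y - mean(y)) - slope * (x - mean(x))
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tv <- if (se == 0) sign(slope) * t_cap else slope / se
  tv <- max(min(tv, t_cap), -t_cap)
  list(cvr = slope, tvalue = tv, baseline = NA_real_, excluded = FALSE)
}

#' Configuration of the CVR mapping stage
#'
#' @param cutoff_hz low-pass cutoff (Hz). 0.1 Hz keeps the CO2 step
#'   (fundamental well below 0.01 Hz) while removing thermal noise.
#' @param loess_span robust-lowess span, fraction of run length.
#' @param loess_iter bisquare iterations.
#' @param lag_window half-width of the lag search (s).
#' @param lag_grid lag search step (s).
#' @param baseline_seconds duration of the baseline window used for
#'   percent conversion: the initial clamp period. `NULL` defers to the
#'   caller ([run_cohort()] substitutes the protocol's clamp duration;
#'   [compute_cvr_map()] alone falls back to 100 s).
#' @param smooth logical; apply temporal smoothing.
#' @param t_cap cap on reported |t| for numerically exact fits.
#' @return list of class `cvr_config`.
#' @export
cvr_config <- function(cutoff_hz = 0.1, loess_span = 0.1, loess_iter = 2,
                       lag_window = 10, lag_grid = 1, baseline_seconds = NULL,
                       smooth = TRUE, t_cap = 1e6) {
  structure(list(cutoff_hz = cutoff_hz, loess_span = loess_span,
                 loess_iter = loess_iter, lag_window = lag_window,
                 lag_grid = lag_grid, baseline_seconds = baseline_seconds,
                 smooth = smooth, t_cap = t_cap), class = "cvr_config")
}

#' Voxel-wise BOLD-CVR mapping
#'
#' The full CVR pipeline for one run: percent conversion against the
#' baseline clamp, temporal smoothing (low-pass plus robust lowess,
#' applied identically to the voxel signal and to every candidate
#' lag-shifted CO2 regressor so smoothing cannot bias the slope),
#' voxel-wise lag estimation by cross-correlation, and an OLS fit of
#' percent signal on the lag-aligned regressor. Returns slope (CVR), lag
#' and t-value maps plus the analysis mask.
#'
#' @param run a `bold_run` with `run_type = "cvr"`.
#' @param trace the run's `co2_trace`.
#' @param mask logical analysis volume (see [make_analysis_mask()]).
#' @param config a [cvr_config()].
#' @return object of class `cvr_fit` with volumes `cvr`, `lag`, `tvalue`,
#'   `baseline`, logical `mask`, per-voxel `flags`, and `mean_cvr`, the
#'   whole-mask mean.
#' @export
compute_cvr_map <- function(run, trace, mask, config = cvr_config()) {
  stopifnot(inherits(run, "bold_run"))
  if (!identical(run$run_type, "cvr"))
    stop("compute_cvr_map expects a CVR run", call. = FALSE)
  dims <- dim(run$data)
  n <- dims[4]
  check_same_dim(array(0, dims[1:3]), mask, "run and mask")
  tr <- run$tr

  Y <- matrix(run$data, prod(dims[1:3]), n)
  vox <- which(as.vector(mask))
  Y <- t(Y[vox, , drop = FALSE])           # n x V

  bsec <- config$baseline_seconds %||% 100
  bidx <- which((seq_len(n) - 0.5) * tr < bsec)
  if (!length(bidx)) stop("configuration error: empty baseline window", call. = FALSE)
  bmean <- colMeans(Y[bidx, , drop = FALSE])
  bad_base <- !is.finite(bmean) | bmean == 0
  bsafe <- ifelse(bad_base, 1, bmean)
  P <- 100 * (sweep(Y, 2, bsafe, `/`) - 1)

  if (config$smooth)
    P <- .smooth_matrix(P, tr, config$cutoff_hz, config$loess_span, config$loess_iter)

  lags <- seq(-config$lag_window, config$lag_window, by = config$lag_grid)
  R <- vapply(lags, function(L) .shifted_regressor(trace, n, tr, L), numeric(n))
  if (config$smooth)
    R <- .smooth_matrix(R, tr, config$cutoff_hz, config$loess_span, config$loess_iter)

  ## correlation of every voxel with every candidate regressor
  sdP <- apply(P, 2, stats::sd)
  flat <- sdP == 0
  Pc <- sweep(P, 2, colMeans(P))
  Rc <- sweep(R, 2, colMeans(R))
  Rsd <- sqrt(colSums(Rc^2))
  CC <- crossprod(Pc, sweep(Rc, 2, Rsd, `/`))          # V x L, unnormalized in P
  pref <- order(abs(lags), lags)
  CCp <- CC[, pref, drop = FALSE]
  best_pref <- max.col(CCp, ties.method = "first")
  lag_idx <- pref[best_pref]
  lag_idx[flat] <- which(lags == 0)
  vlag <- lags[lag_idx]
  saturated <- abs(vlag) >= config$lag_window & !flat

  V <- ncol(P)
  slope <- numeric(V); tval <- numeric(V)
  for (li in sort(unique(lag_idx))) {
    jj <- which(lag_idx == li & !flat)
    if (!length(jj)) next
    x <- R[, li]
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    Pj <- Pc[, jj, drop = FALSE]
    b1 <- as.vector(crossprod(Pj, xc)) / sxx
    rss <- colSums(Pj^2) - b1^2 * sxx
    rss[rss < 0] <- 0
    se <- sqrt(rss / (n - 2) / sxx)
    tv <- ifelse(se == 0, sign(b1) * config$t_cap, b1 / se)
    tv <- pmax(pmin(tv, config$t_cap), -config$t_cap)
    slope[jj] <- b1
    tval[jj] <- tv
  }

  mk_vol <- function(vals, fill = NA_real_) {
    v <- array(fill, dims[1:3]); v[vox] <- vals; v
  }
  final_mask <- array(FALSE, dims[1:3])
  final_mask[vox[!bad_base]] <- TRUE
  slope[bad_base] <- NA_real_; tval[bad_base] <- NA_real_
  flags <- ifelse(bad_base, "zero_baseline",
                  ifelse(flat, "zero_variance",
                         ifelse(saturated, "lag_saturated", "")))

  structure(list(
    cvr = mk_vol(slope), lag = mk_vol(vlag), tvalue = mk_vol(tval),
    baseline = mk_vol(bmean), mask = final_mask,
    flags = mk_vol(match(flags, c("", "zero_baseline", "zero_variance",
                                  "lag_saturated")) - 1, fill = NA_real_),
    mean_cvr = mean(slope[!bad_base]),
    condition = run$condition, config = config, n_volumes = n, tr = tr,
    call = match.call()
  ), class = "cvr_fit")
}
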