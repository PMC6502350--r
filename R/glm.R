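#' Double-gamma hemodynamic response function parameters
#'
#' The canonical shape: a gamma peak at ~6 s minus a scaled gamma
#' undershoot at ~16 s.
#'
#' @param peak_delay,undershoot_delay gamma means (s).
#' @param peak_dispersion,undershoot_dispersion gamma dispersions (s).
#' @param undershoot_ratio relative amplitude of the undershoot.
#' @param duration_s support of the kernel (s).
#' @return list of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16,
                     peak_dispersion = 1, undershoot_dispersion = 1,
                     undershoot_ratio = 1 / 6, duration_s = 32) {
  vals <- c(peak_delay, undershoot_delay, peak_dispersion,
            undershoot_dispersion, undershoot_ratio, duration_s)
  if (any(vals <= 0))
    stop("configuration error: HRF parameters must be positive", call. = FALSE)
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio, duration_s = duration_s),
            class = "hrf_spec")
}

#' Evaluate the double-gamma HRF
#'
#' @param t times (s).
#' @param hrf an [hrf_spec()].
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, hrf = hrf_spec()) {
  h <- stats::dgamma(t, shape = hrf$peak_delay / hrf$peak_dispersion,
                     scale = hrf$peak_dispersion) -
    hrf$undershoot_ratio *
    stats::dgamma(t, shape = hrf$undershoot_delay / hrf$undershoot_dispersion,
                  scale = hrf$undershoot_dispersion)
  h[t < 0] <- 0
  h
}

#' HRF-convolved task regressor at unit peak
#'
#' Builds the block boxcar at fine temporal resolution, convolves it with
#' the double-gamma HRF, samples the result at the volume acquisition
#' midpoints and divides by the maximum of the fine-resolution response
#' (unit peak). With percent-normalized data the task coefficient then
#' reads directly as the task percent signal change.
#'
#' @param paradigm a `paradigm` data.frame (`onset_s`, `duration_s`).
#' @param hrf an [hrf_spec()].
#' @param n_timepoints number of volumes.
#' @param tr repetition time (s).
#' @param dt convolution resolution (s).
#' @return numeric regressor of length `n_timepoints`; attribute
#'   `flagged_empty` is `TRUE` for an empty paradigm (all-zero regressor).
#' @export
hrf_convolved_regressor <- function(paradigm, hrf = hrf_spec(),
                                    n_timepoints, tr, dt = 0.1) {
  total <- n_timepoints * tr
  if (nrow(paradigm) == 0) {
    r <- numeric(n_timepoints)
    attr(r, "flagged_empty") <- TRUE
    return(r)
  }
  if (any(paradigm$onset_s < 0) ||
      any(paradigm$onset_s + paradigm$duration_s > total))
    stop("invalid protocol: paradigm outside the run", call. = FALSE)
  tt <- seq(0, total, by = dt)
  box <- numeric(length(tt))
  for (i in seq_len(nrow(paradigm))) {
    on <- paradigm$onset_s[i]; off <- on + paradigm$duration_s[i]
    box[tt >= on & tt < off] <- 1
  }
  k <- hrf_double_gamma(seq(0, hrf$duration_s, by = dt), hrf)
  conv <- stats::convolve(box, rev(k), type = "open")[seq_along(tt)] * dt
  peak <- max(conv)
  if (peak <= 0) {
    r <- numeric(n_timepoints)
    attr(r, "flagged_empty") <- TRUE
    return(r)
  }
  tq <- (seq_len(n_timepoints) - 0.5) * tr
  r <- stats::approx(tt, conv / peak, xout = tq, rule = 2)$y
  attr(r, "flagged_empty") <- FALSE
  r
}

#' Assemble a first-level design matrix
#'
#' Columns are the task regressor, any nuisance covariates (e.g. motion
#' parameters), polynomial drift terms, and the intercept. The design is
#' checked for full column rank.
#'
#' @param regressor task regressor.
#' @param nuisance optional numeric matrix of nuisance covariates.
#' @param drift_order order of the polynomial drift terms (0 disables).
#' @return numeric matrix with named columns and attribute `rank`.
#' @export
build_design <- function(regressor, nuisance = NULL, drift_order = 0) {
  n <- length(regressor)
  cols <- list(task = as.numeric(regressor))
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n)
      stop_dim("nuisance rows do not match the regressor length")
    cn <- colnames(nuisance) %||% paste0("nuisance", seq_len(ncol(nuisance)))
    for (j in seq_len(ncol(nuisance))) cols[[cn[j]]] <- nuisance[, j]
  }
  if (drift_order > 0) {
    dr <- stats::poly(seq_len(n), degree = drift_order)
    for (j in seq_len(drift_order)) cols[[paste0("drift", j)]] <- dr[, j]
  }
  cols[["intercept"]] <- rep(1, n)
  X <- do.call(cbind, cols)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[-seq_len(qr_x$rank)]]
    stop(sprintf("collinearity error: design is rank deficient (columns: %s)",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  attr(X, "rank") <- qr_x$rank
  X
}

#' Mass-univariate task GLM
#'
#' Fits, per masked voxel, ordinary least squares of the percent-normalized
#' signal on the design matrix. The t-value of the task column is the
#' activation statistic; because the task regressor has unit peak, its
#' coefficient is the task percent signal change (`dpct`).
#'
#' @param run a `bold_run` with `run_type = "task"`.
#' @param design matrix from [build_design()] (rows = run length; must
#'   contain a `task` column).
#' @param mask logical analysis volume.
#' @param baseline_window integer volume indices used for percent
#'   conversion; `NULL` uses the volumes before the first task onset
#'   inferred from the design (first rest block).
#' @param t_cap cap on |t| for numerically exact fits.
#' @return object of class `activation_fit` with volumes `tvalue`,
#'   `dpct`, logical `mask`, and (after [threshold_tmap()]) `sig_mask`.
#' @export
fit_task_glm <- function(run, design, mask, baseline_window = NULL, t_cap = 1e6) {
  stopifnot(inherits(run, "bold_run"))
  dims <- dim(run$data)
  n <- dims[4]
  if (nrow(design) != n)
    stop_dim("design rows do not match the run length")
  if (!"task" %in% colnames(design))
    stop("configuration error: design lacks a 'task' column", call. = FALSE)
  check_same_dim(array(0, dims[1:3]), mask, "run and mask")

  if (is.null(baseline_window)) {
    r <- design[, "task"]
    first_on <- which(r > max(r) * 1e-9)[1]
    if (is.na(first_on)) first_on <- n
    baseline_window <- seq_len(max(1, first_on - 1))
  }

  Y <- matrix(run$data, prod(dims[1:3]), n)
  vox <- which(as.vector(mask))
  Y <- t(Y[vox, , drop = FALSE])
  bmean <- colMeans(Y[baseline_window, , drop = FALSE])
  bad <- !is.finite(bmean) | bmean == 0
  bsafe <- ifelse(bad, 1, bmean)
  P <- 100 * (sweep(Y, 2, bsafe, `/`) - 1)

  X <- design
  XtXi <- chol2inv(chol(crossprod(X)))
  B <- XtXi %*% crossprod(X, P)                      # p x V
  res <- P - X %*% B
  dfres <- n - ncol(X)
  s2 <- colSums(res^2) / dfres
  jt <- which(colnames(X) == "task")
  se <- sqrt(s2 * XtXi[jt, jt])
  beta <- B[jt, ]
  tv <- ifelse(se == 0, sign(beta) * t_cap, beta / se)
  tv <- pmax(pmin(tv, t_cap), -t_cap)

  flat <- apply(P, 2, stats::sd) == 0
  tv[flat] <- 0; beta[flat] <- 0
  tv[bad] <- NA_real_; beta[bad] <- NA_real_

  mk_vol <- function(vals) { v <- array(NA_real_, dims[1:3]); v[vox] <- vals; v }
  final_mask <- array(FALSE, dims[1:3]); final_mask[vox[!bad]] <- TRUE
  structure(list(
    tvalue = mk_vol(tv), dpct = mk_vol(beta), mask = final_mask,
    sig_mask = NULL, threshold = NA_real_,
    n_nuisance = ncol(X) - 2L, df = dfres, condition = run$condition,
    flags = mk_vol(as.numeric(flat | bad)), call = match.call()
  ), class = "activation_fit")
}

#' Threshold a t-map into a binary significance mask
#'
#' Strict exceedance: a voxel is significant iff `t > threshold`.
#'
#' @param result an `activation_fit`.
#' @param threshold t threshold (default 3.43, an average p < 0.05
#'   familywise-corrected level for this design).
#' @return the `activation_fit` with `sig_mask` and `threshold` set.
#' @export
threshold_tmap <- function(result, threshold = 3.43) {
  stopifnot(inherits(result, "activation_fit"), is.finite(threshold))
  sig <- result$tvalue > threshold
  sig[is.na(sig)] <- FALSE
  result$sig_mask <- sig & result$mask
  result$threshold <- threshold
  result
}

#' Union of two significance masks
#'
#' Voxels significant in at least one of two runs (e.g. the normocapnic
#' and hypercapnic task runs); the voxel set over which regional means
#' are compared across conditions.
#'
#' @param mask_normo,mask_hyper logical volumes of the same shape.
#' @return logical volume, the voxelwise union.
#' @export
combined_sig_mask <- function(mask_normo, mask_hyper) {
  check_same_dim(mask_normo, mask_hyper, "significance masks")
  mask_normo | mask_hyper
}
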