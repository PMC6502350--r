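#' Simulate an end-tidal CO2 trace for one run
#'
#' Produces the PetCO2 time course that a prospective end-tidal targeting
#' system delivers during a CVR run: a baseline clamp at the subject's
#' resting value (elevated by the hypercapnic offset under `"hyper"`),
#' then a pseudo-square step held for `step_seconds` with linear ramp
#' edges, then a return to baseline. Sampled at 1 s.
#'
#' @param protocol a [protocol_spec()].
#' @param condition `"normo"` or `"hyper"`.
#' @param resting_petco2 resting PetCO2 (mmHg).
#' @return data.frame of class `co2_trace` with columns `time_s`,
#'   `petco2_mmhg`; attributes `condition` and `baseline_mmHg`.
#' @export
make_co2_trace <- function(protocol, condition = c("normo", "hyper"),
                           resting_petco2 = 38) {
  stopifnot(inherits(protocol, "protocol_spec"))
  condition <- match.arg(condition)
  baseline <- resting_petco2 +
    if (condition == "hyper") protocol$hypercapnic_offset_mmHg else 0
  total <- protocol$n_volumes_cvr * protocol$tr_seconds
  tt <- seq(0, total - 1, by = 1)
  ramp <- protocol$ramp_seconds
  t_up <- protocol$clamp_seconds
  t_plateau <- t_up + ramp
  t_down <- t_plateau + protocol$step_seconds
  t_base <- t_down + ramp
  p <- numeric(length(tt)) + baseline
  if (ramp > 0) {
    i <- tt >= t_up & tt < t_plateau
    p[i] <- baseline + protocol$step_mmHg * (tt[i] - t_up) / ramp
    i <- tt >= t_down & tt < t_base
    p[i] <- baseline + protocol$step_mmHg * (1 - (tt[i] - t_down) / ramp)
  }
  p[tt >= t_plateau & tt < t_down] <- baseline + protocol$step_mmHg
  out <- data.frame(time_s = tt, petco2_mmhg = p)
  structure(out, class = c("co2_trace", "data.frame"),
            condition = condition, baseline_mmHg = baseline)
}

#' Simulate a block-design task paradigm and its clamped CO2 trace
#'
#' The task run alternates rest and task blocks, starting with one rest
#' block, while PetCO2 is clamped at a constant baseline.
#'
#' @param protocol a [protocol_spec()].
#' @param condition_baseline the clamped PetCO2 level (mmHg).
#' @param jitter_sd_mmHg optional Gaussian jitter of the clamp (mmHg).
#' @param seed optional seed for the jitter draw.
#' @return list with `paradigm` (data.frame `onset_s`, `duration_s`,
#'   `condition`, class `paradigm`) and `trace` (a `co2_trace`).
#' @export
make_task_paradigm <- function(protocol, condition_baseline = 38,
                               jitter_sd_mmHg = 0, seed = NULL) {
  stopifnot(inherits(protocol, "protocol_spec"))
  nb <- protocol$n_task_blocks
  bl <- protocol$task_block_seconds
  total <- protocol$n_volumes_task * protocol$tr_seconds
  if (nb > 0) {
    onsets <- bl * (2 * seq_len(nb) - 1)
    if (max(onsets) + bl > total)
      stop("invalid protocol: task blocks exceed run length", call. = FALSE)
    par <- data.frame(onset_s = onsets, duration_s = rep(bl, nb),
                      condition = "task", stringsAsFactors = FALSE)
  } else {
    par <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      condition = character(0), stringsAsFactors = FALSE)
  }
  class(par) <- c("paradigm", "data.frame")
  tt <- seq(0, total - 1, by = 1)
  p <- rep(condition_baseline, length(tt))
  if (jitter_sd_mmHg > 0)
    p <- p + with_seed(seed, stats::rnorm(length(tt), 0, jitter_sd_mmHg))
  trace <- data.frame(time_s = tt, petco2_mmhg = p)
  trace <- structure(trace, class = c("co2_trace", "data.frame"),
                     condition = "clamp", baseline_mmHg = condition_baseline)
  list(paradigm = par, trace = trace)
}

## Partition 1..n into k contiguous nearly equal runs; returns list of index vectors
.partition_axis <- function(n, k) {
  br <- floor(seq(0, n, length.out = k + 1))
  lapply(seq_len(k), function(i) seq(br[i] + 1, br[i + 1]))
}

#' Build a digital phantom with known voxel-wise ground truth
#'
#' Lays the nine motor-network regions out as equal-sized rectangular
#' blocks (a 3 x 3 arrangement in-plane, restricted to the middle slices)
#' on a background of non-brain voxels, and populates ground-truth CVR,
#' task activation, baseline signal, hemodynamic lag and tissue
#' probability volumes. Region geometry and the per-voxel lag draw are
#' deterministic given `spec$seed`.
#'
#' @param spec a [subject_spec()].
#' @param grid_shape integer triple, the volume dimensions.
#' @param co2_dt_s CO2 sampling interval (s); lags are quantized to this
#'   grid so that exact recovery is a testable property.
#' @return object of class `phantom`: label volume plus `truth_cvr`,
#'   `truth_dpct` (lists with `normo`/`hyper` volumes), `truth_lag`,
#'   `gm_prob`, `wm_prob`, `s0`, and the region name map.
#' @export
make_phantom <- function(spec, grid_shape = c(24, 24, 12), co2_dt_s = 1) {
  stopifnot(inherits(spec, "subject_spec"))
  if (length(grid_shape) != 3 || any(grid_shape < 3))
    stop("configuration error: grid_shape must be a triple of dims >= 3", call. = FALSE)
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  px <- .partition_axis(nx, 3); py <- .partition_axis(ny, 3)
  if (any(lengths(px) < 1) || any(lengths(py) < 1))
    stop("configuration error: grid too small for 9 non-empty regions", call. = FALSE)
  zlo <- floor(nz / 4) + 1; zhi <- floor(3 * nz / 4)
  if (zhi < zlo) stop("configuration error: grid too small in z", call. = FALSE)

  regions <- motor_region_names()
  labels <- array(0L, dim = grid_shape)
  k <- 0L
  for (iy in 1:3) for (ix in 1:3) {
    k <- k + 1L
    labels[px[[ix]], py[[iy]], zlo:zhi] <- k
  }
  name_map <- stats::setNames(seq_along(regions), regions)

  truth <- spec$region_truth
  rownames(truth) <- truth$region
  lookup <- function(col) {
    v <- array(0, dim = grid_shape)
    for (r in regions) v[labels == name_map[[r]]] <- truth[r, col]
    v
  }
  truth_cvr <- list(normo = lookup("true_cvr_normo"), hyper = lookup("true_cvr_hyper"))
  truth_dpct <- list(normo = lookup("true_dpct_normo"), hyper = lookup("true_dpct_hyper"))

  brain <- labels > 0L
  gm <- array(0.05, dim = grid_shape); gm[brain] <- 0.70
  wm <- array(0.02, dim = grid_shape); wm[brain] <- 0.30
  s0 <- array(spec$s0_background, dim = grid_shape); s0[brain] <- spec$s0

  truth_lag <- array(0, dim = grid_shape)
  nb <- sum(brain)
  lag <- with_seed(spec$seed, stats::runif(nb, spec$lag_range_seconds[1],
                                           spec$lag_range_seconds[2]))
  truth_lag[brain] <- round(lag / co2_dt_s) * co2_dt_s

  structure(list(
    grid_shape = grid_shape, labels = labels, region_names = name_map,
    gm_prob = gm, wm_prob = wm, truth_cvr = truth_cvr,
    truth_dpct = truth_dpct, truth_lag = truth_lag, s0 = s0, spec = spec
  ), class = "phantom")
}

## Order-1 and order-2 Legendre polynomials on [-1, 1]
.legendre_basis <- function(n, order) {
  u <- seq(-1, 1, length.out = n)
  basis <- list(u, 0.5 * (3 * u^2 - 1))
  if (order < 1) return(NULL)
  do.call(cbind, basis[seq_len(min(order, 2))])
}

## Shared nuisance: slow Legendre drift + iid Gaussian noise, scaled by s0.
## Returns an n x V matrix in scanner units.
.nuisance_matrix <- function(n, s0_vec, spec, drift_order, seed) {
  V <- length(s0_vec)
  with_seed(seed, {
    eps <- matrix(stats::rnorm(n * V, 0, 1), n, V)
    drift <- matrix(0, n, V)
    if (drift_order > 0 && spec$drift_amplitude_pct > 0) {
      B <- .legendre_basis(n, drift_order)
      cf <- matrix(stats::runif(ncol(B) * V, -spec$drift_amplitude_pct,
                                spec$drift_amplitude_pct), ncol(B), V)
      drift <- B %*% cf
    }
    sweep(eps * (spec$noise_sd_pct / 100) + drift / 100, 2, s0_vec, `*`)
  })
}

## Evaluate a co2_trace at arbitrary times, clamping to the endpoints
.trace_at <- function(trace, times) {
  stats::approx(trace$time_s, trace$petco2_mmhg, xout = times, rule = 2)$y
}

#' Simulate a BOLD CVR run from a phantom and a CO2 trace
#'
#' Voxel model: `S(t) = S0 * (1 + CVR/100 * (CO2(t - lag) - baseline))`
#' plus slow Legendre drift and iid Gaussian noise (both scaled to S0).
#' Volumes are sampled at acquisition midpoints `(k + 1/2) * TR`.
#' Background voxels have zero CVR.
#'
#' @param phantom a [make_phantom()] result.
#' @param trace a `co2_trace` whose duration matches the protocol.
#' @param protocol a [protocol_spec()].
#' @param condition `"normo"` or `"hyper"`; selects the condition-specific
#'   true slopes (vasodilatory saturation makes the hypercapnic slope
#'   roughly half the normocapnic one).
#' @param seed seed for noise and drift draws (`NULL`: ambient RNG).
#' @param drift_order order of the Legendre drift (0 disables).
#' @return object of class `bold_run`: 4D array plus `tr`, `condition`,
#'   `run_type`.
#' @export
simulate_cvr_run <- function(phantom, trace, protocol,
                             condition = c("normo", "hyper"),
                             seed = NULL, drift_order = 2) {
  stopifnot(inherits(phantom, "phantom"), inherits(trace, "co2_trace"),
            inherits(protocol, "protocol_spec"))
  condition <- match.arg(condition)
  n <- protocol$n_volumes_cvr
  tr <- protocol$tr_seconds
  if (max(trace$time_s) < (n - 0.5) * tr - 1)
    stop("coverage error: CO2 trace shorter than the run", call. = FALSE)
  spec <- phantom$spec
  baseline <- attr(trace, "baseline_mmHg") %||% trace$petco2_mmhg[1]
  tmid <- (seq_len(n) - 0.5) * tr
  dims <- phantom$grid_shape
  V <- prod(dims)
  s0 <- as.vector(phantom$s0)
  cvr <- as.vector(phantom$truth_cvr[[condition]])
  lagv <- as.vector(phantom$truth_lag)

  ## one shifted regressor per distinct lag value
  sig <- matrix(0, n, V)
  for (L in unique(lagv)) {
    idx <- which(lagv == L)
    x <- .trace_at(trace, tmid - L) - baseline
    sig[, idx] <- outer(x, cvr[idx] / 100)
  }
  sig <- sweep(1 + sig, 2, s0, `*`)
  sig <- sig + .nuisance_matrix(n, s0, spec, drift_order, seed)
  structure(list(data = array(t(sig), dim = c(dims, n)), tr = tr,
                 condition = condition, run_type = "cvr"),
            class = "bold_run")
}

#' Simulate a task-evoked BOLD run from a phantom and a paradigm
#'
#' Voxel model: `S(t) = S0 * (1 + dpct/100 * r(t))` plus drift and noise,
#' where `r(t)` is the HRF-convolved block paradigm normalized to unit
#' peak (the same regressor the GLM stage fits, so the task coefficient
#' reads directly as the embedded percent signal change).
#'
#' @inheritParams simulate_cvr_run
#' @param paradigm a `paradigm` data.frame (see [make_task_paradigm()]).
#' @param hrf an [hrf_spec()].
#' @return a `bold_run` with `run_type = "task"`.
#' @export
simulate_task_run <- function(phantom, paradigm, protocol,
                              condition = c("normo", "hyper"),
                              seed = NULL, drift_order = 2, hrf = hrf_spec()) {
  stopifnot(inherits(phantom, "phantom"), inherits(protocol, "protocol_spec"))
  condition <- match.arg(condition)
  n <- protocol$n_volumes_task
  tr <- protocol$tr_seconds
  if (nrow(paradigm) && max(paradigm$onset_s + paradigm$duration_s) > n * tr)
    stop("invalid protocol: paradigm exceeds run duration", call. = FALSE)
  spec <- phantom$spec
  r <- hrf_convolved_regressor(paradigm, hrf, n, tr)
  dims <- phantom$grid_shape
  s0 <- as.vector(phantom$s0)
  dpct <- as.vector(phantom$truth_dpct[[condition]])
  sig <- 1 + outer(r, dpct / 100)
  sig <- sweep(sig, 2, s0, `*`)
  sig <- sig + .nuisance_matrix(n, s0, spec, drift_order, seed)
  structure(list(data = array(t(sig), dim = c(dims, n)), tr = tr,
                 condition = condition, run_type = "task"),
            class = "bold_run")
}
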