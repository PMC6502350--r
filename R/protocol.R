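#' The nine motor-network regions
#'
#' Bilateral precentral and postcentral gyri, frontal opercula (FO),
#' cerebella, and the supplementary motor area (SMA): the anatomical
#' components of the finger-tapping motor network that the ROI analysis
#' summarizes.
#'
#' @return character vector of the nine region names.
#' @export
motor_region_names <- function() {
  c("precentral right", "precentral left",
    "postcentral right", "postcentral left",
    "FO right", "FO left",
    "cerebellum right", "cerebellum left",
    "SMA")
}

#' Default regional ground truth for synthetic cohorts
#'
#' Literature-informed group-mean values for healthy adults: BOLD-CVR
#' (percent signal change per mmHg CO2) under a normocapnic and a
#' hypercapnic baseline, and task-evoked percent signal change
#' (finger-tapping) under the same two baselines. The hypercapnic CVR
#' column is roughly half the normocapnic one, encoding the vasodilatory
#' saturation that a raised CO2 baseline produces.
#'
#' @return data.frame with columns `region`, `true_cvr_normo`,
#'   `true_cvr_hyper`, `true_dpct_normo`, `true_dpct_hyper`.
#' @export
default_region_truth <- function() {
  data.frame(
    region          = motor_region_names(),
    true_cvr_normo  = c(0.22, 0.21, 0.24, 0.26, 0.29, 0.34, 0.29, 0.28, 0.24),
    true_cvr_hyper  = c(0.11, 0.10, 0.13, 0.13, 0.11, 0.14, 0.16, 0.16, 0.10),
    true_dpct_normo = c(0.85, 0.84, 0.87, 0.87, 0.50, 0.54, 0.70, 0.63, 0.55),
    true_dpct_hyper = c(0.56, 0.53, 0.60, 0.59, 0.29, 0.33, 0.43, 0.30, 0.41),
    stringsAsFactors = FALSE
  )
}

#' Acquisition and gas-stimulus protocol
#'
#' Timing parameters of one combined session: a CVR run (baseline CO2
#' clamp followed by a pseudo-square hypercapnic step) and a block-design
#' finger-tapping run acquired at a constant CO2 clamp.
#'
#' @param tr_seconds repetition time (s).
#' @param n_volumes_cvr volumes acquired during the CVR run.
#' @param n_volumes_task volumes acquired during the task run.
#' @param clamp_seconds duration of the initial baseline clamp in the CVR
#'   run (s).
#' @param step_seconds duration of the hypercapnic plateau (s).
#' @param step_mmHg height of the CO2 step (mmHg).
#' @param hypercapnic_offset_mmHg baseline elevation of the hypercapnic
#'   condition relative to the subject's resting PetCO2 (mmHg).
#' @param task_block_seconds duration of one task (and one rest) block (s).
#' @param n_task_blocks number of task blocks.
#' @param ramp_seconds rise/fall time of the pseudo-square step edges (s);
#'   gas delivery cannot switch instantaneously.
#' @return object of class `protocol_spec`.
#' @export
protocol_spec <- function(tr_seconds = 2, n_volumes_cvr = 200, n_volumes_task = 135,
                          clamp_seconds = 100, step_seconds = 80, step_mmHg = 10,
                          hypercapnic_offset_mmHg = 6, task_block_seconds = 30,
                          n_task_blocks = 4, ramp_seconds = 6) {
  if (tr_seconds <= 0 || n_volumes_cvr <= 0 || n_volumes_task <= 0 ||
      step_seconds <= 0 || task_block_seconds <= 0)
    stop("invalid protocol: durations and volume counts must be positive", call. = FALSE)
  if (clamp_seconds < 0 || ramp_seconds < 0 || n_task_blocks < 0)
    stop("invalid protocol: negative clamp, ramp or block count", call. = FALSE)
  if (clamp_seconds + step_seconds >= n_volumes_cvr * tr_seconds)
    stop("invalid protocol: clamp + step must fit inside the CVR run", call. = FALSE)
  if (n_task_blocks * 2 * task_block_seconds > n_volumes_task * tr_seconds)
    stop("invalid protocol: task blocks exceed the task-run duration", call. = FALSE)
  structure(list(
    tr_seconds = tr_seconds, n_volumes_cvr = as.integer(n_volumes_cvr),
    n_volumes_task = as.integer(n_volumes_task), clamp_seconds = clamp_seconds,
    step_seconds = step_seconds, step_mmHg = step_mmHg,
    hypercapnic_offset_mmHg = hypercapnic_offset_mmHg,
    task_block_seconds = task_block_seconds,
    n_task_blocks = as.integer(n_task_blocks), ramp_seconds = ramp_seconds
  ), class = "protocol_spec")
}

#' Per-subject simulation parameters
#'
#' Ground-truth regional CVR and task activation together with the
#' nuisance levels (noise, drift) and the subject's resting end-tidal CO2.
#'
#' @param subject_id character label.
#' @param resting_petco2_mmHg resting PetCO2 (mmHg). Healthy adults
#'   typically clamp near 38 mmHg.
#' @param region_truth data.frame as returned by [default_region_truth()];
#'   may include an all-zero `"background"` row.
#' @param lag_range_seconds 2-vector: voxel hemodynamic lags are drawn
#'   uniformly from this interval (s) and quantized to the CO2 sampling
#'   grid (1 s).
#' @param noise_sd_pct thermal-noise standard deviation, percent of the
#'   voxel baseline signal.
#' @param drift_amplitude_pct amplitude of the slow scanner drift, percent
#'   of baseline (Legendre polynomial coefficients drawn uniformly in
#'   plus/minus this value).
#' @param seed integer seed controlling the phantom geometry draw.
#' @param s0 baseline signal (arbitrary scanner units) inside the brain.
#' @param s0_background baseline signal outside the brain.
#' @return object of class `subject_spec`.
#' @export
subject_spec <- function(subject_id = "sub-01", resting_petco2_mmHg = 38,
                         region_truth = default_region_truth(),
                         lag_range_seconds = c(0, 8), noise_sd_pct = 1,
                         drift_amplitude_pct = 0, seed = 1L,
                         s0 = 340, s0_background = 20) {
  stopifnot(is.data.frame(region_truth))
  need <- c("region", "true_cvr_normo", "true_cvr_hyper",
            "true_dpct_normo", "true_dpct_hyper")
  if (!all(need %in% names(region_truth)))
    stop("configuration error: region_truth lacks required columns", call. = FALSE)
  rn <- region_truth$region
  extra <- setdiff(rn, c(motor_region_names(), "background"))
  missing <- setdiff(motor_region_names(), rn)
  if (length(extra) || length(missing))
    stop(sprintf("configuration error: region_truth must name exactly the nine motor regions (missing: %s; unknown: %s)",
                 paste(missing, collapse = ", "), paste(extra, collapse = ", ")),
         call. = FALSE)
  cvr_cols <- region_truth[, c("true_cvr_normo", "true_cvr_hyper")]
  if (any(unlist(cvr_cols) < 0))
    stop("configuration error: true CVR values must be non-negative", call. = FALSE)
  if (noise_sd_pct < 0)
    stop("configuration error: negative noise sd", call. = FALSE)
  if (drift_amplitude_pct < 0)
    stop("configuration error: negative drift amplitude", call. = FALSE)
  if (length(lag_range_seconds) != 2 || diff(lag_range_seconds) < 0)
    stop("configuration error: lag_range_seconds must be an increasing interval", call. = FALSE)
  ## background row is implicit: all truths zero
  if (!"background" %in% rn) {
    region_truth <- rbind(region_truth[, need],
                          data.frame(region = "background", true_cvr_normo = 0,
                                     true_cvr_hyper = 0, true_dpct_normo = 0,
                                     true_dpct_hyper = 0))
  }
  structure(list(
    subject_id = subject_id, resting_petco2_mmHg = resting_petco2_mmHg,
    region_truth = region_truth, lag_range_seconds = lag_range_seconds,
    noise_sd_pct = noise_sd_pct, drift_amplitude_pct = drift_amplitude_pct,
    seed = as.integer(seed), s0 = s0, s0_background = s0_background
  ), class = "subject_spec")
}
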