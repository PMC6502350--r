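#' Cohort-level configuration
#'
#' Bundles everything one synthetic study needs: cohort size, protocol
#' timings, the per-subject template (ground truth, noise), analysis
#' thresholds and the master seed. Every threshold and timing is surfaced
#' here with its conventional default.
#'
#' @param n_subjects number of subjects (default 17).
#' @param protocol a [protocol_spec()].
#' @param subject_template a [subject_spec()]; per-subject id and seed are
#'   filled in by [run_cohort()].
#' @param grid_shape phantom dimensions.
#' @param t_threshold significance threshold on task t-maps.
#' @param dpct_lt,cvr_gt thresholds of the low-activation/preserved-CVR
#'   voxel rule.
#' @param mask_prob combined grey+white probability threshold of the
#'   analysis mask.
#' @param master_seed integer master seed; per-subject seeds are derived
#'   with [derive_seed()].
#' @param output_dir directory for intermediate volumes, tables and logs
#'   (`NULL`: keep everything in memory only).
#' @param cvr a [cvr_config()].
#' @param hrf an [hrf_spec()].
#' @param glm_drift_order polynomial drift order of the task design.
#' @param sim_drift_order Legendre order of the simulated scanner drift.
#' @param roi_voxel_set voxel set for regional summaries
#'   (`"combined_sig"` or `"all_masked"`).
#' @param correction_factor Bonferroni factor for the paired tests;
#'   `NULL` = 9 regions x 4 measures.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 17, protocol = protocol_spec(),
                          subject_template = subject_spec(),
                          grid_shape = c(24, 24, 12), t_threshold = 3.43,
                          dpct_lt = 1, cvr_gt = 0.15, mask_prob = 0.8,
                          master_seed = 1L, output_dir = NULL,
                          cvr = cvr_config(), hrf = hrf_spec(),
                          glm_drift_order = 0, sim_drift_order = 2,
                          roi_voxel_set = "combined_sig",
                          correction_factor = NULL) {
  if (n_subjects < 1) stop("configuration error: n_subjects >= 1", call. = FALSE)
  stopifnot(is.finite(t_threshold), is.finite(dpct_lt), is.finite(cvr_gt),
            is.finite(mask_prob))
  structure(list(
    n_subjects = as.integer(n_subjects), protocol = protocol,
    subject_template = subject_template, grid_shape = grid_shape,
    t_threshold = t_threshold, dpct_lt = dpct_lt, cvr_gt = cvr_gt,
    mask_prob = mask_prob, master_seed = as.integer(master_seed),
    output_dir = output_dir, cvr = cvr, hrf = hrf,
    glm_drift_order = glm_drift_order, sim_drift_order = sim_drift_order,
    roi_voxel_set = roi_voxel_set,
    correction_factor = correction_factor %||% 9 * 4
  ), class = "cohort_config")
}

#' Read a cohort configuration from YAML
#'
#' Top-level keys mirror the [cohort_config()] arguments; `protocol`,
#' `subject` and `cvr` sub-maps are passed to [protocol_spec()],
#' [subject_spec()] and [cvr_config()].
#'
#' @param path YAML file.
#' @return a `cohort_config`.
#' @export
cohort_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("n_subjects", "grid_shape", "t_threshold", "dpct_lt", "cvr_gt",
              "mask_prob", "master_seed", "output_dir", "glm_drift_order",
              "sim_drift_order", "roi_voxel_set", "correction_factor"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$protocol)) args$protocol <- do.call(protocol_spec, y$protocol)
  if (!is.null(y$subject)) args$subject_template <- do.call(subject_spec, y$subject)
  if (!is.null(y$cvr)) args$cvr <- do.call(cvr_config, y$cvr)
  do.call(cohort_config, args)
}

.log_line <- function(con, run_id, stage, subject, msg) {
  line <- sprintf("[%s] run=%s stage=%s subject=%s %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), run_id, stage,
                  subject, msg)
  if (!is.null(con)) writeLines(line, con)
  invisible(line)
}

.stage <- function(con, run_id, stage, subject, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed for subject '%s': %s",
                 stage, subject, conditionMessage(e)), call. = FALSE))
  .log_line(con, run_id, stage, subject,
            sprintf("done in %.2fs", proc.time()[["elapsed"]] - t0))
  out
}

#' Run a full synthetic cohort through the analysis pipeline
#'
#' For each subject: build the phantom, simulate the CVR and task runs
#' under both CO2 baselines, map CVR, fit the task GLM, threshold, form
#' the combined significant-voxel set, and summarize per region. Then
#' assemble the group report: whole-brain CVR per condition and pooled,
#' group regional means, paired condition tests, CVR-vs-activation
#' regressions, and the false-negative voxel summary. Deterministic given
#' `master_seed`.
#'
#' @param config a [cohort_config()].
#' @return object of class `cohort_report`.
#' @export
run_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  proto <- config$protocol
  out_dir <- config$output_dir
  logcon <- NULL
  run_id <- sprintf("cohort-%d", config$master_seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    logcon <- file(file.path(out_dir, "run.log"), open = "wt")
    on.exit(close(logcon), add = TRUE)
  }

  subj_rows <- list(); wb_rows <- list(); count_rows <- list()
  fn_rows <- list(); low_rows <- list()
  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("sub-%02d", i)
    tmpl <- config$subject_template
    spec <- subject_spec(
      subject_id = sid, resting_petco2_mmHg = tmpl$resting_petco2_mmHg,
      region_truth = tmpl$region_truth,
      lag_range_seconds = tmpl$lag_range_seconds,
      noise_sd_pct = tmpl$noise_sd_pct,
      drift_amplitude_pct = tmpl$drift_amplitude_pct,
      seed = derive_seed(config$master_seed, i, 0L),
      s0 = tmpl$s0, s0_background = tmpl$s0_background)

    phan <- .stage(logcon, run_id, "phantom", sid,
                   make_phantom(spec, config$grid_shape))
    mask <- make_analysis_mask(phan$gm_prob, phan$wm_prob, config$mask_prob)

    fits_cvr <- list(); fits_task <- list()
    for (cond in c("normo", "hyper")) {
      tr_cvr <- make_co2_trace(proto, cond, spec$resting_petco2_mmHg)
      run_cvr <- .stage(logcon, run_id, paste0("simulate-cvr-", cond), sid,
        simulate_cvr_run(phan, tr_cvr, proto, cond,
                         seed = derive_seed(config$master_seed, i,
                                            if (cond == "normo") 1L else 2L),
                         drift_order = config$sim_drift_order))
      cvr_cfg <- config$cvr
      if (is.null(cvr_cfg$baseline_seconds))
        cvr_cfg$baseline_seconds <- proto$clamp_seconds
      fits_cvr[[cond]] <- .stage(logcon, run_id, paste0("cvr-map-", cond), sid,
        compute_cvr_map(run_cvr, tr_cvr, mask, cvr_cfg))

      base <- spec$resting_petco2_mmHg +
        if (cond == "hyper") proto$hypercapnic_offset_mmHg else 0
      tp <- make_task_paradigm(proto, base)
      run_task <- .stage(logcon, run_id, paste0("simulate-task-", cond), sid,
        simulate_task_run(phan, tp$paradigm, proto, cond,
                          seed = derive_seed(config$master_seed, i,
                                             if (cond == "normo") 3L else 4L),
                          drift_order = config$sim_drift_order,
                          hrf = config$hrf))
      reg <- hrf_convolved_regressor(tp$paradigm, config$hrf,
                                     proto$n_volumes_task, proto$tr_seconds)
      X <- build_design(reg, drift_order = config$glm_drift_order)
      fit <- .stage(logcon, run_id, paste0("glm-", cond), sid,
                    fit_task_glm(run_task, X, mask))
      fits_task[[cond]] <- threshold_tmap(fit, config$t_threshold)

      if (!is.null(out_dir)) {
        sdir <- file.path(out_dir, sid)
        dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
        write_volume(fits_cvr[[cond]]$cvr, file.path(sdir, paste0("cvr_", cond, ".nii.gz")))
        write_volume(fits_task[[cond]]$tvalue, file.path(sdir, paste0("task_t_", cond, ".nii.gz")))
        write_co2_trace(tr_cvr, file.path(sdir, paste0("co2_", cond, ".csv")))
      }
    }

    comb <- combined_sig_mask(fits_task$normo$sig_mask, fits_task$hyper$sig_mask)
    for (cond in c("normo", "hyper")) {
      tab <- summarize_roi(fits_cvr[[cond]], fits_task[[cond]], phan,
                           voxel_set = config$roi_voxel_set,
                           combined_mask = comb)
      tab$subject <- sid
      subj_rows[[length(subj_rows) + 1]] <- tab
      wb_rows[[length(wb_rows) + 1]] <- data.frame(
        subject = sid, condition = cond,
        mean_cvr = fits_cvr[[cond]]$mean_cvr, stringsAsFactors = FALSE)
      cn <- count_significant(fits_task[[cond]]$sig_mask, phan)
      count_rows[[length(count_rows) + 1]] <- data.frame(
        subject = sid, condition = cond, region = names(cn),
        n_sig_voxels = unname(cn), stringsAsFactors = FALSE)
    }
    fn <- false_negative_voxels(fits_task$normo$sig_mask,
                                fits_task$hyper$sig_mask, phan)
    fn_rows[[length(fn_rows) + 1]] <- data.frame(
      subject = sid, region = names(fn$counts),
      n_false_negative = unname(fn$counts), stringsAsFactors = FALSE)
    low <- low_activation_high_cvr(fits_task$normo$dpct, fits_cvr$normo$cvr,
                                   fits_task$normo$sig_mask,
                                   config$dpct_lt, config$cvr_gt)
    lc <- count_significant(low, phan)
    low_rows[[length(low_rows) + 1]] <- data.frame(
      subject = sid, region = names(lc), n_low_act_high_cvr = unname(lc),
      stringsAsFactors = FALSE)
  }

  per_subject <- do.call(rbind, subj_rows)
  whole_brain_subject <- do.call(rbind, wb_rows)
  counts <- do.call(rbind, count_rows)
  fn_tab <- do.call(rbind, fn_rows)
  low_tab <- do.call(rbind, low_rows)

  wb <- stats::aggregate(mean_cvr ~ condition, whole_brain_subject, mean_sd)
  whole_brain <- data.frame(condition = c(wb$condition, "pooled"),
                            mean_cvr = c(wb$mean_cvr[, "mean"],
                                         mean(whole_brain_subject$mean_cvr)),
                            sd_cvr = c(wb$mean_cvr[, "sd"],
                                       stats::sd(whole_brain_subject$mean_cvr)),
                            stringsAsFactors = FALSE)

  group <- if (config$n_subjects >= 2) summarize_group(per_subject) else NULL

  paired <- NULL; regressions <- NULL
  if (config$n_subjects >= 2) {
    paired <- .paired_tests(per_subject, counts, config$correction_factor)
    regressions <- .roi_regressions(per_subject)
  }

  rep <- structure(list(
    per_subject = per_subject, whole_brain_subject = whole_brain_subject,
    whole_brain = whole_brain, group = group, counts = counts,
    paired_tests = paired, regressions = regressions,
    false_negatives = fn_tab, low_activation = low_tab,
    config = config, call = match.call()
  ), class = "cohort_report")

  if (!is.null(out_dir)) {
    .write_report_csvs(rep, out_dir)
    summ <- list(run_id = run_id, n_subjects = config$n_subjects,
                 master_seed = config$master_seed,
                 whole_brain = whole_brain)
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    .log_line(logcon, run_id, "report", "-", "written")
  }
  rep
}

.paired_tests <- function(per_subject, counts, correction_factor) {
  res <- list()
  measures <- list(
    cvr_dpct = list(mod = "cvr", col = "mean_dpct"),
    fmri_dpct = list(mod = "fmri", col = "mean_dpct"),
    fmri_t = list(mod = "fmri", col = "mean_tvalue"))
  for (r in unique(per_subject$region)) {
    for (m in names(measures)) {
      mm <- measures[[m]]
      sub <- per_subject[per_subject$region == r &
                           per_subject$modality == mm$mod, ]
      x <- sub[sub$condition == "normo", ]
      y <- sub[sub$condition == "hyper", ]
      y <- y[match(x$subject, y$subject), ]
      vx <- x[[mm$col]]; vy <- y[[mm$col]]
      ok <- is.finite(vx) & is.finite(vy)
      if (sum(ok) < 2) next
      pt <- paired_condition_test(vx[ok], vy[ok], correction_factor, region = r)
      pt$measure <- m
      res[[length(res) + 1]] <- pt
    }
    cs <- counts[counts$region == r, ]
    xn <- cs[cs$condition == "normo", ]
    xh <- cs[cs$condition == "hyper", ]
    xh <- xh[match(xn$subject, xh$subject), ]
    pt <- paired_condition_test(xn$n_sig_voxels, xh$n_sig_voxels,
                                correction_factor, region = r)
    pt$measure <- "n_sig_voxels"
    res[[length(res) + 1]] <- pt
  }
  do.call(rbind, res)
}

.roi_regressions <- function(per_subject) {
  res <- list()
  for (r in unique(per_subject$region)) {
    sub <- per_subject[per_subject$region == r, ]
    wide <- merge(
      sub[sub$modality == "cvr", c("subject", "condition", "mean_dpct", "mean_tvalue")],
      sub[sub$modality == "fmri", c("subject", "condition", "mean_dpct", "mean_tvalue")],
      by = c("subject", "condition"), suffixes = c("_cvr", "_fmri"))
    for (pairing in c("dpct", "tvalue")) {
      xcol <- paste0("mean_", pairing, "_cvr")
      ycol <- paste0("mean_", pairing, "_fmri")
      for (cs in c("normo", "hyper", "pooled")) {
        w <- if (cs == "pooled") wide else wide[wide$condition == cs, ]
        ok <- is.finite(w[[xcol]]) & is.finite(w[[ycol]])
        if (sum(ok) < 3 || stats::sd(w[[xcol]][ok]) == 0) next
        rg <- regress_cvr_vs_dpct(w[[xcol]][ok], w[[ycol]][ok])
        res[[length(res) + 1]] <- data.frame(
          region = r, pairing = pairing, conditions = cs,
          slope = rg$slope, intercept = rg$intercept, r = rg$r, p = rg$p,
          n_points = rg$n_points, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, res)
}

.write_report_csvs <- function(rep, out_dir) {
  wr <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wr(rep$per_subject, "per_subject_roi.csv")
  wr(rep$whole_brain_subject, "whole_brain_subject.csv")
  wr(rep$whole_brain, "whole_brain.csv")
  if (!is.null(rep$group)) wr(rep$group, "group_roi.csv")
  wr(rep$counts, "significant_voxel_counts.csv")
  if (!is.null(rep$paired_tests)) wr(rep$paired_tests, "paired_tests.csv")
  if (!is.null(rep$regressions)) wr(rep$regressions, "regressions.csv")
  wr(rep$false_negatives, "false_negatives.csv")
  wr(rep$low_activation, "low_activation_high_cvr.csv")
  invisible(NULL)
}

#' Group mean and standard deviation of regional summaries
#'
#' Collapses per-subject ROI rows to group mean plus/minus sample
#' standard deviation (n - 1 denominator) per region, condition and
#' modality. A (region, condition, modality) cell missing for some
#' subject is flagged.
#'
#' @param per_subject_tables a `roi_table` with a `subject` column, or a
#'   list of such tables.
#' @return data.frame with mean and sd columns for `mean_dpct`,
#'   `mean_tvalue` and `n_sig_voxels`, plus `n_subjects` and `flag`.
#' @export
summarize_group <- function(per_subject_tables) {
  tab <- if (is.data.frame(per_subject_tables)) per_subject_tables
         else do.call(rbind, per_subject_tables)
  ns <- length(unique(tab$subject))
  if (ns < 2)
    stop("configuration error: group summary needs at least 2 subjects", call. = FALSE)
  key <- interaction(tab$region, tab$condition, tab$modality, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    s <- tab[key == k, ]
    data.frame(
      region = s$region[1], condition = s$condition[1], modality = s$modality[1],
      mean_dpct = mean(s$mean_dpct, na.rm = TRUE),
      sd_dpct = stats::sd(s$mean_dpct, na.rm = TRUE),
      mean_tvalue = mean(s$mean_tvalue, na.rm = TRUE),
      sd_tvalue = stats::sd(s$mean_tvalue, na.rm = TRUE),
      mean_n_sig = mean(s$n_sig_voxels, na.rm = TRUE),
      sd_n_sig = stats::sd(s$n_sig_voxels, na.rm = TRUE),
      n_subjects = nrow(s),
      flag = if (nrow(s) < ns) "missing_cells" else "",
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
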