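#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("Acquisition protocol: TR %gs; CVR run %d vols (%gs clamp + %+g mmHg x %gs step); task run %d vols (%d x %gs blocks)\n",
              x$tr_seconds, x$n_volumes_cvr, x$clamp_seconds, x$step_mmHg,
              x$step_seconds, x$n_volumes_task, x$n_task_blocks,
              x$task_block_seconds))
  invisible(x)
}

#' @export
print.subject_spec <- function(x, ...) {
  cat(sprintf("Subject %s: resting PetCO2 %g mmHg, noise %g%%, drift %g%%, lags [%g, %g]s, seed %d\n",
              x$subject_id, x$resting_petco2_mmHg, x$noise_sd_pct,
              x$drift_amplitude_pct, x$lag_range_seconds[1],
              x$lag_range_seconds[2], x$seed))
  invisible(x)
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Phantom %s: grid %s, %d regions + background (%d brain voxels)\n",
              x$spec$subject_id, paste(x$grid_shape, collapse = "x"),
              length(x$region_names), sum(x$labels > 0)))
  invisible(x)
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("BOLD %s run (%s): %s voxels x %d volumes, TR %gs\n",
              x$run_type, x$condition, paste(d[1:3], collapse = "x"), d[4], x$tr))
  invisible(x)
}

#' @export
print.cvr_fit <- function(x, ...) {
  cat(sprintf("Voxel-wise BOLD-CVR map (%s): %d masked voxels, whole-mask mean CVR %.4f %%/mmHg\n",
              x$condition, sum(x$mask), x$mean_cvr))
  invisible(x)
}

#' @export
summary.cvr_fit <- function(object, ...) {
  v <- object$cvr[object$mask]
  l <- object$lag[object$mask]
  out <- list(condition = object$condition, n_voxels = sum(object$mask),
              mean_cvr = mean(v), sd_cvr = stats::sd(v),
              lag_range = range(l), mean_lag = mean(l),
              n_flagged = sum(object$flags[object$mask] > 0, na.rm = TRUE))
  class(out) <- "summary.cvr_fit"
  out
}

#' @export
print.summary.cvr_fit <- function(x, ...) {
  cat(sprintf("BOLD-CVR map (%s)\n", x$condition))
  cat(sprintf("  voxels in mask : %d (%d flagged)\n", x$n_voxels, x$n_flagged))
  cat(sprintf("  CVR            : %.4f +/- %.4f %%/mmHg\n", x$mean_cvr, x$sd_cvr))
  cat(sprintf("  lag            : mean %.2f s, range [%g, %g] s\n",
              x$mean_lag, x$lag_range[1], x$lag_range[2]))
  invisible(x)
}

#' @export
coef.cvr_fit <- function(object, ...) {
  object$cvr[object$mask]
}

#' @export
print.activation_fit <- function(x, ...) {
  nsig <- if (is.null(x$sig_mask)) NA_integer_ else sum(x$sig_mask)
  cat(sprintf("Task activation map (%s): %d masked voxels%s\n",
              x$condition, sum(x$mask),
              if (is.na(nsig)) " (unthresholded)"
              else sprintf(", %d significant at t > %.2f", nsig, x$threshold)))
  invisible(x)
}

#' @export
summary.activation_fit <- function(object, ...) {
  v <- object$dpct[object$mask]; tv <- object$tvalue[object$mask]
  out <- list(condition = object$condition, n_voxels = sum(object$mask),
              mean_dpct = mean(v), sd_dpct = stats::sd(v),
              mean_t = mean(tv), threshold = object$threshold,
              n_sig = if (is.null(object$sig_mask)) NA_integer_
                      else sum(object$sig_mask))
  class(out) <- "summary.activation_fit"
  out
}

#' @export
print.summary.activation_fit <- function(x, ...) {
  cat(sprintf("Task activation (%s)\n", x$condition))
  cat(sprintf("  voxels in mask : %d\n", x$n_voxels))
  cat(sprintf("  dpct           : %.4f +/- %.4f %%\n", x$mean_dpct, x$sd_dpct))
  cat(sprintf("  mean t         : %.2f\n", x$mean_t))
  if (!is.na(x$n_sig))
    cat(sprintf("  significant    : %d voxels at t > %.2f\n", x$n_sig, x$threshold))
  invisible(x)
}

#' @export
coef.activation_fit <- function(object, ...) {
  object$dpct[object$mask]
}

#' @export
print.cvr_regression <- function(x, ...) {
  cat(sprintf("Activation ~ CVR: slope %.3f, intercept %.3f, r %.3f, p %.3g (n = %d)\n",
              x$slope, x$intercept, x$r, x$p, x$n_points))
  invisible(x)
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Synthetic cohort report: %d subjects, master seed %d\n",
              x$config$n_subjects, x$config$master_seed))
  wb <- x$whole_brain
  for (i in seq_len(nrow(wb)))
    cat(sprintf("  whole-brain CVR (%s): %.3f +/- %.3f %%/mmHg\n",
                wb$condition[i], wb$mean_cvr[i], wb$sd_cvr[i]))
  if (!is.null(x$false_negatives))
    cat(sprintf("  false-negative voxels (normo sig, hyper not): %.0f per subject on average\n",
                mean(tapply(x$false_negatives$n_false_negative,
                            x$false_negatives$subject, sum))))
  invisible(x)
}

#' @export
summary.cohort_report <- function(object, ...) {
  object$group
}

#' Scatter of ROI-mean task activation against ROI-mean CVR
#'
#' One point per subject, region and condition; the least-squares line is
#' fitted over the pooled points.
#'
#' @param x a `cohort_report`.
#' @param pairing `"dpct"` (percent signal change) or `"tvalue"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cohort_report <- function(x, pairing = c("dpct", "tvalue"), ...) {
  pairing <- match.arg(pairing)
  col <- paste0("mean_", pairing)
  ps <- x$per_subject
  cvr <- ps[ps$modality == "cvr", c("subject", "condition", "region", col)]
  fm <- ps[ps$modality == "fmri", c("subject", "condition", "region", col)]
  w <- merge(cvr, fm, by = c("subject", "condition", "region"),
             suffixes = c("_cvr", "_fmri"))
  xs <- w[[paste0(col, "_cvr")]]; ys <- w[[paste0(col, "_fmri")]]
  ok <- is.finite(xs) & is.finite(ys)
  graphics::plot(xs[ok], ys[ok],
                 col = ifelse(w$condition[ok] == "normo", "blue", "red"),
                 pch = 16,
                 xlab = if (pairing == "dpct") "BOLD-CVR (%/mmHg)" else "CVR t-value",
                 ylab = if (pairing == "dpct") "task %fMRI signal change" else "task t-value",
                 ...)
  if (sum(ok) >= 3 && stats::sd(xs[ok]) > 0)
    graphics::abline(stats::lm(ys[ok] ~ xs[ok]), lwd = 2)
  graphics::legend("topleft", legend = c("normocapnia", "hypercapnia"),
                   col = c("blue", "red"), pch = 16, bty = "n")
  invisible(x)
}
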