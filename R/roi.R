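#' ROI label map
#'
#' @param labels integer volume; 0 is background.
#' @param names named integer vector mapping region name to label value,
#'   or a character vector naming labels `1..k` in order.
#' @return list of class `roi_label_map`.
#' @export
roi_label_map <- function(labels, names) {
  if (is.character(names)) names <- stats::setNames(seq_along(names), names)
  lab_vals <- sort(unique(as.vector(labels)))
  lab_vals <- lab_vals[lab_vals != 0]
  unknown <- setdiff(lab_vals, names)
  if (length(unknown))
    stop(sprintf("labeling error: labels without a name: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  structure(list(labels = labels, names = names), class = "roi_label_map")
}

.as_label_map <- function(labels) {
  if (inherits(labels, "roi_label_map")) return(labels)
  if (inherits(labels, "phantom"))
    return(roi_label_map(labels$labels, labels$region_names))
  stop("labeling error: expected a roi_label_map or phantom", call. = FALSE)
}

#' Regional summary of CVR and task activation
#'
#' For each region, the mean CVR, mean task percent signal change and
#' mean t-values over a chosen voxel set: either the combined significant
#' voxels (significant in at least one condition's task run — the voxel
#' set used for cross-condition comparisons) or all masked voxels of the
#' region.
#'
#' @param cvr_fit a [compute_cvr_map()] result.
#' @param activation_fit a thresholded [fit_task_glm()] result.
#' @param labels a `roi_label_map` or `phantom`.
#' @param voxel_set `"combined_sig"` or `"all_masked"`.
#' @param combined_mask logical volume; required for
#'   `voxel_set = "combined_sig"` (see [combined_sig_mask()]).
#' @return data.frame of class `roi_table`: one row per region and
#'   modality (`cvr`, `fmri`) with `mean_dpct` (CVR slope for the cvr
#'   modality, task percent change for fmri), `mean_tvalue`,
#'   `n_sig_voxels`, `n_voxels`, `flag`.
#' @export
summarize_roi <- function(cvr_fit, activation_fit, labels,
                          voxel_set = c("combined_sig", "all_masked"),
                          combined_mask = NULL) {
  voxel_set <- match.arg(voxel_set)
  lm_ <- .as_label_map(labels)
  stopifnot(inherits(cvr_fit, "cvr_fit"), inherits(activation_fit, "activation_fit"))
  check_same_dim(lm_$labels, cvr_fit$cvr, "labels and cvr map")
  check_same_dim(lm_$labels, activation_fit$dpct, "labels and activation map")
  if (voxel_set == "combined_sig") {
    if (is.null(combined_mask))
      stop("configuration error: combined_sig needs a combined_mask", call. = FALSE)
    sel <- combined_mask
  } else {
    sel <- cvr_fit$mask & activation_fit$mask
  }
  sig <- activation_fit$sig_mask
  if (is.null(sig)) sig <- array(FALSE, dim(lm_$labels))

  rows <- list()
  for (r in names(lm_$names)) {
    in_region <- lm_$labels == lm_$names[[r]]
    vs <- in_region & sel
    nv <- sum(vs)
    nsig <- sum(sig & in_region)
    if (nv == 0) {
      for (mod in c("cvr", "fmri"))
        rows[[length(rows) + 1]] <- data.frame(
          region = r, condition = activation_fit$condition %||% NA_character_,
          modality = mod, mean_dpct = NA_real_, mean_tvalue = NA_real_,
          n_sig_voxels = nsig, n_voxels = 0L, flag = "empty_voxel_set",
          stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      region = r, condition = activation_fit$condition %||% NA_character_,
      modality = "cvr",
      mean_dpct = mean(cvr_fit$cvr[vs], na.rm = TRUE),
      mean_tvalue = mean(cvr_fit$tvalue[vs], na.rm = TRUE),
      n_sig_voxels = nsig, n_voxels = nv, flag = "", stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      region = r, condition = activation_fit$condition %||% NA_character_,
      modality = "fmri",
      mean_dpct = mean(activation_fit$dpct[vs], na.rm = TRUE),
      mean_tvalue = mean(activation_fit$tvalue[vs], na.rm = TRUE),
      n_sig_voxels = nsig, n_voxels = nv, flag = "", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("roi_table", "data.frame")
  out
}

#' Count significant voxels per region
#'
#' @param sig_mask logical volume.
#' @param labels a `roi_label_map` or `phantom`.
#' @return named integer vector, one count per region.
#' @export
count_significant <- function(sig_mask, labels) {
  lm_ <- .as_label_map(labels)
  check_same_dim(lm_$labels, sig_mask, "labels and mask")
  vapply(names(lm_$names),
         function(r) sum(sig_mask[lm_$labels == lm_$names[[r]]]),
         integer(1))
}

#' Paired comparison of a regional measure across the two CO2 conditions
#'
#' Two-sided paired Student t-test on per-subject differences, with a
#' Bonferroni correction. Over two conditions this is also exactly the
#' repeated-measures ANOVA of the condition factor, so
#' [repeated_measures_condition_test()] is an alias.
#'
#' @param values_normo,values_hyper equal-length per-subject vectors.
#' @param correction_factor Bonferroni multiplier (default 9 regions).
#' @param region optional region label carried into the result.
#' @return data.frame of class `paired_test` with `statistic`, `df`,
#'   `raw_p`, `corrected_p`, `n_subjects`, `correction_factor`, `flag`.
#' @export
paired_condition_test <- function(values_normo, values_hyper,
                                  correction_factor = 9, region = NA_character_) {
  if (length(values_normo) != length(values_hyper))
    stop("configuration error: unpaired samples", call. = FALSE)
  n <- length(values_normo)
  if (n < 2) stop("configuration error: need at least 2 pairs", call. = FALSE)
  d <- values_normo - values_hyper
  flag <- ""
  ## t.test itself rejects numerically-constant differences, so treat a
  ## residual spread at floating-point level as exactly zero
  degenerate <- stats::sd(d) <= 1e-10 * max(abs(mean(d)), .Machine$double.eps)
  if (degenerate) {
    if (isTRUE(all.equal(mean(d), 0)) || mean(d) == 0) {
      stat <- 0; p <- 1; dof <- n - 1
    } else {
      stat <- sign(mean(d)) * Inf; p <- 0; dof <- n - 1
      flag <- "zero_variance_differences"
    }
  } else {
    tt <- stats::t.test(values_normo, values_hyper, paired = TRUE)
    stat <- unname(tt$statistic); p <- tt$p.value; dof <- unname(tt$parameter)
  }
  out <- data.frame(region = region, statistic = stat, df = dof, raw_p = p,
                    corrected_p = min(1, p * correction_factor),
                    n_subjects = n, correction_factor = correction_factor,
                    flag = flag, stringsAsFactors = FALSE)
  class(out) <- c("paired_test", "data.frame")
  out
}

#' @rdname paired_condition_test
#' @export
repeated_measures_condition_test <- paired_condition_test

#' Regression of task activation on CVR across ROI means
#'
#' Least-squares regression of ROI-averaged task activation on
#' ROI-averaged CVR (CVR as the independent variable), with the Pearson
#' correlation and the slope's t-test p-value. With a single predictor,
#' stepwise selection degenerates to this simple fit.
#'
#' @param cvr ROI-mean CVR values (or a 2-column data.frame/matrix of
#'   `(cvr, dpct)` points).
#' @param dpct ROI-mean activation values.
#' @return list of class `cvr_regression`: `slope`, `intercept`, `r`,
#'   `p`, `n_points`.
#' @export
regress_cvr_vs_dpct <- function(cvr, dpct = NULL) {
  if (is.null(dpct)) {
    pts <- as.data.frame(cvr)
    cvr <- pts[[1]]; dpct <- pts[[2]]
  }
  keep <- is.finite(cvr) & is.finite(dpct)
  cvr <- cvr[keep]; dpct <- dpct[keep]
  n <- length(cvr)
  if (n < 3) stop("configuration error: need at least 3 points", call. = FALSE)
  if (stats::sd(cvr) == 0)
    stop("degenerate-regression error: zero predictor variance", call. = FALSE)
  fit <- stats::lm(dpct ~ cvr)
  ## summary.lm warns on numerically perfect fits; those are legitimate
  ## inputs here (noise-free cohorts, collinear ROI means)
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = unname(stats::cor(cvr, dpct)),
                 p = sm$coefficients[2, 4], n_points = n),
            class = "cvr_regression")
}

#' False-negative activation voxels
#'
#' Voxels significant under normocapnia but sub-threshold under the
#' hypercapnic (CVR-impaired) condition: apparent deactivation in tissue
#' known to respond, i.e. type II error induced by exhausted vasodilatory
#' reserve.
#'
#' @param sig_mask_normo,sig_mask_hyper logical volumes.
#' @param labels optional `roi_label_map`/`phantom` for per-region counts.
#' @return list: `volume` (logical), `n_total`, and `counts` per region
#'   when labels are given.
#' @export
false_negative_voxels <- function(sig_mask_normo, sig_mask_hyper, labels = NULL) {
  check_same_dim(sig_mask_normo, sig_mask_hyper, "significance masks")
  v <- sig_mask_normo & !sig_mask_hyper
  out <- list(volume = v, n_total = sum(v))
  if (!is.null(labels)) out$counts <- count_significant(v, labels)
  out
}

#' Activated voxels with low task response but preserved CVR
#'
#' Selects significant voxels whose task percent signal change is below
#' `dpct_lt` (strict) while CVR exceeds `cvr_gt` (strict): responding
#' tissue whose activation is weak despite intact vasodilatory capacity.
#'
#' @param dpct_map,cvr_map numeric volumes.
#' @param sig_mask logical volume of activated voxels.
#' @param dpct_lt activation threshold (percent; default 1).
#' @param cvr_gt CVR threshold (percent/mmHg; default 0.15).
#' @return logical volume.
#' @export
low_activation_high_cvr <- function(dpct_map, cvr_map, sig_mask,
                                    dpct_lt = 1, cvr_gt = 0.15) {
  check_same_dim(dpct_map, cvr_map, "maps")
  check_same_dim(dpct_map, sig_mask, "map and mask")
  stopifnot(is.finite(dpct_lt), is.finite(cvr_gt))
  sel <- sig_mask & (dpct_map < dpct_lt) & (cvr_map > cvr_gt)
  sel[is.na(sel)] <- FALSE
  sel
}
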