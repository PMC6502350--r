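#' Read and write volumes and runs as NIfTI-1
#'
#' Thin wrappers over RNifti. Volumes are written with a 3 mm isotropic
#' voxel grid and an RAS+ identity orientation; 4D runs carry the TR in
#' the fourth pixdim slot.
#'
#' @param vol 3D numeric or logical array.
#' @param path output file (`.nii` or `.nii.gz`).
#' @param voxel_mm isotropic voxel size (mm).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns
#'   a plain array.
#' @export
write_volume <- function(vol, path, voxel_mm = 3) {
  im <- RNifti::asNifti(array(as.numeric(vol), dim = dim(vol)))
  RNifti::pixdim(im) <- rep(voxel_mm, 3)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  as.array(RNifti::readNifti(path))
}

#' @rdname write_volume
#' @param run a `bold_run`.
#' @export
write_bold_run <- function(run, path, voxel_mm = 3) {
  stopifnot(inherits(run, "bold_run"))
  im <- RNifti::asNifti(run$data)
  RNifti::pixdim(im) <- c(rep(voxel_mm, 3), run$tr)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname write_volume
#' @param condition,run_type metadata restored onto the read run.
#' @export
read_bold_run <- function(path, condition = "normo", run_type = "cvr") {
  im <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(im)
  tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  structure(list(data = as.array(im), tr = tr, condition = condition,
                 run_type = run_type), class = "bold_run")
}

#' Read and write CO2 traces and paradigms as CSV
#'
#' Formats: `time_s,petco2_mmhg` for traces and
#' `onset_s,duration_s,condition` for paradigms.
#'
#' @param trace a `co2_trace`.
#' @param path CSV file.
#' @return readers return the corresponding classed data.frame.
#' @export
write_co2_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[, c("time_s", "petco2_mmhg")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_co2_trace
#' @param condition condition label restored onto the read trace.
#' @export
read_co2_trace <- function(path, condition = "normo") {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "petco2_mmhg") %in% names(df)))
  if (nrow(df) < 2 || is.unsorted(df$time_s, strictly = TRUE) ||
      any(!is.finite(df$petco2_mmhg)))
    stop("invalid CO2 trace: need >= 2 samples, strictly increasing time, finite values",
         call. = FALSE)
  structure(df, class = c("co2_trace", "data.frame"), condition = condition,
            baseline_mmHg = df$petco2_mmhg[1])
}

#' @rdname write_co2_trace
#' @param paradigm a `paradigm` data.frame.
#' @export
write_paradigm <- function(paradigm, path) {
  utils::write.csv(as.data.frame(paradigm), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_co2_trace
#' @export
read_paradigm <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("onset_s", "duration_s") %in% names(df)))
  if (is.unsorted(df$onset_s))
    stop("invalid paradigm: onsets must be sorted", call. = FALSE)
  if (nrow(df) > 1 &&
      any(df$onset_s[-1] < (df$onset_s + df$duration_s)[-nrow(df)]))
    stop("invalid paradigm: overlapping blocks", call. = FALSE)
  class(df) <- c("paradigm", "data.frame")
  df
}

#' Write the three CVR result volumes and a run summary
#'
#' @param fit a `cvr_fit`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_cvr_maps <- function(fit, dir) {
  stopifnot(inherits(fit, "cvr_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(fit$cvr, file.path(dir, "cvr.nii.gz"))
  write_volume(fit$lag, file.path(dir, "lag.nii.gz"))
  write_volume(fit$tvalue, file.path(dir, "tvalue.nii.gz"))
  write_volume(fit$mask, file.path(dir, "mask.nii.gz"))
  utils::write.csv(data.frame(condition = fit$condition,
                              mean_cvr = fit$mean_cvr,
                              n_mask_voxels = sum(fit$mask)),
                   file.path(dir, "summary.csv"), row.names = FALSE)
  invisible(dir)
}
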