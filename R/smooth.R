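## Zero-phase low-pass Butterworth. Forward+backward pass over an
## odd-reflection-padded series so that trends pass through without edge
## transients or phase delay (signal::filtfilt's default edge handling
## distorts ramps, hence the explicit padding here; the filter design is
## signal::butter).
.lowpass_zerophase <- function(x, tr, cutoff_hz, order = 4) {
  n <- length(x)
  nyq <- 1 / (2 * tr)
  if (cutoff_hz >= nyq)
    stop("configuration error: low-pass cutoff at or above Nyquist", call. = FALSE)
  if (cutoff_hz <= 0)
    stop("configuration error: low-pass cutoff must be positive", call. = FALSE)
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  npad <- min(n - 1, max(15 * order, 60))
  ## demean so the filter acts on deviations only: the DC component passes
  ## exactly and the whole operation is exactly affine-equivariant
  mu <- mean(x)
  x <- x - mu
  xb <- 2 * x[1] - x[(npad + 1):2]
  xe <- 2 * x[n] - x[(n - 1):(n - npad)]
  xx <- c(xb, x, xe)
  y <- signal::filter(bf, xx)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  y[(npad + 1):(npad + n)] + mu
}

#' Temporally smooth a BOLD time series
#'
#' Two-stage smoothing used on CVR data before regression: a zero-phase
#' low-pass Butterworth filter (removing thermal noise above the stimulus
#' band) followed by robust locally weighted regression (lowess with
#' bisquare reweighting), which suppresses outlying samples without
#' shifting the response in time. Output length equals input length; a
#' constant or straight-line input passes through unchanged away from the
#' edges.
#'
#' @param series numeric vector (length >= 10).
#' @param tr sampling interval (s).
#' @param cutoff_hz low-pass cutoff (Hz); must be below Nyquist.
#' @param loess_span smoother span as a fraction of the series length.
#' @param loess_iter robustness (bisquare) iterations.
#' @param filter_order Butterworth order.
#' @return smoothed numeric vector, same length as `series`.
#' @export
temporal_smooth <- function(series, tr, cutoff_hz = 0.1, loess_span = 0.1,
                            loess_iter = 2, filter_order = 4) {
  if (length(series) < 10)
    stop("configuration error: series too short to smooth", call. = FALSE)
  y <- .lowpass_zerophase(series, tr, cutoff_hz, filter_order)
  tt <- seq_along(y)
  base <- stats::lowess(tt, y, f = loess_span, iter = 0)$y
  if (loess_iter == 0) return(base)
  ## Bisquare reweighting needs a usable residual scale. When the plain
  ## fit is already (numerically) exact the residual median collapses and
  ## the robustness weights degenerate, so the robust pass only runs when
  ## residuals are non-negligible relative to the series' own spread.
  ## The trigger is scale- and offset-invariant, preserving the affine
  ## equivariance of the whole smoother.
  res_scale <- stats::median(abs(y - base))
  y_scale <- stats::mad(y, constant = 1) + .Machine$double.xmin
  if (res_scale <= 1e-6 * y_scale) return(base)
  stats::lowess(tt, y, f = loess_span, iter = loess_iter)$y
}

## Column-wise temporal_smooth for an n x V matrix
.smooth_matrix <- function(Y, tr, cutoff_hz, loess_span, loess_iter, filter_order = 4) {
  for (j in seq_len(ncol(Y)))
    Y[, j] <- temporal_smooth(Y[, j], tr, cutoff_hz, loess_span, loess_iter, filter_order)
  Y
}
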