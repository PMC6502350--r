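#' @keywords internal
"_PACKAGE"

## Evaluate `code` under a temporary RNG state seeded with `seed`,
## restoring the caller's .Random.seed afterwards. `seed = NULL` leaves
## the ambient RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-subject, per-stage random seed from a master seed
#'
#' Splitting rule used by [run_cohort()] so that subjects are mutually
#' independent and every cohort is reproducible from a single integer:
#' `(master_seed + 7919 * subject_index + stage) mod (2^31 - 1)`.
#'
#' @param master_seed integer master seed for the cohort.
#' @param subject_index 1-based subject index.
#' @param stage integer stage offset (0 phantom, 1 CVR normo, 2 CVR hyper,
#'   3 task normo, 4 task hyper).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, subject_index, stage = 0L) {
  as.integer((as.numeric(master_seed) + 7919 * subject_index + stage) %% 2147483647)
}

stop_dim <- function(what) {
  stop(sprintf("dimension error: %s", what), call. = FALSE)
}

check_same_dim <- function(a, b, what = "volumes") {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(da, db)) stop_dim(sprintf("%s have mismatched shapes", what))
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## Column-wise mean/sd ignoring NA, keeping names
mean_sd <- function(x) c(mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE))
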