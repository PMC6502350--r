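test_that("HRF-convolved regressor matches the direct convolution oracle", {
  hrf <- hrf_spec()

  ## single near-instant event: regressor proportional to the sampled HRF
  ev <- data.frame(onset_s = 10, duration_s = 0.1, condition = "task")
  class(ev) <- c("paradigm", "data.frame")
  r <- hrf_convolved_regressor(ev, hrf, 60, 2)
  tq <- (1:60 - 0.5) * 2
  href <- hrf_double_gamma(tq - 10, hrf)
  keep <- href > 1e-6
  ratio <- r[keep] / href[keep]
  expect_lt(diff(range(ratio)) / mean(ratio), 0.02)

  ## long block: unit-peak contract; plateau close to (but below) the peak
  ## because the running HRF integral overshoots before settling
  long <- data.frame(onset_s = 30, duration_s = 80, condition = "task")
  class(long) <- c("paradigm", "data.frame")
  rl <- hrf_convolved_regressor(long, hrf, 135, 2)
  orc <- oracle_convolved(long, hrf, 135, 2)
  expect_equal(max(orc$y / max(orc$y)), 1)
  expect_lte(max(rl), 1)
  plateau <- rl[tq_idx <- 45]  # t = 89 s, deep inside the block
  expect_gt(plateau, 0.85)
  expect_lt(plateau, 1)

  ## default block paradigm against the Riemann-sum oracle
  proto <- protocol_spec()
  tp <- make_task_paradigm(proto, 38)
  rr <- hrf_convolved_regressor(tp$paradigm, hrf, proto$n_volumes_task, 2)
  od <- oracle_convolved(tp$paradigm, hrf, proto$n_volumes_task, 2)
  oref <- stats::approx(od$t, od$y / max(od$y),
                        xout = (1:proto$n_volumes_task - 0.5) * 2)$y
  expect_equal(as.vector(rr), oref, tolerance = 1e-6)
  ## within each block the response peaks after the HRF peak delay
  first_block <- rr[(1:proto$n_volumes_task - 0.5) * 2 >= 30 &
                    (1:proto$n_volumes_task - 0.5) * 2 < 60]
  expect_gt(which.max(first_block), hrf$peak_delay / 2 - 1)

  empty <- tp$paradigm[0, ]
  class(empty) <- c("paradigm", "data.frame")
  r0 <- hrf_convolved_regressor(empty, hrf, 60, 2)
  expect_true(all(r0 == 0))
  expect_true(attr(r0, "flagged_empty"))
})

test_that("design matrix assembly counts columns and detects collinearity", {
  reg <- hrf_convolved_regressor(make_task_paradigm(protocol_spec(), 38)$paradigm,
                                 hrf_spec(), 135, 2)
  X0 <- build_design(reg)
  expect_equal(ncol(X0), 2)
  expect_identical(colnames(X0), c("task", "intercept"))

  motion <- matrix(rnorm(135 * 6), 135, 6)
  X10 <- build_design(reg, nuisance = motion, drift_order = 2)
  expect_equal(ncol(X10), 10)
  expect_equal(attr(X10, "rank"), 10)

  expect_error(build_design(reg, nuisance = cbind(task2 = reg)),
               "collinearity")
  expect_error(build_design(reg, nuisance = matrix(0, 10, 1)), "dimension")
})

test_that("task GLM is exact without noise and matches the matrix-algebra oracle", {
  proto <- small_protocol()
  spec <- uniform_spec(dpct = 0.85, noise = 0)
  ph <- make_phantom(spec, small_grid)
  tp <- make_task_paradigm(proto, 38)
  reg <- hrf_convolved_regressor(tp$paradigm, hrf_spec(),
                                 proto$n_volumes_task, proto$tr_seconds)
  X <- build_design(reg)
  mask <- ph$labels > 0
  run <- simulate_task_run(ph, tp$paradigm, proto, "normo", seed = 1, drift_order = 0)
  fit <- fit_task_glm(run, X, mask)
  expect_lt(max(abs(fit$dpct[mask] - 0.85)), 1e-9)

  ## random small instances against the oracle
  set.seed(7)
  n <- proto$n_volumes_task
  for (i in 1:25) {
    y <- rnorm(n)
    o <- oracle_ols(y, X)
    dims <- c(1, 1, 1, n)
    rn <- structure(list(data = array(100 + y, dims), tr = proto$tr_seconds,
                         condition = "normo", run_type = "task"),
                    class = "bold_run")
    f <- fit_task_glm(rn, X, array(TRUE, c(1, 1, 1)), baseline_window = 1:n)
    b0 <- mean(100 + y)
    o2 <- oracle_ols(100 * ((100 + y) / b0 - 1), X)
    expect_equal(f$dpct[1, 1, 1], o2$beta[1], tolerance = 1e-8)
    expect_equal(f$tvalue[1, 1, 1], o2$t[1], tolerance = 1e-8)
  }
})

test_that("adding a drift column orthogonal to the task changes t only via df", {
  proto <- small_protocol()
  n <- proto$n_volumes_task
  tp <- make_task_paradigm(proto, 38)
  reg <- hrf_convolved_regressor(tp$paradigm, hrf_spec(), n, proto$tr_seconds)
  X1 <- build_design(reg)
  ## orthogonalize a drift column against both design columns
  raw <- seq_len(n)
  drift <- raw - X1 %*% solve(crossprod(X1), crossprod(X1, raw))
  X2 <- cbind(X1[, "task", drop = FALSE], drift = as.vector(drift),
              intercept = 1)
  set.seed(11)
  y <- 0.5 * reg + rnorm(n)
  o1 <- oracle_ols(y, X1)
  o2 <- oracle_ols(y, X2)
  expect_equal(o1$beta[1], o2$beta[1], tolerance = 1e-10)
  ## same slope; t differs only through the residual df and drift fit
  expect_equal(o2$t[1] / o1$t[1],
               (o1$se[1] / o2$se[1]), tolerance = 1e-10)
})

test_that("thresholding is strict and monotone; combined masks are unions", {
  dims <- c(3, 1, 1)
  fit <- structure(list(
    tvalue = array(c(3.0, 3.43, 3.5), dims), dpct = array(1, dims),
    mask = array(TRUE, dims), sig_mask = NULL, threshold = NA_real_,
    condition = "normo"), class = "activation_fit")
  th <- threshold_tmap(fit, 3.43)
  expect_identical(as.vector(th$sig_mask), c(FALSE, FALSE, TRUE))

  low <- threshold_tmap(fit, 10)
  expect_equal(sum(low$sig_mask), 0)

  ## monotonicity over random maps
  set.seed(3)
  for (i in 1:20) {
    tv <- array(rnorm(64, 2, 2), c(4, 4, 4))
    f <- structure(list(tvalue = tv, dpct = tv, mask = array(TRUE, c(4, 4, 4)),
                        sig_mask = NULL, threshold = NA_real_,
                        condition = "normo"), class = "activation_fit")
    thr <- sort(runif(2, 0, 4))
    m_lo <- threshold_tmap(f, thr[1])$sig_mask
    m_hi <- threshold_tmap(f, thr[2])$sig_mask
    expect_true(all(m_lo | !m_hi))          # raising threshold never adds voxels
    ## union properties
    m_u <- combined_sig_mask(m_lo, m_hi)
    expect_equal(sum(m_u), sum(m_lo) + sum(m_hi) - sum(m_lo & m_hi))
    expect_true(all(m_u | !m_lo))
    expect_true(all(m_u | !m_hi))
  }
  a <- array(c(rep(TRUE, 10), rep(FALSE, 54)), c(4, 4, 4))
  b <- array(c(rep(FALSE, 59), rep(TRUE, 5)), c(4, 4, 4))
  expect_equal(sum(combined_sig_mask(a, b)), 15)
  expect_identical(combined_sig_mask(a, a), a)
  expect_error(combined_sig_mask(a, array(TRUE, c(2, 2, 2))), "dimension")
})

test_that("pure-noise voxels rarely exceed the significance threshold", {
  ## null calibration at the run length used in practice (135 volumes)
  proto <- protocol_spec()
  tp <- make_task_paradigm(proto, 38)
  reg <- hrf_convolved_regressor(tp$paradigm, hrf_spec(),
                                 proto$n_volumes_task, proto$tr_seconds)
  X <- build_design(reg)
  set.seed(123)
  n_vox <- 400
  dims <- c(n_vox, 1, 1, proto$n_volumes_task)
  dat <- array(100 * (1 + matrix(rnorm(n_vox * proto$n_volumes_task), n_vox) / 100),
               dims)
  run <- structure(list(data = dat, tr = 2, condition = "normo",
                        run_type = "task"), class = "bold_run")
  fit <- threshold_tmap(fit_task_glm(run, X, array(TRUE, dims[1:3])), 3.43)
  expect_lt(mean(fit$sig_mask), 0.005)
})
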