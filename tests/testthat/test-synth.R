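test_that("CO2 trace reproduces the clamp + pseudo-square step protocol", {
  proto <- protocol_spec()
  tr_n <- make_co2_trace(proto, "normo", 38)
  expect_equal(min(tr_n$petco2_mmhg), 38)
  expect_equal(max(tr_n$petco2_mmhg), 48)
  ## plateau held for the full step duration
  expect_gte(sum(tr_n$petco2_mmhg == 48), proto$step_seconds)
  ## clamped at baseline throughout the initial clamp
  expect_true(all(tr_n$petco2_mmhg[tr_n$time_s < proto$clamp_seconds] == 38))
  ## total duration covers the run
  expect_equal(nrow(tr_n), proto$n_volumes_cvr * proto$tr_seconds)

  tr_h <- make_co2_trace(proto, "hyper", 38)
  expect_equal(min(tr_h$petco2_mmhg), 44)
  expect_equal(attr(tr_h, "baseline_mmHg"), 44)

  flat <- make_co2_trace(protocol_spec(step_mmHg = 0), "normo", 38)
  expect_true(all(flat$petco2_mmhg == 38))

  expect_error(protocol_spec(step_seconds = -1), "positive")
  expect_error(protocol_spec(n_volumes_cvr = 10), "clamp \\+ step")
})

test_that("task paradigm alternates rest and task blocks on a constant clamp", {
  proto <- protocol_spec()
  tp <- make_task_paradigm(proto, 38)
  expect_equal(tp$paradigm$onset_s, c(30, 90, 150, 210))
  expect_equal(tp$paradigm$duration_s, rep(30, 4))
  expect_true(all(tp$trace$petco2_mmhg == 38))

  empty <- make_task_paradigm(protocol_spec(n_task_blocks = 0), 38)
  expect_equal(nrow(empty$paradigm), 0)
  expect_true(all(empty$trace$petco2_mmhg == 38))

  ## boxcar volume count: midpoints falling inside a block
  tmid <- (seq_len(proto$n_volumes_task) - 0.5) * proto$tr_seconds
  inside <- vapply(tmid, function(t)
    any(t >= tp$paradigm$onset_s & t < tp$paradigm$onset_s + tp$paradigm$duration_s),
    logical(1))
  expect_equal(sum(inside), 60)
})

test_that("phantom embeds exact region-wise truth and is seed-deterministic", {
  spec <- uniform_spec(cvr = 0.2, seed = 11)
  ph <- make_phantom(spec, small_grid)
  expect_true(all(ph$truth_cvr$normo[ph$labels > 0] == 0.2))
  expect_true(all(ph$truth_cvr$normo[ph$labels == 0] == 0))

  ph2 <- make_phantom(spec, small_grid)
  expect_identical(ph, ph2)

  ## literature-seeded spec: per-region mean equals the truth table exactly
  spec_t <- subject_spec(seed = 3)
  ph_t <- make_phantom(spec_t)
  truth <- default_region_truth()
  for (i in seq_len(nrow(truth))) {
    r <- truth$region[i]
    vox <- ph_t$labels == ph_t$region_names[[r]]
    expect_identical(mean(ph_t$truth_cvr$normo[vox]), truth$true_cvr_normo[i])
    expect_identical(mean(ph_t$truth_dpct$hyper[vox]), truth$true_dpct_hyper[i])
  }
  ## labels cover every voxel exactly once; equal-sized regions by design
  expect_true(all(ph_t$labels %in% 0:9))
  expect_equal(length(unique(tabulate(ph_t$labels[ph_t$labels > 0]))), 1L)
  ## lags quantized to the 1 s grid inside the configured range
  lags <- ph_t$truth_lag[ph_t$labels > 0]
  expect_true(all(lags == round(lags)))
  expect_true(all(lags >= 0 & lags <= 8))

  expect_error(make_phantom(spec, c(2, 2, 2)), "configuration error")
})

test_that("noise-free CVR run is exactly linear in the lagged CO2 regressor", {
  proto <- small_protocol()
  spec <- uniform_spec(cvr = 0.3, noise = 0, drift = 0, lag_range = c(0, 0))
  ph <- make_phantom(spec, small_grid)
  trc <- make_co2_trace(proto, "normo", 38)
  run <- simulate_cvr_run(ph, trc, proto, "normo", seed = 1, drift_order = 0)
  vox <- which(ph$labels == 1)[1]
  idx <- arrayInd(vox, small_grid)
  y <- run$data[idx[1], idx[2], idx[3], ]
  fit <- fit_voxel_cvr(y, trc, proto$tr_seconds, lag = 0,
                       baseline_window = 1:20)
  expect_equal(fit$cvr, 0.3, tolerance = 1e-10)
  expect_equal(fit$tvalue, 1e6)

  ## zero CVR everywhere: fitted slopes vanish
  spec0 <- uniform_spec(cvr = 0, dpct = 0, cvr_hyper = 0, dpct_hyper = 0)
  ph0 <- make_phantom(spec0, small_grid)
  run0 <- simulate_cvr_run(ph0, trc, proto, "normo", seed = 1, drift_order = 0)
  y0 <- run0$data[idx[1], idx[2], idx[3], ]
  expect_equal(stats::sd(y0), 0)
})

test_that("simulated lag is recovered by an exhaustive shift search", {
  proto <- small_protocol()
  spec <- uniform_spec(cvr = 0.3, noise = 0, lag_range = c(4, 4))
  ph <- make_phantom(spec, small_grid)
  trc <- make_co2_trace(proto, "normo", 38)
  run <- simulate_cvr_run(ph, trc, proto, "normo", seed = 1, drift_order = 0)
  vox <- which(ph$labels == 5)[3]
  idx <- arrayInd(vox, small_grid)
  y <- run$data[idx[1], idx[2], idx[3], ]
  expect_equal(oracle_best_lag(y, trc, proto$tr_seconds, -10:10), 4)
})

test_that("task run embeds the exact activation and respects the paradigm", {
  proto <- small_protocol()
  spec <- uniform_spec(dpct = 0.85, noise = 0)
  ph <- make_phantom(spec, small_grid)
  tp <- make_task_paradigm(proto, 38)
  run <- simulate_task_run(ph, tp$paradigm, proto, "normo", seed = 1, drift_order = 0)
  reg <- hrf_convolved_regressor(tp$paradigm, hrf_spec(),
                                 proto$n_volumes_task, proto$tr_seconds)
  mask <- ph$labels > 0
  fit <- fit_task_glm(run, build_design(reg), mask)
  expect_lt(max(abs(fit$dpct[mask] - 0.85)), 1e-9)

  ## no activation: t-map flat at zero
  spec0 <- uniform_spec(dpct = 0, dpct_hyper = 0, noise = 0)
  ph0 <- make_phantom(spec0, small_grid)
  run0 <- simulate_task_run(ph0, tp$paradigm, proto, "normo", seed = 1, drift_order = 0)
  fit0 <- threshold_tmap(fit_task_glm(run0, build_design(reg), mask), 0.1)
  expect_equal(sum(fit0$sig_mask), 0)
})

test_that("noisy activation estimate stays within 3 SE of the embedded truth", {
  proto <- small_protocol()
  spec <- uniform_spec(dpct = 0.85, noise = 1, seed = 5)
  ph <- make_phantom(spec, small_grid)
  tp <- make_task_paradigm(proto, 38)
  run <- simulate_task_run(ph, tp$paradigm, proto, "normo", seed = 99, drift_order = 0)
  reg <- hrf_convolved_regressor(tp$paradigm, hrf_spec(),
                                 proto$n_volumes_task, proto$tr_seconds)
  X <- build_design(reg)
  mask <- ph$labels > 0
  fit <- fit_task_glm(run, X, mask)
  ## regression SE from the design and the known noise level (1% of S0)
  XtXi <- solve(t(X) %*% X)
  se <- sqrt(XtXi["task", "task"])  # sigma = 1 in percent units
  dev <- abs(fit$dpct[mask] - 0.85)
  expect_gt(mean(dev < 3 * se), 0.99)
})

test_that("generators are seed-deterministic and percent-scale invariant", {
  proto <- small_protocol()
  spec <- uniform_spec(cvr = 0.25, noise = 1, drift = 0.5, seed = 2)
  ph <- make_phantom(spec, small_grid)
  trc <- make_co2_trace(proto, "normo", 38)
  r1 <- simulate_cvr_run(ph, trc, proto, "normo", seed = 7)
  r2 <- simulate_cvr_run(ph, trc, proto, "normo", seed = 7)
  expect_identical(r1$data, r2$data)

  ## doubling S0 changes nothing downstream of percent conversion
  truth2 <- spec$region_truth[spec$region_truth$region != "background", ]
  spec2 <- subject_spec(region_truth = truth2, noise_sd_pct = 1,
                        drift_amplitude_pct = 0.5, seed = 2, s0 = 2 * 340,
                        lag_range_seconds = c(0, 0), s0_background = 40)
  ph2 <- make_phantom(spec2, small_grid)
  r3 <- simulate_cvr_run(ph2, trc, proto, "normo", seed = 7)
  expect_equal(r3$data, 2 * r1$data, tolerance = 1e-12)
  mask <- ph$labels > 0
  f1 <- compute_cvr_map(r1, trc, mask)
  f3 <- compute_cvr_map(r3, trc, mask)
  expect_equal(f1$cvr, f3$cvr, tolerance = 1e-10)
  expect_equal(f1$tvalue, f3$tvalue, tolerance = 1e-8)
  expect_identical(f1$lag, f3$lag)
})

test_that("invalid subject configurations are rejected", {
  expect_error(subject_spec(noise_sd_pct = -1), "negative noise")
  truth <- default_region_truth()
  truth$true_cvr_hyper[3] <- -0.1
  expect_error(subject_spec(region_truth = truth), "non-negative")
  expect_error(subject_spec(region_truth = default_region_truth()[-1, ]),
               "nine motor regions")
})
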