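test_that("the analytic-signal phase of a planted rotation tracks omega*t", {
  omega <- 2 * pi * 1.5
  tt <- seq(0, 10, by = 0.01)
  cix <- cos(omega * tt); ciy <- sin(omega * tt)
  phx <- Arg(hilbert_analytic(cix))
  phy <- Arg(hilbert_analytic(ciy))
  cph <- atan2(sin(phx) + sin(phy + pi / 2), cos(phx) + cos(phy + pi / 2))
  interior <- 51:(length(tt) - 50)
  err <- abs(wrap_angle(cph[interior] - omega * tt[interior]))
  expect_lt(max(err), 0.05)
  # rotation frequency from the mean phase velocity, within 2 percent
  om_hat <- mean(wrap_angle(diff(cph[interior]))) / 0.01
  expect_lt(abs(om_hat - omega) / omega, 0.02)
})

test_that("equal phases average to themselves and short segments are missing", {
  a <- stats::runif(50, -pi, pi)
  expect_equal(cidyn:::circ_mean2(a, a), a, tolerance = 1e-12)

  raw <- matrix(stats::runif(6 * 40, 4, 6), nrow = 6)
  rm_ <- make_rate_matrix(raw)
  pl <- suppressWarnings(fit_jpca(rm_$rates, n_pc = 4))
  ph <- project_and_phase(rm_, pl, segments = list(1:8, 9:40))
  expect_true(all(is.na(ph$ci_phi[ph$segment == 1])))
  expect_true(all(!is.na(ph$ci_phi[ph$segment == 2])))
})

test_that("a single iteration reduces exactly to the event-aligned fit", {
  ses <- small_session(seed = 31, n_trials = 20, n_units = 12)
  subs <- accepted_subs(segment_session(ses$traces, ses$targets))
  rm_ <- bin_smooth_sqrt(ses$spikes, ses$session_length_ms)
  segs <- trial_segments(rm_, ses$trials)
  fit <- iterate_ciphase(rm_, subs$peak_time_ms, segments = segs, n_iter = 1)
  traj <- ci_average_by_event(rm_, subs$peak_time_ms, c(-500, 300), segs)
  plane <- align_plane(fit_jpca(traj, dt = 0.01), rm_, segs)
  expect_equal(fit$plane$basis, plane$basis, tolerance = 1e-12)
})

test_that("simulated sessions cycle counter-clockwise by convention", {
  ses <- small_session(seed = 37, n_trials = 25, n_units = 15)
  subs <- accepted_subs(segment_session(ses$traces, ses$targets))
  rm_ <- bin_smooth_sqrt(ses$spikes, ses$session_length_ms)
  segs <- trial_segments(rm_, ses$trials)
  fit <- iterate_ciphase(rm_, subs$peak_time_ms, segments = segs)
  dphi <- unlist(lapply(split(fit$phase$ci_phi, fit$phase$segment),
                        function(p) wrap_angle(diff(p))))
  expect_gt(mean(dphi, na.rm = TRUE), 0)
})

test_that("cross-validation is guarded and generalises on simulated data", {
  ses <- small_session(seed = 41, n_trials = 60, n_units = 20)
  subs <- accepted_subs(segment_session(ses$traces, ses$targets))
  rm_ <- bin_smooth_sqrt(ses$spikes, ses$session_length_ms)
  segs <- trial_segments(rm_, ses$trials)
  ev <- subs$peak_time_ms

  expect_error(crossval_ciphase(rm_, ev, ses$trials, k = 1), "at least 2")
  expect_error(crossval_ciphase(rm_, ev, ses$trials, k = 61), "exceeds")

  cv <- crossval_ciphase(rm_, ev, ses$trials, k = 5, seed = 2)
  expect_setequal(cv$folds$fold, 1:5)
  # held-out phase concentration at true peaks close to in-sample
  fit <- iterate_ciphase(rm_, ev, segments = segs)
  gt_cols <- cidyn:::time_to_col(rm_, ses$ground_truth$peak_time_ms)
  r_test <- circ_mean_sd(stats::na.omit(
    cv$phase$ci_phi[match(gt_cols, cv$phase$col)]))$R
  r_train <- circ_mean_sd(stats::na.omit(
    fit$phase$ci_phi[match(gt_cols, fit$phase$col)]))$R
  expect_gt(r_test, 0.5)
  expect_lt(abs(r_test - r_train) / r_train, 0.10)
})

test_that("timing offsets are invariant to uniform time translation", {
  ses <- small_session(seed = 43, n_trials = 15, n_units = 12)
  subs <- accepted_subs(segment_session(ses$traces, ses$targets))
  rm_ <- bin_smooth_sqrt(ses$spikes, ses$session_length_ms)
  segs <- trial_segments(rm_, ses$trials)
  fit <- iterate_ciphase(rm_, subs$peak_time_ms, segments = segs, n_iter = 1)
  ev1 <- ciphase_predict_times(fit$phase, subs)
  ph2 <- fit$phase
  ph2$t_ms <- ph2$t_ms + 12345
  subs2 <- subs
  subs2$peak_time_ms <- subs2$peak_time_ms + 12345
  ev2 <- ciphase_predict_times(ph2, subs2)
  expect_equal(ev1$offset_ms, ev2$offset_ms, tolerance = 1e-9)
})
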