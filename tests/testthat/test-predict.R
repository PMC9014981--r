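test_that("regression recovers an exactly speed-coding unit", {
  set.seed(14)
  n_sub <- 20
  peaks <- seq(500, by = 1000, length.out = n_sub)
  speeds <- stats::runif(n_sub, 400, 1600)
  raw <- matrix(stats::rnorm(3 * 2000, 10, 0.01), nrow = 3)
  for (s in seq_len(n_sub)) {
    cols <- cidyn:::time_to_col(make_rate_matrix(raw), peaks[s]) + (-30:10)
    raw[2, cols] <- speeds[s] / 50
  }
  rm_ <- make_rate_matrix(raw)
  subs <- data.frame(peak_time_ms = peaks, peak_speed = speeds,
                     class = "initial")
  mod <- fit_rate_regression(rm_, subs)
  expect_gt(mod$r_squared, 0.999)
  expect_gt(abs(mod$weights[2]) * stats::sd(raw[2, ]),
            10 * max(abs(mod$weights[c(1, 3)]) * c(stats::sd(raw[1, ]), stats::sd(raw[3, ]))))

  # shuffling the speeds destroys the fit
  set.seed(15)
  r2s <- replicate(20, {
    subs2 <- subs; subs2$peak_speed <- sample(subs2$peak_speed)
    fit_rate_regression(rm_, subs2)$r_squared
  })
  expect_lt(stats::median(r2s), 0.3)
})

test_that("a constructed neural signal yields exact timing offsets", {
  peaks <- seq(2000, by = 1500, length.out = 10)
  n_col <- 1600
  raw <- matrix(1, nrow = 1, ncol = n_col)
  rm_ <- make_rate_matrix(raw)
  for (p in peaks) {
    cc <- cidyn:::time_to_col(rm_, p - 150)
    raw[1, cc + (-5:5)] <- 1 + exp(-(-5:5)^2 / 8)
  }
  rm_ <- make_rate_matrix(raw)
  subs <- data.frame(peak_time_ms = peaks, peak_speed = 1000, class = "initial")
  mod <- structure(list(weights = 1, intercept = 0,
                        window_ms = c(-300, 100)), class = "rate_regression")
  te <- rate_model_predict_times(mod, rm_, subs)
  expect_true(all(te$aligned))
  expect_true(all(abs(te$offset_ms - (-150)) <= 5))
  expect_lt(stats::sd(te$offset_ms), 1e-9)

  # flat signal: no local maxima, everything unaligned
  rm_flat <- make_rate_matrix(matrix(1, 1, n_col))
  te_flat <- rate_model_predict_times(mod, rm_flat, subs)
  expect_true(all(!te_flat$aligned))
})

test_that("a phase ramp crossing zero at -150 ms gives exact predictions", {
  t_ms <- seq(5, by = 10, length.out = 2000)
  peaks <- seq(2000, by = 1500, length.out = 10)
  omega <- 2 * pi / 1500  # one cycle per submovement, rad/ms
  phase <- data.frame(col = seq_along(t_ms), t_ms = t_ms,
                      CIx = 0, CIy = 0, phi_x = 0, phi_y = 0,
                      ci_phi = wrap_angle(omega * (t_ms - (peaks[1] - 150))),
                      segment = 1)
  class(phase) <- c("phase_series", "data.frame")
  subs <- data.frame(peak_time_ms = peaks, peak_speed = 1000, class = "initial")
  te <- ciphase_predict_times(phase, subs)
  expect_true(all(te$aligned))
  expect_true(all(abs(te$offset_ms + 150) < 1e-6))
})

test_that("scrambled phase is a negative control", {
  ses <- small_session(seed = 51, n_trials = 30, n_units = 15)
  subs <- accepted_subs(segment_session(ses$traces, ses$targets))
  rm_ <- bin_smooth_sqrt(ses$spikes, ses$session_length_ms)
  segs <- trial_segments(rm_, ses$trials)
  fit <- iterate_ciphase(rm_, subs$peak_time_ms, segments = segs, n_iter = 1)
  te <- ciphase_predict_times(fit$phase, subs)
  ph2 <- fit$phase
  half <- floor(nrow(ph2) / 2)
  ph2$ci_phi <- c(ph2$ci_phi[(half + 1):nrow(ph2)], ph2$ci_phi[1:half])
  te2 <- ciphase_predict_times(ph2, subs)
  # offsets become dispersed: concentration drops relative to intact phase
  ang <- function(te) 2 * pi * (te$offset_ms[te$aligned] + 300) / 400 - pi
  expect_gt(circ_mean_sd(ang(te))$R, circ_mean_sd(ang(te2))$R)
  expect_gt(rayleigh_test(ang(te2))$p, 1e-4)
})

test_that("variance-ratio test matches the analytic F distribution", {
  # identical evaluations: F = 1, p = 1
  te <- data.frame(peak_time_ms = 1:50, class = "initial",
                   offset_ms = stats::rnorm(50), aligned = TRUE,
                   model = "x")
  class(te) <- c("timing_eval", "data.frame")
  vt <- variance_ratio_test(te, te)
  expect_equal(vt$F, 1)
  expect_equal(vt$p, 1)

  # library oracle on data scaled to exact SDs
  set.seed(33)
  x <- stats::rnorm(1000); x <- (x - mean(x)) / stats::sd(x) * 66.1
  y <- stats::rnorm(1000); y <- (y - mean(y)) / stats::sd(y) * 84.4
  ours <- variance_ratio_test(66.1, 84.4, n1 = 1000, n2 = 1000)
  lib <- stats::var.test(x, y)
  expect_equal(ours$F, unname(lib$statistic), tolerance = 1e-12)
  expect_equal(ours$p, lib$p.value, tolerance = 1e-12)
  expect_equal(ours$conf_int, as.numeric(lib$conf.int), tolerance = 1e-9)
  expect_lt(ours$p, 0.001)
  expect_equal(ours$F, 0.613, tolerance = 1e-3)
})

test_that("speed-phase correlation finds exact and absent dependence", {
  t_ms <- seq(5, by = 10, length.out = 3000)
  phi <- wrap_angle(2 * pi * t_ms / 700)
  phase <- data.frame(col = seq_along(t_ms), t_ms = t_ms, CIx = 0, CIy = 0,
                      phi_x = 0, phi_y = 0, ci_phi = phi, segment = 1)
  res <- speed_phase_correlation(phase, 500 + 400 * cos(phi))
  expect_gt(res$r, 0.999)
  expect_lt(abs(res$phase_max_speed), 2 * pi / 36)
  t_ms <- seq(5, by = 10, length.out = 10000)
  phase0 <- data.frame(col = seq_along(t_ms), t_ms = t_ms, CIx = 0, CIy = 0,
                       phi_x = 0, phi_y = 0,
                       ci_phi = wrap_angle(2 * pi * t_ms / 700), segment = 1)
  set.seed(60)
  res0 <- speed_phase_correlation(phase0, stats::rnorm(10000, 500, 50))
  expect_lt(res0$r, 0.05)
})
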