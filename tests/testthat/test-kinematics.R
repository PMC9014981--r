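make_trace <- function(x, y, step = 10) {
  data.frame(trial_id = 1L, t_ms = seq(0, by = step, length.out = length(x)),
             x_px = x, y_px = y)
}

test_that("speed of a stationary cursor is identically zero", {
  tr <- make_trace(rep(500, 100), rep(500, 100))
  sp <- compute_speed(tr)
  expect_true(all(abs(sp$speed) < 1e-9))
})

test_that("constant-velocity motion recovers the true speed in the interior", {
  v <- 800  # px/s, well below the filter cutoff band
  t <- seq(0, 990, by = 10)
  tr <- make_trace(100 + v * t / 1000, rep(500, length(t)))
  sp <- compute_speed(tr)
  interior <- 30:70
  expect_true(all(abs(sp$speed[interior] - v) / v < 0.01))
})

test_that("a Gaussian bump's peak speed and FWHM are recovered", {
  # a broad bump sits well inside the 10-Hz passband: attenuation < 2%
  tr <- gaussian_bump_trace(peak_speed = 900, fwhm_ms = 300, peak_ms = 1200,
                            t_ms = seq(0, 2400, by = 10))
  sp <- compute_speed(tr)
  pk <- find_speed_peaks(sp)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$peak_speed - 900) / 900, 0.02)
  expect_lt(abs(pk$peak_time_ms - 1200), 10 + 1e-9)

  # narrower bump: compare against the analytic zero-phase Lorentzian
  # response |H|^2 = 1/(1 + (f/fc)^2) applied to the exact Gaussian speed
  tr2 <- gaussian_bump_trace(900, 220, 1000, t_ms = seq(0, 2000, by = 10))
  sp2 <- compute_speed(tr2)
  pk2 <- find_speed_peaks(sp2)
  hm <- half_max_duration(sp2, pk2$idx)
  expect_lt(abs(hm$fwhm_ms - 220), 10 + 1e-9)
  n <- 2^14; dt <- 0.001
  v <- 900 * exp(-(((1:n) - n / 2) * dt)^2 / (2 * (0.220 / 2.3548)^2))
  f <- c(0:(n / 2), -(n / 2 - 1):-1) / (n * dt)
  vf <- Re(stats::fft(stats::fft(v) / (1 + (f / 10)^2), inverse = TRUE)) / n
  expect_lt(abs(pk2$peak_speed - max(vf)) / max(vf), 0.01)
})

test_that("hand-evaluated prominence examples behave as specified", {
  # two equal peaks: troughs scan past the equal neighbour to the boundary
  s1 <- data.frame(t_ms = seq(0, 40, 10), speed = c(0, 300, 0, 300, 0))
  pk1 <- find_speed_peaks(s1)
  expect_equal(nrow(pk1), 2L)
  expect_equal(pk1$prominence, c(300, 300))

  # 1000 then 1100 with a 600 trough: first prominence 400 < 500, rejected
  s2 <- data.frame(t_ms = seq(0, 40, 10), speed = c(0, 1000, 600, 1100, 0))
  pk2 <- find_speed_peaks(s2)
  expect_equal(nrow(pk2), 1L)
  expect_equal(pk2$peak_speed, 1100)
  expect_equal(pk2$prominence, 1100)

  # monotone ramp: no peaks
  s3 <- data.frame(t_ms = seq(0, 90, 10), speed = seq(0, 900, 100))
  expect_equal(nrow(find_speed_peaks(s3)), 0L)
})

test_that("peak detection is invariant to translating the cursor positions", {
  set.seed(21)
  ses <- small_session(n_trials = 5)
  tr <- ses$traces[[1]]
  sp1 <- compute_speed(tr)
  tr2 <- tr
  tr2$x_px <- tr2$x_px + 123.4
  tr2$y_px <- tr2$y_px - 77.1
  sp2 <- compute_speed(tr2)
  p1 <- find_speed_peaks(sp1); p2 <- find_speed_peaks(sp2)
  expect_equal(p1$peak_time_ms, p2$peak_time_ms)
  expect_equal(p1$prominence, p2$prominence, tolerance = 1e-9)
})

test_that("prominence rule matches the brute-force scan oracle", {
  set.seed(42)
  for (i in 1:100) {
    s <- random_speed_trace(250)
    got <- find_speed_peaks(data.frame(t_ms = seq_along(s) * 10, speed = s))
    want <- oracle_peaks(s)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$idx, unname(want[, "idx"]))
      expect_equal(got$prominence, unname(want[, "prom"]), tolerance = 1e-12)
    }
  }
})

test_that("half-max duration follows hand geometry and plateau rules", {
  # symmetric triangle 0 -> 400 -> 0 over 200 ms: FWHM = 100 ms
  up <- seq(0, 400, by = 40)
  tri <- data.frame(t_ms = seq(0, 200, 10), speed = c(up, rev(up)[-1]))
  hm <- half_max_duration(tri, which.max(tri$speed))
  expect_equal(hm$fwhm_ms, 100)

  # plateau at the half-max level: first crossings moving outward
  pl <- data.frame(t_ms = seq(0, 60, 10), speed = c(0, 200, 400, 400, 400, 200, 0))
  hm2 <- half_max_duration(pl, 3L)
  expect_equal(hm2$onset_ms, 10)
  expect_equal(hm2$offset_ms, 50)

  # open-ended when the crossing leaves the trial
  op <- data.frame(t_ms = seq(0, 40, 10), speed = c(300, 350, 400, 300, 250))
  expect_true(half_max_duration(op, 3L)$open_ended)
})

test_that("profile similarity is scale invariant and sign reversing", {
  tr <- gaussian_bump_trace(800, 220, 600, t_ms = seq(0, 1200, 10))
  sp <- compute_speed(tr)
  tr2 <- gaussian_bump_trace(400, 220, 600, t_ms = seq(0, 1200, 10))
  sp2 <- compute_speed(tr2)
  expect_equal(profile_similarity(sp, 600, sp, 600), 1)
  expect_equal(profile_similarity(sp, 600, sp2, 600), 1, tolerance = 1e-6)
  spm <- sp
  spm$speed <- 2 * mean(sp$speed) - sp$speed
  expect_equal(profile_similarity(sp, 600, spm, 600), -1, tolerance = 1e-12)
  flat <- sp; flat$speed <- rep(1, nrow(sp))
  expect_true(is.na(profile_similarity(sp, 600, flat, 600)))
})

test_that("trough-to-peak ratio follows its arithmetic definition", {
  s <- data.frame(t_ms = seq(0, 40, 10), speed = c(0, 1000, 150, 400, 0))
  expect_equal(trough_peak_ratio(s, 2L, 4L), 0.15)
  merged <- data.frame(t_ms = seq(0, 30, 10), speed = c(0, 500, 600, 0))
  expect_true(is.na(trough_peak_ratio(merged, 2L, 3L)))
})

test_that("classification separates initial, corrective and within-target peaks", {
  t_ms <- seq(0, 3000, by = 10)
  # initial reach into a large target at 0 degrees, then a small bump
  # entirely inside the target: rejected within-target
  b1 <- gaussian_bump_trace(1400, 230, 800, 0, t_ms)
  b2 <- gaussian_bump_trace(330, 180, 1900, 0, t_ms, start = c(0, 0))
  tr <- b1
  tr$x_px <- tr$x_px + (b2$x_px)  # second displacement appended along +x
  sp <- compute_speed(tr)
  pk <- find_speed_peaks(sp)
  expect_equal(nrow(pk), 2L)
  cls <- classify_submovements(pk, tr, sp, direction_deg = 0,
                               size_class = "large")
  expect_equal(cls$class, c("initial", "rejected:within-target"))

  # single clean reach: exactly one initial
  sp1 <- compute_speed(b1)
  pk1 <- find_speed_peaks(sp1)
  cls1 <- classify_submovements(pk1, b1, sp1, 0, "large")
  expect_equal(cls1$class, "initial")
})

test_that("segmentation recovers simulator ground truth on noise-free trials", {
  ses <- small_session(seed = 19, n_trials = 30)
  subs <- segment_session(ses$traces, ses$targets)
  m <- match_ground_truth(subs, ses$ground_truth)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$class_agreement, 1)
  expect_lt(m$mean_abs_dt_ms, 10)
})
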