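test_that("skew least squares is exact when the model is exact", {
  set.seed(2)
  for (d in 4:6) {
    M0 <- matrix(rnorm(d * d), d); M0 <- (M0 - t(M0)) / 2
    X <- matrix(rnorm(d * 50), d)
    M <- solve_skew_ls(X, M0 %*% X)
    expect_lt(norm(M - M0, "F") / norm(M0, "F"), 1e-10)
  }
})

test_that("closed-form skew fit matches the numerical optimisation oracle", {
  set.seed(6)
  for (i in 1:10) {
    d <- sample(4:6, 1)
    X <- matrix(rnorm(d * 40), d)
    Xdot <- matrix(rnorm(d * 40), d)
    M1 <- solve_skew_ls(X, Xdot)
    M2 <- oracle_skew(X, Xdot)
    expect_lt(norm(M1 - M2, "F") / norm(M1, "F"), 1e-6)
  }
})

test_that("a planted rotation's plane and frequency are recovered", {
  set.seed(9)
  omega <- 9
  tt <- seq(0, 2, by = 0.01)
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))[, 1:2]
  traj <- Q %*% rbind(cos(omega * tt), sin(omega * tt)) +
    0.01 * matrix(rnorm(6 * length(tt)), 6)
  pl <- fit_jpca(traj, n_pc = 6, dt = 0.01)
  expect_lt(max(principal_angles(Q, pl$basis)) * 180 / pi, 5)
  expect_lt(abs(pl$omega - omega) / omega, 0.02)
  # structural invariants
  expect_equal(crossprod(pl$plane2d), diag(2), tolerance = 1e-10)
  expect_lt(norm(pl$M + t(pl$M), "F"), 1e-10)
  expect_lt(max(abs(Re(pl$eigvals))), 1e-8)
})

test_that("rank-deficient trajectories reduce dimensionality with a warning", {
  set.seed(10)
  base <- matrix(rnorm(3 * 30), 3)
  traj <- rbind(base, base[c(1, 2, 3, 1, 2, 3), ])  # rank 3, 9 units
  expect_warning(pl <- fit_jpca(traj, n_pc = 6), "rank")
  expect_lte(pl$n_pc, 3)
})

test_that("alignment points +CIx at the population-rate peak phase", {
  # 8 units whose rates rotate at 1 Hz with spread phase offsets and
  # asymmetric amplitudes, so the population rate peaks at a known phase
  set.seed(12)
  tt <- seq(0.005, 30, by = 0.01)
  psi <- seq(0, 2 * pi, length.out = 9)[-9]
  amp <- c(4, 3, 2, 1, 0.5, 1, 2, 3)
  raw <- t(sapply(1:8, function(i)
    10 + amp[i] * (1 + cos(2 * pi * tt - psi[i]))))
  rm_ <- make_rate_matrix(raw + 0.05 * matrix(rnorm(length(raw)), 8))
  pl <- fit_jpca(rm_$rates, n_pc = 4, dt = 0.01)
  pl <- align_plane(pl, rm_)
  ph <- project_and_phase(rm_, pl)
  # population rate peaks when cos(2 pi t - chi) is maximal
  chi <- Arg(sum(amp * exp(1i * psi)))
  tmax <- (chi %% (2 * pi)) / (2 * pi)  # first peak time in s
  peaks <- seq(tmax, 29.5, by = 1)     # 1-Hz cycle
  idx <- vapply(peaks * 1000, function(tm) which.min(abs(ph$t_ms - tm)), 0L)
  idx <- idx[idx > 300 & idx < length(tt) - 300]
  mphi <- circ_mean_sd(ph$ci_phi[idx])
  expect_lt(abs(mphi$mean), 2 * pi / 36 + 0.15)

  # gauge invariance: an arbitrary in-plane rotation is undone by alignment
  pl2 <- cidyn:::rotate_plane(pl, 1.1)
  pl2$aligned <- FALSE
  pl2 <- align_plane(pl2, rm_)
  ph2 <- project_and_phase(rm_, pl2)
  expect_lt(max(abs(wrap_angle(ph2$ci_phi - ph$ci_phi))), 0.05)
})

test_that("constant population rate leaves alignment at identity with warning", {
  raw <- matrix(5, nrow = 6, ncol = 200)
  raw <- raw + 0  # exact constant
  rm_ <- make_rate_matrix(raw)
  rm_$rates <- rm_$rates + 0.1 * sin(outer(1:6, 1:200))  # structure for fit
  pl <- suppressWarnings(fit_jpca(rm_$rates, n_pc = 4))
  expect_warning(align_plane(pl, rm_), "alignment undefined")
})

test_that("permuting unit order leaves the CI phase unchanged", {
  ses <- small_session(seed = 23, n_trials = 20, n_units = 12)
  subs <- accepted_subs(segment_session(ses$traces, ses$targets))
  rm_ <- bin_smooth_sqrt(ses$spikes, ses$session_length_ms)
  segs <- trial_segments(rm_, ses$trials)
  fit1 <- iterate_ciphase(rm_, subs$peak_time_ms, segments = segs, n_iter = 1)
  perm <- sample(1:12)
  rm2 <- rm_
  rm2$rates <- rm_$rates[perm, ]
  rm2$rates_raw <- rm_$rates_raw[perm, ]
  rm2$unit_ids <- rm_$unit_ids[perm]
  fit2 <- iterate_ciphase(rm2, subs$peak_time_ms, segments = segs, n_iter = 1)
  expect_lt(max(abs(wrap_angle(fit1$phase$ci_phi - fit2$phase$ci_phi)),
                na.rm = TRUE), 1e-6)
})
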