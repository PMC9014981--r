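# CI phase: Hilbert-transform instantaneous phase of the plane projections,
# iterative phase-averaged refinement of the plane, and trial-wise
# cross-validation.

#' Analytic signal via the Hilbert transform
#'
#' FFT construction of the analytic signal z(t) = x(t) + i H\{x\}(t): the
#' negative-frequency half of the spectrum is zeroed and the positive half
#' doubled. The instantaneous phase is \code{Arg(z)}.
#'
#' @param x real numeric vector.
#' @return complex vector, same length.
#' @export
hilbert_analytic <- function(x) {
  n <- length(x)
  if (n < 2L) return(complex(real = x, imaginary = 0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Project rates into the CI plane and compute the CI phase
#'
#' CIx and CIy are the plane projections of the (centered, square-root
#' transformed) population rates, mean-subtracted per contiguous segment.
#' Each segment's analytic signal gives instantaneous phases phi_x and
#' phi_y; the CI phase is the circular mean of phi_x and phi_y + pi/2
#' (CIy lags CIx by a quarter cycle under the alignment convention).
#' Segments shorter than \code{min_len} samples get missing phase.
#'
#' @param rm the session \code{rate_matrix}.
#' @param plane an aligned \code{ci_plane}.
#' @param segments list of contiguous column ranges; NULL = whole session.
#' @param min_len minimum segment length (samples) for a defined phase.
#' @return a \code{phase_series} data frame: \code{col} (rate-matrix
#'   column), \code{t_ms}, \code{CIx}, \code{CIy}, \code{phi_x},
#'   \code{phi_y}, \code{ci_phi}, \code{segment}.
#' @export
project_and_phase <- function(rm, plane, segments = NULL, min_len = 10L) {
  if (is.null(segments)) segments <- list(seq_along(rm$bin_times))
  out <- vector("list", length(segments))
  for (si in seq_along(segments)) {
    s <- segments[[si]]
    if (length(s) == 0L) next
    P <- project_plane(plane, rm, s)
    cix <- P[1, ] - mean(P[1, ])
    ciy <- P[2, ] - mean(P[2, ])
    if (length(s) < min_len) {
      phx <- phy <- cph <- rep(NA_real_, length(s))
    } else {
      phx <- Arg(hilbert_analytic(cix))
      phy <- Arg(hilbert_analytic(ciy))
      cph <- circ_mean2(phx, phy + pi / 2)
    }
    out[[si]] <- data.frame(col = s, t_ms = rm$bin_times[s], CIx = cix,
                            CIy = ciy, phi_x = phx, phi_y = phy,
                            ci_phi = cph, segment = si)
  }
  res <- do.call(rbind, out)
  class(res) <- c("phase_series", class(res))
  res
}

# vectorised circular mean of two angle vectors
circ_mean2 <- function(a, b) {
  atan2(sin(a) + sin(b), cos(a) + cos(b))
}

#' Iterative CI-phase estimation
#'
#' Iteration 1 averages unit rates aligned on the supplied events
#' (speed peaks) and fits the rotational plane on that average. Subsequent
#' iterations re-average the unit rates within CI-phase bins (a
#' phase-averaged trajectory, units x \code{n_phase_bins}, treated as one
#' closed cycle) and refit, alternating until \code{n_iter} fits have been
#' done. The plane is re-aligned to the population rate each iteration, so
#' the phase convention is stable. The principal angle between successive
#' planes is logged; if it increases the last iterate is returned with a
#' warning.
#'
#' @param rm session \code{rate_matrix}.
#' @param events_ms speed-peak times, session ms.
#' @param segments contiguous column ranges (e.g. [trial_segments()]).
#' @param n_iter number of jPCA fits, default 3 (1 = event-aligned only).
#' @param n_phase_bins bins for phase averaging, default 36.
#' @param n_angle_bins bins for the alignment rule, default 36.
#' @param window_ms event-aligned averaging window, default c(-500, 300).
#' @param n_pc principal components, default 6.
#' @return list with \code{plane} (final aligned \code{ci_plane}),
#'   \code{phase} (full \code{phase_series} over \code{segments}),
#'   \code{iterations} (data frame: iteration, principal angle to previous
#'   plane in degrees), \code{n_iter}.
#' @export
iterate_ciphase <- function(rm, events_ms, segments = NULL, n_iter = 3,
                            n_phase_bins = 36, n_angle_bins = 36,
                            window_ms = c(-500, 300), n_pc = 6) {
  stopifnot(n_iter >= 1)
  traj <- ci_average_by_event(rm, events_ms, window_ms, segments)
  plane <- fit_jpca(traj, n_pc = n_pc, dt = rm$bin_ms / 1000)
  plane <- align_plane(plane, rm, segments, n_angle_bins)
  phase <- project_and_phase(rm, plane, segments)
  log <- data.frame(iteration = 1L, principal_angle_deg = NA_real_)

  if (n_iter > 1L) for (it in 2:n_iter) {
    traj_p <- phase_binned_average(rm, phase, n_phase_bins)
    new_plane <- fit_jpca(traj_p, n_pc = n_pc, dt = 1, periodic = TRUE)
    new_plane <- align_plane(new_plane, rm, segments, n_angle_bins)
    pa <- max(principal_angles(plane$basis, new_plane$basis)) * 180 / pi
    log <- rbind(log, data.frame(iteration = it, principal_angle_deg = pa))
    if (it > 2L && pa > log$principal_angle_deg[it - 1L] + 1e-9)
      warning("plane principal angle increased between iterations ",
              it - 1L, " and ", it, " (", signif(pa, 3), " deg)")
    plane <- new_plane
    phase <- project_and_phase(rm, plane, segments)
  }
  list(plane = plane, phase = phase, iterations = log, n_iter = n_iter)
}

# Occupancy-weighted mean sqrt-rate per CI-phase bin; empty bins filled by
# circular interpolation. Columns ordered by bin center from -pi to pi.
phase_binned_average <- function(rm, phase, n_phase_bins) {
  ok <- !is.na(phase$ci_phi)
  bin <- pmin(floor((phase$ci_phi[ok] + pi) / (2 * pi / n_phase_bins)) + 1L,
              n_phase_bins)
  cols <- phase$col[ok]
  traj <- matrix(NA_real_, nrow = nrow(rm$rates), ncol = n_phase_bins)
  for (b in unique(bin)) {
    traj[, b] <- rowMeans(rm$rates[, cols[bin == b], drop = FALSE])
  }
  t(apply(traj, 1L, interp_circular_gaps))
}

#' Cross-validated CI phase
#'
#' Trials are partitioned into \code{k} seeded folds. For each fold the
#' plane is fitted with [iterate_ciphase()] on the other k-1 folds' trials
#' and events, and the held-out trials are projected into that plane. The
#' pooled held-out phase series is returned.
#'
#' @param rm session \code{rate_matrix}.
#' @param events_ms speed-peak times (session ms), used for the
#'   event-aligned initial iteration.
#' @param trials data frame with \code{trial_id}, \code{start_ms},
#'   \code{end_ms}.
#' @param k number of folds, default 5 (must be >= 2 and <= n_trials).
#' @param seed integer seed for the fold assignment.
#' @param ... passed to [iterate_ciphase()].
#' @return list with \code{phase} (pooled test \code{phase_series} with a
#'   \code{fold} column), \code{planes} (per-fold), \code{folds} (trial
#'   fold assignment), \code{train} (per-fold iteration logs).
#' @export
crossval_ciphase <- function(rm, events_ms, trials, k = 5, seed = 1L, ...) {
  n_trials <- nrow(trials)
  if (k < 2L) stop("k must be at least 2")
  if (k > n_trials) stop("k exceeds the number of trials")
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n_trials))
  segs <- trial_segments(rm, trials)
  ev_trial <- findInterval(events_ms, trials$start_ms)
  phases <- vector("list", k)
  planes <- vector("list", k)
  logs <- vector("list", k)
  for (f in seq_len(k)) {
    tr_idx <- which(fold != f)
    te_idx <- which(fold == f)
    fit <- iterate_ciphase(rm, events_ms[ev_trial %in% tr_idx],
                           segments = segs[tr_idx], ...)
    ph <- project_and_phase(rm, fit$plane, segments = segs[te_idx])
    ph$segment <- te_idx[ph$segment]
    ph$fold <- f
    phases[[f]] <- ph
    planes[[f]] <- fit$plane
    logs[[f]] <- fit$iterations
  }
  pooled <- do.call(rbind, phases)
  pooled <- pooled[order(pooled$col), ]
  rownames(pooled) <- NULL
  class(pooled) <- c("phase_series", "data.frame")
  list(phase = pooled, planes = planes,
       folds = data.frame(trial_id = trials$trial_id, fold = fold),
       train = logs)
}
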