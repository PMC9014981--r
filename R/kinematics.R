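# Submovement kinematics: filtered cursor speed, speed-peak detection with a
# prominence rule, initial/corrective classification against the target
# geometry, and per-submovement shape statistics.

#' Cursor speed from a 100-Hz position trace
#'
#' Positions are low-pass filtered with a first-order Butterworth filter
#' (default cutoff 10 Hz) applied forward and backward for zero phase lag,
#' then differentiated with the five-point central difference
#' (coefficients (1, -8, 0, 8, -1)/12 per sample, scaled by the sample
#' rate). Edges are handled by reflect-padding before filtering and
#' differentiating, so the returned series has the same length as the input.
#'
#' @param trace a \code{cursor_trace} data frame with columns \code{t_ms},
#'   \code{x_px}, \code{y_px}, uniformly sampled.
#' @param cutoff_hz low-pass cutoff in Hz.
#' @param sample_rate sampling rate in Hz (checked against \code{t_ms}).
#' @return data frame with columns \code{t_ms}, \code{speed} (px/s),
#'   \code{vx}, \code{vy}, plus unfiltered \code{speed_raw} for display.
#' @export
compute_speed <- function(trace, cutoff_hz = 10, sample_rate = 100) {
  t <- trace$t_ms
  n <- length(t)
  if (n < 5L) stop("need at least 5 samples to differentiate")
  dt <- diff(t)
  step <- 1000 / sample_rate
  if (any(abs(dt - step) > 1e-6)) stop("non-uniform sampling in cursor trace")

  xf <- filtfilt_reflect(trace$x_px, cutoff_hz, sample_rate)
  yf <- filtfilt_reflect(trace$y_px, cutoff_hz, sample_rate)
  vx <- central_diff5(xf) * sample_rate
  vy <- central_diff5(yf) * sample_rate
  vxr <- central_diff5(trace$x_px) * sample_rate
  vyr <- central_diff5(trace$y_px) * sample_rate
  data.frame(
    t_ms = t,
    speed = sqrt(vx^2 + vy^2),
    vx = vx, vy = vy,
    speed_raw = sqrt(vxr^2 + vyr^2)
  )
}

# Zero-phase first-order Butterworth with reflect padding. signal::filtfilt
# zero-pads, which distorts trials that do not start/end at rest, so padding
# is done here: the series is mirrored about each endpoint value.
filtfilt_reflect <- function(x, cutoff_hz, sample_rate, n_pad = NULL) {
  n <- length(x)
  if (is.null(n_pad)) n_pad <- min(n - 1L, as.integer(sample_rate))
  bf <- signal::butter(1, cutoff_hz / (sample_rate / 2), type = "low")
  head_pad <- 2 * x[1] - x[(n_pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - n_pad)]
  xp <- c(head_pad, x, tail_pad)
  fwd <- signal::filter(bf, xp)
  bwd <- rev(signal::filter(bf, rev(fwd)))
  bwd[(n_pad + 1):(n_pad + n)]
}

# Five-point central difference per unit sample step, reflect-padded by two
# samples so the output matches the input length.
central_diff5 <- function(x) {
  n <- length(x)
  xp <- c(2 * x[1] - x[3:2], x, 2 * x[n] - x[(n - 1):(n - 2)])
  i <- 3:(n + 2)
  (xp[i - 2] - 8 * xp[i - 1] + 8 * xp[i + 1] - xp[i + 2]) / 12
}

#' Candidate speed peaks with height and prominence criteria
#'
#' Local maxima of the speed series are accepted as submovement candidates
#' when (1) the peak speed exceeds \code{min_height} and (2) the peak's
#' prominence is at least \code{prom_frac} of its absolute height.
#' Prominence is the height of the peak above the larger of its two
#' adjacent troughs, where each trough is the minimum speed between the
#' peak and the nearest strictly larger sample on that side (or the series
#' boundary). Ties in height across a plateau are broken toward the
#' earlier sample.
#'
#' @param speed data frame from [compute_speed()] (columns \code{t_ms},
#'   \code{speed}), or a numeric speed vector with \code{t_ms} supplied.
#' @param min_height detection threshold in px/s.
#' @param prom_frac required prominence as a fraction of peak height.
#' @param window_ms half-width of the submovement window around each peak.
#' @return data frame, one row per accepted peak: \code{idx},
#'   \code{peak_time_ms}, \code{peak_speed}, \code{prominence},
#'   \code{win_start_ms}, \code{win_end_ms}. Zero rows if none qualify.
#' @export
find_speed_peaks <- function(speed, min_height = 250, prom_frac = 0.5,
                             window_ms = 200) {
  if (is.data.frame(speed)) {
    s <- speed$speed; t <- speed$t_ms
  } else {
    s <- as.numeric(speed); t <- seq_along(s)
  }
  n <- length(s)
  cand <- local_maxima(s)
  if (length(cand) == 0L) return(empty_peaks())
  keep <- logical(length(cand))
  prom <- numeric(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    h <- s[i]
    # nearest strictly larger sample on each side bounds the trough search
    left_stop <- which(s[seq_len(i - 1L)] > h)
    lo <- if (length(left_stop)) max(left_stop) + 1L else 1L
    right_stop <- which(s[(i + 1L):n] > h)
    hi <- if (i < n && length(right_stop)) i + min(right_stop) - 1L else n
    ltr <- if (lo <= i - 1L) min(s[lo:(i - 1L)]) else s[i]
    rtr <- if (hi >= i + 1L) min(s[(i + 1L):hi]) else s[i]
    prom[k] <- h - max(ltr, rtr)
    keep[k] <- (h > min_height) && (prom[k] >= prom_frac * h)
  }
  out <- data.frame(
    idx = cand[keep],
    peak_time_ms = t[cand[keep]],
    peak_speed = s[cand[keep]],
    prominence = prom[keep]
  )
  out$win_start_ms <- out$peak_time_ms - window_ms
  out$win_end_ms <- out$peak_time_ms + window_ms
  out
}

empty_peaks <- function() {
  data.frame(idx = integer(), peak_time_ms = numeric(), peak_speed = numeric(),
             prominence = numeric(), win_start_ms = numeric(),
             win_end_ms = numeric())
}

# Indices of strict local maxima; plateaus contribute their first sample.
local_maxima <- function(s) {
  n <- length(s)
  if (n < 3L) return(integer())
  idx <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (s[i] > s[i - 1L]) {
      j <- i
      while (j < n && s[j + 1L] == s[i]) j <- j + 1L
      if (j < n && s[j + 1L] < s[i]) idx <- c(idx, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  idx
}

#' Target region membership for the precision center-out task
#'
#' Targets are annular sectors in polar coordinates around the workspace
#' center: large targets span 45 degrees covering 250-450 px from the
#' center, shallow targets span 45 degrees covering 325-375 px, and narrow
#' targets span 15 degrees covering 250-450 px.
#'
#' @param x,y cursor position(s) in px.
#' @param direction_deg target direction in degrees.
#' @param size_class one of "large", "shallow", "narrow".
#' @param center workspace center, default c(500, 500).
#' @return logical vector, TRUE where the point lies inside the target.
#' @export
in_target <- function(x, y, direction_deg, size_class,
                      center = c(500, 500)) {
  geom <- target_geometry(size_class)
  dx <- x - center[1]; dy <- y - center[2]
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)
  dang <- abs(angle_diff(ang, direction_deg * pi / 180))
  r >= geom$r_in & r <= geom$r_out & dang <= geom$half_span
}

target_geometry <- function(size_class) {
  switch(as.character(size_class),
    large   = list(r_in = 250, r_out = 450, half_span = 22.5 * pi / 180),
    shallow = list(r_in = 325, r_out = 375, half_span = 22.5 * pi / 180),
    narrow  = list(r_in = 250, r_out = 450, half_span = 7.5 * pi / 180),
    stop("unknown size class: ", size_class)
  )
}

#' Half-maximum onset/offset and duration of a submovement
#'
#' Finds the nearest time points on either side of the peak at which speed
#' crosses one-half of the peak speed, by linear interpolation between
#' samples. On a plateau the first crossing encountered moving away from
#' the peak is used.
#'
#' @param speed data frame from [compute_speed()].
#' @param peak_idx sample index of the peak.
#' @return list with \code{onset_ms}, \code{offset_ms}, \code{fwhm_ms} and
#'   logical \code{open_ended} (TRUE if a crossing was not found within the
#'   trial on one side; the trial boundary is then used).
#' @export
half_max_duration <- function(speed, peak_idx) {
  s <- speed$speed; t <- speed$t_ms
  n <- length(s)
  half <- s[peak_idx] / 2
  open <- FALSE
  onset <- t[1]; offset <- t[n]
  i <- peak_idx
  while (i > 1L && s[i - 1L] >= half) i <- i - 1L
  if (i == 1L) open <- TRUE else {
    frac <- (s[i] - half) / (s[i] - s[i - 1L])
    onset <- t[i] - frac * (t[i] - t[i - 1L])
  }
  j <- peak_idx
  while (j < n && s[j + 1L] >= half) j <- j + 1L
  if (j == n) open <- TRUE else {
    frac <- (s[j] - half) / (s[j] - s[j + 1L])
    offset <- t[j] + frac * (t[j + 1L] - t[j])
  }
  list(onset_ms = onset, offset_ms = offset, fwhm_ms = offset - onset,
       open_ended = open)
}

#' Classify detected speed peaks as initial or corrective submovements
#'
#' The initial submovement is the first accepted peak whose movement end
#' (cursor position at the half-max offset) lies at least
#' \code{initial_dist_px} from the workspace center; accepted peaks before
#' it are rejected as "pre-initial". Later peaks are corrective
#' submovements if any sample of the acceleration phase (from the speed
#' trough preceding the peak up to the peak) lies outside the trial's
#' target region; otherwise they are rejected as "within-target".
#'
#' @param peaks data frame from [find_speed_peaks()].
#' @param trace the trial's \code{cursor_trace}.
#' @param speed data frame from [compute_speed()] for the same trial.
#' @param direction_deg,size_class trial target geometry.
#' @param initial_dist_px minimum movement-end distance from the center for
#'   the initial submovement.
#' @param center workspace center.
#' @return data frame, one row per accepted peak (including rejected ones),
#'   with columns \code{class} ("initial", "corrective", or
#'   "rejected:<reason>"), \code{peak_time_ms}, \code{peak_speed},
#'   \code{prominence}, \code{onset_ms}, \code{offset_ms}, \code{fwhm_ms}.
#'   Zero rows (with a "no-initial" attribute) if no peak qualifies as
#'   initial.
#' @export
classify_submovements <- function(peaks, trace, speed, direction_deg,
                                  size_class, initial_dist_px = 150,
                                  center = c(500, 500)) {
  if (nrow(peaks) == 0L) return(empty_submovements())
  hm <- lapply(peaks$idx, function(i) half_max_duration(speed, i))
  end_x <- stats::approx(trace$t_ms, trace$x_px,
                         xout = vapply(hm, `[[`, 0, "offset_ms"))$y
  end_y <- stats::approx(trace$t_ms, trace$y_px,
                         xout = vapply(hm, `[[`, 0, "offset_ms"))$y
  end_dist <- sqrt((end_x - center[1])^2 + (end_y - center[2])^2)

  cls <- rep(NA_character_, nrow(peaks))
  init_k <- which(end_dist >= initial_dist_px)[1]
  if (is.na(init_k)) {
    out <- empty_submovements()
    attr(out, "no_initial") <- TRUE
    return(out)
  }
  if (init_k > 1L) cls[seq_len(init_k - 1L)] <- "rejected:pre-initial"
  cls[init_k] <- "initial"
  if (init_k < nrow(peaks)) {
    for (k in (init_k + 1L):nrow(peaks)) {
      trough <- which.min(speed$speed[peaks$idx[k - 1L]:peaks$idx[k]]) +
        peaks$idx[k - 1L] - 1L
      seg <- trough:peaks$idx[k]
      outside <- !in_target(trace$x_px[seg], trace$y_px[seg],
                            direction_deg, size_class, center)
      cls[k] <- if (any(outside)) "corrective" else "rejected:within-target"
    }
  }
  data.frame(
    class = cls,
    peak_time_ms = peaks$peak_time_ms,
    peak_speed = peaks$peak_speed,
    prominence = peaks$prominence,
    onset_ms = vapply(hm, `[[`, 0, "onset_ms"),
    offset_ms = vapply(hm, `[[`, 0, "offset_ms"),
    fwhm_ms = vapply(hm, `[[`, 0, "fwhm_ms")
  )
}

empty_submovements <- function() {
  data.frame(class = character(), peak_time_ms = numeric(),
             peak_speed = numeric(), prominence = numeric(),
             onset_ms = numeric(), offset_ms = numeric(), fwhm_ms = numeric())
}

#' Pearson similarity between two submovement speed profiles
#'
#' Both profiles are the speed samples from -window_ms to +window_ms around
#' their respective peaks (41 samples at 100 Hz with the default window).
#'
#' @param speedA,speedB speed data frames for the two trials.
#' @param peak_ms_A,peak_ms_B peak times in ms.
#' @param window_ms half window, default 200.
#' @return Pearson correlation in [-1, 1], or NA if either profile has zero
#'   variance or the window leaves the trial.
#' @export
profile_similarity <- function(speedA, peak_ms_A, speedB, peak_ms_B,
                               window_ms = 200) {
  pa <- profile_window(speedA, peak_ms_A, window_ms)
  pb <- profile_window(speedB, peak_ms_B, window_ms)
  if (is.null(pa) || is.null(pb)) return(NA_real_)
  if (stats::sd(pa) < 1e-12 || stats::sd(pb) < 1e-12) return(NA_real_)
  stats::cor(pa, pb)
}

profile_window <- function(speed, peak_ms, window_ms) {
  step <- speed$t_ms[2] - speed$t_ms[1]
  lags <- seq(-window_ms, window_ms, by = step)
  out <- stats::approx(speed$t_ms, speed$speed, xout = peak_ms + lags)$y
  if (anyNA(out)) NULL else out
}

#' Trough-to-peak speed ratio between consecutive submovements
#'
#' @param speed speed data frame for the trial.
#' @param peak_idx_1,peak_idx_2 sample indices of the two consecutive peaks.
#' @return minimum speed between the peaks divided by the first peak's
#'   speed, or NA if the bumps merged with no interior minimum.
#' @export
trough_peak_ratio <- function(speed, peak_idx_1, peak_idx_2) {
  stopifnot(peak_idx_2 > peak_idx_1)
  if (peak_idx_2 - peak_idx_1 < 2L) return(NA_real_)
  seg <- speed$speed[(peak_idx_1 + 1L):(peak_idx_2 - 1L)]
  if (min(seg) >= min(speed$speed[peak_idx_1], speed$speed[peak_idx_2]))
    return(NA_real_)
  min(seg) / speed$speed[peak_idx_1]
}

#' Segment every trial of a session into submovements
#'
#' Convenience driver: computes filtered speed, detects peaks, and
#' classifies them per trial.
#'
#' @param traces list of \code{cursor_trace} data frames (one per trial),
#'   each carrying \code{direction_deg} and \code{size_class} attributes or
#'   columns.
#' @param targets data frame with \code{trial_id}, \code{direction_deg},
#'   \code{size_class}.
#' @param min_height,prom_frac,initial_dist_px,cutoff_hz detection
#'   parameters, see the individual functions.
#' @return data frame of submovements across trials with a \code{trial_id}
#'   column; rejected peaks are retained with their reason in \code{class}.
#' @export
segment_session <- function(traces, targets, min_height = 250,
                            prom_frac = 0.5, initial_dist_px = 150,
                            cutoff_hz = 10) {
  res <- lapply(traces, function(tr) {
    tid <- tr$trial_id[1]
    tg <- targets[targets$trial_id == tid, ]
    sp <- compute_speed(tr, cutoff_hz = cutoff_hz)
    pk <- find_speed_peaks(sp, min_height = min_height, prom_frac = prom_frac)
    sm <- classify_submovements(pk, tr, sp, tg$direction_deg[1],
                                tg$size_class[1],
                                initial_dist_px = initial_dist_px)
    if (nrow(sm) > 0L) cbind(trial_id = tid, sm) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- cbind(trial_id = integer(), empty_submovements())
  rownames(out) <- NULL
  out
}
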