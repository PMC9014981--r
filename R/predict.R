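# Timing prediction: CI-phase zero crossings versus a single-dimension
# firing-rate regression baseline, and the statistical comparison between
# them (variance-ratio F test, circular-linear speed/phase correlation).

#' Fit the firing-rate regression comparator
#'
#' Ordinary least squares of submovement peak speed on each unit's raw
#' smoothed firing rate averaged over a window around the peak (default
#' -300 to +100 ms), with no per-unit lags. The weight vector defines a
#' single neural dimension whose instantaneous value predicts speed.
#'
#' @param rm session \code{rate_matrix}.
#' @param submovements data frame with \code{peak_time_ms} and
#'   \code{peak_speed} (accepted submovements only).
#' @param window_ms averaging window relative to peak speed.
#' @param segments optional contiguous column ranges; windows are clipped
#'   to the segment containing the peak.
#' @return a \code{rate_regression} list: \code{weights} (per unit),
#'   \code{intercept}, \code{window_ms}, \code{r_squared}.
#' @export
fit_rate_regression <- function(rm, submovements, window_ms = c(-300, 100),
                                segments = NULL) {
  if (nrow(submovements) < 2L) stop("need at least 2 submovements")
  X <- window_mean_rates(rm, submovements$peak_time_ms, window_ms, segments)
  y <- submovements$peak_speed
  fit <- stats::lm.fit(cbind(1, X), y)
  coefs <- fit$coefficients
  if (any(is.na(coefs))) {
    warning("rate regression design is rank deficient; ",
            "aliased units get zero weight")
    coefs[is.na(coefs)] <- 0
  }
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  structure(list(weights = coefs[-1], intercept = coefs[1],
                 window_ms = window_ms, r_squared = r2),
            class = "rate_regression")
}

window_mean_rates <- function(rm, peak_times_ms, window_ms, segments) {
  if (is.null(segments)) segments <- list(seq_along(rm$bin_times))
  seg_first <- vapply(segments, function(s) if (length(s)) s[1] else NA_integer_, 0L)
  seg_last <- vapply(segments, function(s) if (length(s)) s[length(s)] else NA_integer_, 0L)
  lag_lo <- round(window_ms[1] / rm$bin_ms)
  lag_hi <- round(window_ms[2] / rm$bin_ms)
  t(vapply(peak_times_ms, function(ev) {
    cc <- time_to_col(rm, ev)
    seg <- which(seg_first <= cc & seg_last >= cc)[1]
    lo <- cc + lag_lo; hi <- cc + lag_hi
    if (!is.na(seg)) {
      lo <- max(lo, seg_first[seg]); hi <- min(hi, seg_last[seg])
    }
    rowMeans(rm$rates_raw[, lo:hi, drop = FALSE])
  }, numeric(nrow(rm$rates_raw))))
}

#' Predicted submovement times from the rate-regression signal
#'
#' The weighted sum of instantaneous (raw smoothed) unit rates forms a 1-D
#' neural signal. For each submovement the predicted time is the local peak
#' of this signal within the evaluation window around the speed peak
#' (several peaks: the latest one before the speed peak, else the earliest
#' after - mirroring the CI-phase rule); no local peak means the
#' submovement is unaligned.
#'
#' @param model a \code{rate_regression}.
#' @param rm session \code{rate_matrix}.
#' @param submovements accepted submovements (needs \code{peak_time_ms},
#'   \code{class}).
#' @param eval_window_ms window for an aligned prediction, default
#'   c(-300, 100) ms.
#' @param segments optional contiguous column ranges (peaks of the signal
#'   are only sought within the segment holding the speed peak).
#' @return a \code{timing_eval} data frame: \code{peak_time_ms},
#'   \code{class}, \code{offset_ms} (NA when unaligned), \code{aligned},
#'   \code{model}.
#' @export
rate_model_predict_times <- function(model, rm, submovements,
                                     eval_window_ms = c(-300, 100),
                                     segments = NULL) {
  sig <- as.numeric(crossprod(model$weights, rm$rates_raw)) + model$intercept
  if (is.null(segments)) segments <- list(seq_along(rm$bin_times))
  cand_t <- unlist(lapply(segments, function(s) {
    if (length(s) < 3L) return(numeric())
    rm$bin_times[s[local_maxima(sig[s])]]
  }))
  offsets <- pick_offsets(cand_t, submovements$peak_time_ms, eval_window_ms)
  timing_eval(submovements, offsets, "rate")
}

#' Predicted submovement times from CI-phase zero crossings
#'
#' The predicted time for each submovement is the upward (wrap-aware)
#' zero crossing of the CI phase within the evaluation window around the
#' speed peak; several crossings resolve to the latest before the peak,
#' else the earliest after. Crossing times are interpolated between
#' samples.
#'
#' @param phase a \code{phase_series}.
#' @param submovements accepted submovements.
#' @param eval_window_ms evaluation window, default c(-300, 100) ms.
#' @return a \code{timing_eval} data frame (see
#'   [rate_model_predict_times()]), \code{model = "ciphase"}.
#' @export
ciphase_predict_times <- function(phase, submovements,
                                  eval_window_ms = c(-300, 100)) {
  cand_t <- phase_zero_crossings(phase)
  offsets <- pick_offsets(cand_t, submovements$peak_time_ms, eval_window_ms)
  timing_eval(submovements, offsets, "ciphase")
}

# Interpolated times of upward ci_phi = 0 crossings, per contiguous segment.
phase_zero_crossings <- function(phase) {
  out <- numeric(0)
  for (si in unique(phase$segment)) {
    d <- phase[phase$segment == si, ]
    ph <- d$ci_phi
    if (all(is.na(ph))) next
    n <- nrow(d)
    u <- wrap_angle(ph[-n])
    dphi <- wrap_angle(ph[-1] - ph[-n])
    s_frac <- ((-u) %% (2 * pi)) / dphi
    hit <- which(!is.na(s_frac) & dphi > 0 & s_frac >= 0 & s_frac <= 1)
    if (length(hit))
      out <- c(out, d$t_ms[hit] + s_frac[hit] * (d$t_ms[hit + 1] - d$t_ms[hit]))
  }
  sort(out)
}

# For each event, pick a candidate time within the window: latest candidate
# before the event, else earliest after. NA if none.
pick_offsets <- function(cand_t, event_t, window_ms) {
  vapply(event_t, function(ev) {
    off <- cand_t - ev
    off <- off[off >= window_ms[1] & off <= window_ms[2]]
    if (length(off) == 0L) return(NA_real_)
    before <- off[off <= 0]
    if (length(before)) max(before) else min(off)
  }, numeric(1))
}

timing_eval <- function(submovements, offsets, model) {
  out <- data.frame(
    peak_time_ms = submovements$peak_time_ms,
    class = submovements$class,
    offset_ms = offsets,
    aligned = !is.na(offsets),
    model = model
  )
  class(out) <- c("timing_eval", "data.frame")
  out
}

#' Summarise a timing evaluation
#'
#' @param eval a \code{timing_eval}.
#' @return data frame per class (plus "all"): \code{n},
#'   \code{aligned_frac}, \code{mean_offset_ms}, \code{sd_offset_ms}
#'   (over aligned submovements).
#' @export
timing_summary <- function(eval) {
  one <- function(d, label) {
    al <- d$offset_ms[d$aligned]
    data.frame(class = label, n = nrow(d),
               aligned_frac = mean(d$aligned),
               mean_offset_ms = if (length(al)) mean(al) else NA_real_,
               sd_offset_ms = if (length(al) > 1) stats::sd(al) else NA_real_)
  }
  rbind(one(eval, "all"),
        do.call(rbind, lapply(split(eval, eval$class),
                              function(d) one(d, d$class[1]))))
}

#' Variance-ratio (F) test between two timing models
#'
#' Tests whether the SD of model A's aligned prediction offsets differs
#' from model B's, assuming approximate normality:
#' F = sd_A^2 / sd_B^2 with (n_A - 1, n_B - 1) degrees of freedom,
#' two-sided p, and a 95 percent confidence interval on the variance ratio.
#'
#' Can be called either with two \code{timing_eval} objects (optionally
#' restricted to one class) or directly with summary statistics.
#'
#' @param a,b \code{timing_eval} data frames, or for the direct form
#'   \code{a = sd1}, \code{b = sd2} with \code{n1}, \code{n2} supplied.
#' @param class optional submovement class filter ("initial",
#'   "corrective").
#' @param n1,n2 sample sizes for the direct form.
#' @param conf confidence level, default 0.95.
#' @return list with \code{sd1}, \code{sd2}, \code{F}, \code{df},
#'   \code{p}, \code{conf_int}, \code{n}.
#' @export
variance_ratio_test <- function(a, b, class = NULL, n1 = NULL, n2 = NULL,
                                conf = 0.95) {
  if (inherits(a, "timing_eval")) {
    if (!is.null(class)) {
      a <- a[a$class == class, ]
      b <- b[b$class == class, ]
    }
    x1 <- a$offset_ms[a$aligned]; x2 <- b$offset_ms[b$aligned]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 3L || n2 < 3L) stop("need at least 3 aligned offsets per model")
    sd1 <- stats::sd(x1); sd2 <- stats::sd(x2)
  } else {
    sd1 <- a; sd2 <- b
    if (is.null(n1) || is.null(n2)) stop("supply n1 and n2 with raw SDs")
    if (n1 < 3L || n2 < 3L) stop("need n >= 3 in each group")
  }
  df <- c(n1 - 1, n2 - 1)
  F <- sd1^2 / sd2^2
  p <- 2 * min(stats::pf(F, df[1], df[2]),
               stats::pf(F, df[1], df[2], lower.tail = FALSE))
  p <- min(p, 1)
  alpha <- 1 - conf
  ci <- c(F / stats::qf(1 - alpha / 2, df[1], df[2]),
          F / stats::qf(alpha / 2, df[1], df[2]))
  list(sd1 = sd1, sd2 = sd2, F = F, df = df, p = p, conf_int = ci,
       n = c(n1, n2))
}

#' Circular-linear correlation between CI phase and cursor speed
#'
#' Pairs each phase sample with the cursor speed at the same time bin and
#' computes the circular-linear correlation (see [circ_corr_cl()]),
#' together with the phase at which the binned mean speed is largest.
#'
#' @param phase a \code{phase_series}.
#' @param speed_at_bins numeric vector of cursor speed per rate-matrix
#'   column (NA outside trials), e.g. from [session_speed_bins()].
#' @param n_bins phase bins for the max-speed phase, default 36.
#' @return list with \code{r}, \code{p}, \code{n},
#'   \code{phase_max_speed} (rad) and \code{mean_speed_by_phase}
#'   (data frame phase, speed).
#' @export
speed_phase_correlation <- function(phase, speed_at_bins, n_bins = 36) {
  sp <- speed_at_bins[phase$col]
  ok <- !is.na(phase$ci_phi) & !is.na(sp)
  cc <- circ_corr_cl(phase$ci_phi[ok], sp[ok])
  bin <- pmin(floor((phase$ci_phi[ok] + pi) / (2 * pi / n_bins)) + 1L, n_bins)
  ms <- rep(NA_real_, n_bins)
  agg <- tapply(sp[ok], bin, mean)
  ms[as.integer(names(agg))] <- agg
  centers <- -pi + (seq_len(n_bins) - 0.5) * (2 * pi / n_bins)
  c(cc, list(phase_max_speed = centers[which.max(ms)],
             mean_speed_by_phase = data.frame(phase = centers, speed = ms)))
}

#' Cursor speed resampled onto the rate-matrix bins
#'
#' @param rm session \code{rate_matrix}.
#' @param traces list of per-trial cursor traces.
#' @param cutoff_hz speed filter cutoff.
#' @return numeric vector, one speed per rate-matrix column (NA where no
#'   trial covers the bin).
#' @export
session_speed_bins <- function(rm, traces, cutoff_hz = 10) {
  out <- rep(NA_real_, length(rm$bin_times))
  for (tr in traces) {
    sp <- compute_speed(tr, cutoff_hz = cutoff_hz)
    cols <- time_to_col(rm, sp$t_ms)
    out[cols] <- sp$speed
  }
  out
}
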