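# Firing-rate preprocessing: 10-ms binning, Gaussian smoothing, square-root
# variance stabilisation, and event-aligned condition-independent averaging.

#' Bin, smooth and square-root transform spike trains
#'
#' Spike counts in \code{bin_ms} bins are converted to rates (spikes/s),
#' smoothed with a Gaussian kernel (truncated at +/- 4 sigma and
#' renormalised, including at the series edges so kernel mass is conserved),
#' and square-root transformed to equalise variance between high- and
#' low-rate units. The raw smoothed rates are retained alongside: the
#' population-average raw rate drives plane alignment, and the rate
#' regression baseline uses raw rates.
#'
#' @param spikes either the \code{spikes} element of a session (list with
#'   \code{units} and \code{times}) or a named list of spike-time vectors.
#' @param session_length_ms session duration; bins cover (0, length].
#' @param bin_ms bin width, default 10 ms (100 Hz).
#' @param sigma_ms Gaussian smoothing SD, default 30 ms.
#' @return a \code{rate_matrix}: list with \code{unit_ids},
#'   \code{bin_times} (bin centers, ms), \code{rates} (units x bins,
#'   sqrt(spikes/s)), \code{rates_raw} (units x bins, spikes/s),
#'   \code{pop_rate} (mean raw rate across units per bin), \code{bin_ms},
#'   \code{sigma_ms}, \code{sqrt_transformed = TRUE}.
#' @export
bin_smooth_sqrt <- function(spikes, session_length_ms, bin_ms = 10,
                            sigma_ms = 30) {
  times <- if (!is.null(spikes$times)) spikes$times else spikes
  unit_ids <- if (!is.null(spikes$units)) spikes$units$unit_id else
    seq_along(times)
  n_bins <- ceiling(session_length_ms / bin_ms)
  kern <- gauss_kernel(sigma_ms / bin_ms)
  raw <- matrix(0, nrow = length(times), ncol = n_bins)
  for (j in seq_along(times)) {
    st <- times[[j]]
    st <- st[st > 0 & st <= n_bins * bin_ms]
    counts <- tabulate(pmin(ceiling(st / bin_ms), n_bins), nbins = n_bins)
    raw[j, ] <- smooth_renorm(counts * (1000 / bin_ms), kern)
  }
  structure(list(
    unit_ids = unit_ids,
    bin_times = (seq_len(n_bins) - 0.5) * bin_ms,
    rates = sqrt(pmax(raw, 0)),
    rates_raw = raw,
    pop_rate = colMeans(raw),
    bin_ms = bin_ms,
    sigma_ms = sigma_ms,
    sqrt_transformed = TRUE
  ), class = "rate_matrix")
}

gauss_kernel <- function(sigma_bins) {
  half <- max(1L, ceiling(4 * sigma_bins))
  k <- exp(-((-half):half)^2 / (2 * sigma_bins^2))
  k / sum(k)
}

# Convolution with edge renormalisation: near the boundaries the kernel is
# re-scaled by the in-range mass so a constant input stays constant and
# total mass is conserved for interior events.
smooth_renorm <- function(x, kern) {
  n <- length(x)
  half <- (length(kern) - 1L) / 2L
  xp <- c(rep(0, half), x, rep(0, half))
  sm <- stats::convolve(xp, kern, type = "filter")
  mass <- stats::convolve(c(rep(0, half), rep(1, n), rep(0, half)), kern,
                          type = "filter")
  sm / mass
}

#' Column segments of a rate matrix covered by each trial
#'
#' @param rm a \code{rate_matrix}.
#' @param trials data frame with \code{start_ms} and \code{end_ms}.
#' @return list of integer column ranges, one per trial (possibly empty).
#' @export
trial_segments <- function(rm, trials) {
  lapply(seq_len(nrow(trials)), function(i) {
    which(rm$bin_times > trials$start_ms[i] & rm$bin_times < trials$end_ms[i])
  })
}

# Column index of the bin containing time t_ms.
time_to_col <- function(rm, t_ms) {
  pmin(pmax(ceiling(t_ms / rm$bin_ms), 1L), length(rm$bin_times))
}

#' Event-aligned condition-independent average trajectory
#'
#' Averages each unit's (square-root transformed) firing rate across all
#' events at each lag in the window, regardless of movement condition.
#' Events whose window does not fit inside a single contiguous segment are
#' dropped (count reported as an attribute).
#'
#' @param rm a \code{rate_matrix}.
#' @param events_ms event (speed-peak) times in session ms.
#' @param window_ms c(before, after) window around each event, default
#'   c(-500, 300).
#' @param segments optional list of contiguous column ranges (e.g. from
#'   [trial_segments()]); if NULL the whole session is one segment.
#' @return matrix units x lags with attributes \code{lags_ms},
#'   \code{n_used}, \code{n_dropped}.
#' @export
ci_average_by_event <- function(rm, events_ms, window_ms = c(-500, 300),
                                segments = NULL) {
  if (length(events_ms) < 1L) stop("need at least one event")
  if (is.null(segments)) segments <- list(seq_along(rm$bin_times))
  lag_lo <- round(window_ms[1] / rm$bin_ms)
  lag_hi <- round(window_ms[2] / rm$bin_ms)
  lags <- lag_lo:lag_hi
  seg_first <- vapply(segments, function(s) if (length(s)) s[1] else NA_integer_, 0L)
  seg_last <- vapply(segments, function(s) if (length(s)) s[length(s)] else NA_integer_, 0L)
  acc <- matrix(0, nrow = nrow(rm$rates), ncol = length(lags))
  used <- 0L
  for (ev in events_ms) {
    cc <- time_to_col(rm, ev)
    seg <- which(seg_first <= cc & seg_last >= cc)[1]
    if (is.na(seg)) next
    if (cc + lag_lo < seg_first[seg] || cc + lag_hi > seg_last[seg]) next
    acc <- acc + rm$rates[, cc + lags, drop = FALSE]
    used <- used + 1L
  }
  if (used == 0L) stop("no usable events: all windows fall outside segments")
  out <- acc / used
  attr(out, "lags_ms") <- lags * rm$bin_ms
  attr(out, "n_used") <- used
  attr(out, "n_dropped") <- length(events_ms) - used
  out
}
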