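# Independent oracles used across tests. These deliberately use different
# algorithms from the package implementations.

# Brute-force peak prominence: for each local maximum, scan outward sample
# by sample to the nearest strictly larger sample on each side and take the
# interval minima. O(n^2), explicit loops.
oracle_peaks <- function(s, min_height = 250, prom_frac = 0.5) {
  n <- length(s)
  out <- NULL
  i <- 2L
  while (i <= n - 1L) {
    if (s[i] > s[i - 1L]) {
      j <- i
      while (j < n && s[j + 1L] == s[i]) j <- j + 1L
      if (j < n && s[j + 1L] < s[i]) {
        h <- s[i]
        l <- i - 1L; ltr <- s[l]
        while (l >= 1L && s[l] <= h) { ltr <- min(ltr, s[l]); l <- l - 1L }
        r <- i + 1L; rtr <- s[r]
        while (r <= n && s[r] <= h) { rtr <- min(rtr, s[r]); r <- r + 1L }
        prom <- h - max(ltr, rtr)
        if (h > min_height && prom >= prom_frac * h)
          out <- rbind(out, c(idx = i, height = h, prom = prom))
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Brute-force skew-symmetric least squares via numerical optimisation.
oracle_skew <- function(X, Xdot) {
  d <- nrow(X)
  from_par <- function(p) {
    M <- matrix(0, d, d); M[upper.tri(M)] <- p; M - t(M)
  }
  obj <- function(p) sum((Xdot - from_par(p) %*% X)^2)
  grad <- function(p) {
    M <- from_par(p)
    G <- 2 * (M %*% X - Xdot) %*% t(X)
    Gs <- (G - t(G)) / 2
    2 * Gs[upper.tri(Gs)]
  }
  o <- stats::optim(rep(0, d * (d - 1) / 2), obj, grad, method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-15))
  from_par(o$par)
}

# Random rough speed traces (px/s) for property tests: smoothed positive
# noise with occasional large excursions.
random_speed_trace <- function(n = 300) {
  x <- stats::rnorm(n)
  k <- exp(-(-10:10)^2 / 18)
  s <- stats::convolve(c(rep(0, 10), x, rep(0, 10)), k / sum(k),
                       type = "filter")
  400 * abs(s) + stats::runif(1, 0, 120)
}

# A hand-built rate_matrix for unit tests.
make_rate_matrix <- function(raw, bin_ms = 10, sigma_ms = 30) {
  structure(list(
    unit_ids = seq_len(nrow(raw)),
    bin_times = (seq_len(ncol(raw)) - 0.5) * bin_ms,
    rates = sqrt(pmax(raw, 0)),
    rates_raw = raw,
    pop_rate = colMeans(raw),
    bin_ms = bin_ms, sigma_ms = sigma_ms, sqrt_transformed = TRUE
  ), class = "rate_matrix")
}

# Small simulated session shared by several tests.
small_session <- function(seed = 7, n_trials = 40, n_units = 15, ...) {
  simulate_session(sim_config(n_trials = n_trials, n_units = n_units,
                              seed = seed, ...))
}

accepted_subs <- function(subs) subs[subs$class %in% c("initial", "corrective"), ]
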