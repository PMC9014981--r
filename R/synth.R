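# Synthetic precision center-out sessions: Gaussian-bump submovement
# kinematics plus cosine-tuned inhomogeneous Poisson spiking, with full
# ground truth so every downstream stage can be tested by parameter
# recovery.

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: 8 target
#' directions at 45-degree spacing crossed with 3 target sizes in a
#' 1000 x 1000 px workspace (center radius 75 px); bell-shaped (Gaussian)
#' speed profiles with corrective peak speeds averaging one-third of
#' initial; inter-peak intervals from a shifted gamma with mean 570 ms;
#' per-unit firing-rate bumps leading each speed peak by a unit-specific
#' lag, amplitude scaling with submovement peak speed, cosine directional
#' tuning, and Poisson spiking at 1-ms resolution.
#'
#' Peak speeds are drawn from the configured distribution and displacements
#' follow from the target geometry, so each submovement's duration (FWHM)
#' is derived from the two; \code{fwhm_initial_ms} and
#' \code{fwhm_corrective_ms} are the nominal values used by the standalone
#' bump helper and documentation. Corrective displacements are drawn so the
#' acceleration phase starts outside the peripheral target, guaranteeing
#' classifiable corrective submovements.
#'
#' @param n_trials number of trials.
#' @param sample_rate cursor sampling rate, Hz.
#' @param directions target directions, degrees.
#' @param size_classes target size classes.
#' @param p_extra_submovement probability a trial has at least one
#'   corrective submovement.
#' @param p_second_corrective conditional probability of a second
#'   corrective given the first.
#' @param initial_peak_speed_mean,initial_peak_speed_sd px/s.
#' @param corrective_amplitude_ratio mean corrective/initial peak-speed
#'   ratio, in (0, 1).
#' @param corrective_speed_jitter_sd SD of the lognormal jitter on the
#'   corrective peak-speed ratio.
#' @param fwhm_initial_ms,fwhm_corrective_ms nominal full-width at
#'   half-maximum of the speed bumps, ms.
#' @param corrective_dist_range range of corrective displacement, px.
#' @param inter_peak_shift_ms,inter_peak_gamma_shape,inter_peak_gamma_scale
#'   shifted-gamma inter-peak interval parameters (mean =
#'   shift + shape * scale, default 570 ms).
#' @param n_units number of recorded units.
#' @param baseline_rate_range per-unit baseline firing rate, spikes/s.
#' @param lag_range per-unit lead time of the rate bump relative to the
#'   speed peak, ms (negative = leads).
#' @param tuning_depth_range cosine tuning depth, in [0, 1].
#' @param amplitude_gain_range per-unit gain, (spikes/s) per (px/s) of peak
#'   speed.
#' @param gain_noise_sd optional lognormal SD of trial-to-trial gain noise
#'   (0 disables it).
#' @param position_noise_sd additive cursor position noise, px (0 = noise
#'   free).
#' @param seed integer master seed; fans out to per-trial and per-unit
#'   substreams so adding trials or units does not perturb earlier ones.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_trials = 200,
                       sample_rate = 100,
                       directions = seq(0, 315, by = 45),
                       size_classes = c("large", "narrow", "shallow"),
                       p_extra_submovement = 0.32,
                       p_second_corrective = 0.4,
                       initial_peak_speed_mean = 1350,
                       initial_peak_speed_sd = 150,
                       corrective_amplitude_ratio = 1 / 3,
                       corrective_speed_jitter_sd = 0.12,
                       fwhm_initial_ms = 230,
                       fwhm_corrective_ms = 200,
                       corrective_dist_range = c(75, 115),
                       inter_peak_shift_ms = 300,
                       inter_peak_gamma_shape = 3,
                       inter_peak_gamma_scale = 90,
                       n_units = 30,
                       baseline_rate_range = c(5, 20),
                       lag_range = c(-200, 0),
                       tuning_depth_range = c(0, 0.5),
                       amplitude_gain_range = c(0.008, 0.03),
                       gain_noise_sd = 0,
                       position_noise_sd = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_trials < 1 || cfg$n_trials != round(cfg$n_trials))
    stop("n_trials must be a positive integer")
  if (cfg$n_units < 1) stop("n_units must be positive")
  if (cfg$sample_rate <= 0) stop("sample_rate must be positive")
  if (cfg$corrective_amplitude_ratio <= 0 || cfg$corrective_amplitude_ratio >= 1)
    stop("corrective_amplitude_ratio must lie in (0, 1)")
  if (cfg$fwhm_initial_ms <= 0 || cfg$fwhm_corrective_ms <= 0)
    stop("FWHM values must be positive")
  if (any(cfg$tuning_depth_range < 0) || any(cfg$tuning_depth_range > 1))
    stop("tuning_depth_range must lie in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

FWHM_TO_SD <- 2 * sqrt(2 * log(2))  # ~2.355

#' Analytic cursor trace for a single Gaussian speed bump
#'
#' Speed profile v(t) = peak_speed * exp(-(t - peak_ms)^2 / (2 sigma^2))
#' with sigma = fwhm_ms / (2 sqrt(2 log 2)); the position is its closed-form
#' integral. Useful as an oracle for the kinematics functions.
#'
#' @param peak_speed px/s; \code{fwhm_ms} bump width; \code{peak_ms} peak
#'   time; \code{direction_rad} movement direction; \code{t_ms} sample
#'   times; \code{start} starting position.
#' @param fwhm_ms,peak_ms,direction_rad,t_ms,start see above.
#' @return a \code{cursor_trace}-style data frame (trial_id 1).
#' @export
gaussian_bump_trace <- function(peak_speed, fwhm_ms, peak_ms,
                                direction_rad = 0,
                                t_ms = seq(0, 2 * peak_ms, by = 10),
                                start = c(500, 500)) {
  sigma <- fwhm_ms / FWHM_TO_SD
  d_px <- peak_speed * (sigma / 1000) * sqrt(2 * pi)
  disp <- d_px * stats::pnorm((t_ms - peak_ms) / sigma)
  data.frame(trial_id = 1L, t_ms = t_ms,
             x_px = start[1] + cos(direction_rad) * disp,
             y_px = start[2] + sin(direction_rad) * disp)
}

#' Simulate a complete synthetic session
#'
#' Generates per-trial cursor traces (sum of Gaussian-bump submovement
#' displacements aimed from the current position toward the target or a
#' corrected endpoint), per-unit spike trains from rectified inhomogeneous
#' Poisson rates, and the ground truth needed for parameter-recovery tests.
#'
#' Unit i's instantaneous rate is
#' \code{baseline_i + sum_s gain_i * v_s * exp(-(t - (t_s + lag_i))^2 /
#' (2 sigma_s^2)) * (1 + depth_i * cos(theta_s - pref_i))}, rectified at
#' zero and sampled as Poisson counts in 1-ms bins, where \code{v_s},
#' \code{theta_s}, \code{sigma_s} are the submovement's peak speed,
#' direction and temporal width.
#'
#' @param config a [sim_config()].
#' @return list with \code{traces} (list of per-trial cursor data frames),
#'   \code{targets} (trial_id, direction_deg, size_class),
#'   \code{spikes} (list: \code{units} data frame of ground-truth unit
#'   parameters, \code{times} named list of spike-time vectors in session
#'   ms), \code{ground_truth} (one row per generated submovement),
#'   \code{trials} (trial_id, start_ms, end_ms), \code{session_length_ms},
#'   and \code{config}.
#' @export
simulate_session <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  combos <- expand.grid(direction_deg = cfg$directions,
                        size_class = cfg$size_classes,
                        stringsAsFactors = FALSE)
  center <- c(500, 500)

  # ---- per-unit ground-truth parameters (substream block 2) ----
  units <- do.call(rbind, lapply(seq_len(cfg$n_units), function(j) {
    set.seed(substream_seed(cfg$seed, 2, j))
    data.frame(
      unit_id = j,
      baseline = stats::runif(1, cfg$baseline_rate_range[1],
                              cfg$baseline_rate_range[2]),
      gain = stats::runif(1, cfg$amplitude_gain_range[1],
                          cfg$amplitude_gain_range[2]),
      depth = stats::runif(1, cfg$tuning_depth_range[1],
                           cfg$tuning_depth_range[2]),
      pref_rad = stats::runif(1, -pi, pi),
      lag_ms = stats::runif(1, cfg$lag_range[1], cfg$lag_range[2])
    )
  }))

  # ---- per-trial kinematics (substream block 1) ----
  step <- 1000 / cfg$sample_rate
  gap_ms <- 200
  traces <- vector("list", cfg$n_trials)
  gt_rows <- vector("list", cfg$n_trials)
  trial_meta <- vector("list", cfg$n_trials)
  t_start <- 0
  for (i in seq_len(cfg$n_trials)) {
    set.seed(substream_seed(cfg$seed, 1, i))
    combo <- combos[((i - 1L) %% nrow(combos)) + 1L, ]
    tr <- simulate_trial_kinematics(cfg, combo, center, step)
    tr$trace$t_ms <- tr$trace$t_ms + t_start
    tr$trace$trial_id <- i
    tr$subs$peak_time_ms <- tr$subs$peak_time_ms + t_start
    tr$subs$trial_id <- i
    traces[[i]] <- tr$trace
    gt_rows[[i]] <- tr$subs
    trial_meta[[i]] <- data.frame(trial_id = i, start_ms = t_start,
                                  end_ms = t_start + tr$len_ms,
                                  direction_deg = combo$direction_deg,
                                  size_class = combo$size_class,
                                  gain_factor = tr$gain_factor)
    t_start <- t_start + tr$len_ms + gap_ms
  }
  ground_truth <- do.call(rbind, gt_rows)
  trials <- do.call(rbind, trial_meta)
  session_len <- ceiling(t_start)

  # ---- per-unit spike trains (substream block 3) ----
  gt_gain <- ground_truth$peak_speed *
    trials$gain_factor[match(ground_truth$trial_id, trials$trial_id)]
  times <- vector("list", cfg$n_units)
  for (j in seq_len(cfg$n_units)) {
    set.seed(substream_seed(cfg$seed, 3, j))
    u <- units[j, ]
    rate <- rep(u$baseline, session_len)
    centers <- ground_truth$peak_time_ms + u$lag_ms
    amps <- u$gain * gt_gain *
      (1 + u$depth * cos(ground_truth$direction_rad - u$pref_rad))
    for (s in seq_len(nrow(ground_truth))) {
      sg <- ground_truth$sigma_ms[s]
      lo <- max(1L, floor(centers[s] - 4 * sg))
      hi <- min(session_len, ceiling(centers[s] + 4 * sg))
      if (lo > hi) next
      tt <- lo:hi
      rate[tt] <- rate[tt] + amps[s] * exp(-(tt - centers[s])^2 / (2 * sg^2))
    }
    rate <- pmax(rate, 0)
    counts <- stats::rpois(session_len, rate / 1000)
    nz <- which(counts > 0L)
    st <- rep(nz - 1L, counts[nz]) + stats::runif(sum(counts))
    times[[j]] <- sort(st)
  }
  names(times) <- units$unit_id

  targets <- trials[, c("trial_id", "direction_deg", "size_class")]
  structure(list(
    traces = traces,
    targets = targets,
    spikes = list(units = units, times = times),
    ground_truth = ground_truth,
    trials = trials[, c("trial_id", "start_ms", "end_ms")],
    session_length_ms = session_len,
    config = cfg
  ), class = "cidyn_session")
}

# One trial: decide the submovement chain geometry, then evaluate the
# closed-form trajectory on the sampling grid. Times here are trial-local ms.
simulate_trial_kinematics <- function(cfg, combo, center, step) {
  theta_c <- combo$direction_deg * pi / 180
  geom <- target_geometry(combo$size_class)

  v_init <- max(stats::rnorm(1, cfg$initial_peak_speed_mean,
                             cfg$initial_peak_speed_sd), 600)
  has_corr <- stats::runif(1) < cfg$p_extra_submovement
  n_corr <- if (!has_corr) 0L else
    1L + as.integer(stats::runif(1) < cfg$p_second_corrective)
  eps <- stats::runif(1, -3, 3) * pi / 180
  a0 <- theta_c + eps

  # geometry of the chain (all positions relative to workspace center)
  if (n_corr == 0L) {
    d_init <- 350 + stats::runif(1, -20, 20)
    pts <- list(d_init * c(cos(a0), sin(a0)))
    v_corr <- numeric()
  } else {
    v_corr <- v_init * cfg$corrective_amplitude_ratio *
      exp(stats::rnorm(n_corr, 0, cfg$corrective_speed_jitter_sd))
    d_corr <- stats::runif(n_corr, cfg$corrective_dist_range[1],
                           cfg$corrective_dist_range[2])
    u_frac <- stats::runif(1, 0.4, 0.6)
    r0 <- geom$r_in - d_corr[n_corr] * u_frac
    if (n_corr == 2L) {
      # first corrective moves tangentially at radius r0 (outside the
      # target), second enters it radially
      delta <- 2 * asin(min(d_corr[1] / (2 * r0), 1))
      p1 <- r0 * c(cos(a0 + delta), sin(a0 + delta))
      p2 <- r0 * c(cos(a0), sin(a0))
      p3 <- (r0 + d_corr[2]) * c(cos(a0), sin(a0))
      pts <- list(p1, p2, p3)
    } else {
      p1 <- r0 * c(cos(a0), sin(a0))
      p2 <- (r0 + d_corr[1]) * c(cos(a0), sin(a0))
      pts <- list(p1, p2)
    }
  }

  # peak times: pre-instruction hold, reaction, then shifted-gamma intervals
  instr <- stats::runif(1, 300, 500)
  tp <- instr + stats::runif(1, 300, 450)
  speeds <- c(v_init, v_corr)
  n_sub <- length(pts)
  peak_times <- numeric(n_sub)
  peak_times[1] <- tp
  if (n_sub > 1L) for (s in 2:n_sub)
    peak_times[s] <- peak_times[s - 1] + cfg$inter_peak_shift_ms +
      stats::rgamma(1, shape = cfg$inter_peak_gamma_shape,
                    scale = cfg$inter_peak_gamma_scale)

  prev <- c(0, 0)
  dirs <- d_px <- sigma <- numeric(n_sub)
  for (s in seq_len(n_sub)) {
    seg <- pts[[s]] - prev
    d_px[s] <- sqrt(sum(seg^2))
    dirs[s] <- atan2(seg[2], seg[1])
    sigma[s] <- d_px[s] * 1000 / (speeds[s] * sqrt(2 * pi))
    prev <- pts[[s]]
  }

  len_ms <- ceiling((peak_times[n_sub] + 800) / step) * step
  t_ms <- seq(0, len_ms, by = step)
  x <- rep(center[1], length(t_ms))
  y <- rep(center[2], length(t_ms))
  for (s in seq_len(n_sub)) {
    disp <- d_px[s] * stats::pnorm((t_ms - peak_times[s]) / sigma[s])
    x <- x + cos(dirs[s]) * disp
    y <- y + sin(dirs[s]) * disp
  }
  if (cfg$position_noise_sd > 0) {
    x <- x + stats::rnorm(length(x), 0, cfg$position_noise_sd)
    y <- y + stats::rnorm(length(y), 0, cfg$position_noise_sd)
  }
  gain_factor <- if (cfg$gain_noise_sd > 0)
    exp(stats::rnorm(1, 0, cfg$gain_noise_sd)) else 1

  list(
    trace = data.frame(trial_id = NA_integer_, t_ms = t_ms, x_px = x, y_px = y),
    subs = data.frame(
      trial_id = NA_integer_,
      peak_time_ms = peak_times,
      class = c("initial", rep("corrective", n_sub - 1L)),
      peak_speed = speeds,
      direction_rad = dirs,
      sigma_ms = sigma,
      d_px = d_px
    ),
    len_ms = len_ms,
    gain_factor = gain_factor
  )
}

#' Write / read a session to plain-text files
#'
#' Writes kinematics, targets and spikes as CSV and the ground truth,
#' trials and configuration as JSON under \code{path}. Spike times are
#' written with full double precision so the round trip is exact.
#'
#' @param session a \code{cidyn_session} from [simulate_session()].
#' @param path directory to create/write into.
#' @return \code{path}, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  kin <- if (length(session$traces)) do.call(rbind, session$traces) else
    data.frame(trial_id = integer(), t_ms = numeric(),
               x_px = numeric(), y_px = numeric())
  utils::write.csv(kin, file.path(path, "kinematics.csv"), row.names = FALSE)
  utils::write.csv(session$targets, file.path(path, "targets.csv"),
                   row.names = FALSE)
  ids <- rep(session$spikes$units$unit_id,
             vapply(session$spikes$times, length, 0L))
  tms <- unlist(session$spikes$times, use.names = FALSE)
  con <- file(file.path(path, "spikes.csv"), "w")
  writeLines("unit_id,t_ms", con)
  if (length(ids)) writeLines(sprintf("%d,%.17g", ids, tms), con)
  close(con)
  utils::write.csv(session$spikes$units, file.path(path, "units.csv"),
                   row.names = FALSE)
  meta <- list(ground_truth = session$ground_truth,
               trials = session$trials,
               session_length_ms = session$session_length_ms,
               config = unclass(session$config))
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session
#' @return for \code{read_session}, a \code{cidyn_session} list.
#' @export
read_session <- function(path) {
  need <- c("kinematics.csv", "targets.csv", "spikes.csv", "units.csv",
            "session.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("session directory is missing file(s): ", paste(missing, collapse = ", "))
  kin <- utils::read.csv(file.path(path, "kinematics.csv"))
  for (col in c("trial_id", "t_ms", "x_px", "y_px"))
    if (!col %in% names(kin))
      stop("kinematics.csv: missing required column '", col, "'")
  targets <- utils::read.csv(file.path(path, "targets.csv"))
  units <- utils::read.csv(file.path(path, "units.csv"))
  sp <- utils::read.csv(file.path(path, "spikes.csv"))
  if (nrow(sp) && !all(c("unit_id", "t_ms") %in% names(sp)))
    stop("spikes.csv: expected columns unit_id,t_ms")
  meta <- jsonlite::read_json(file.path(path, "session.json"),
                              simplifyVector = TRUE)
  traces <- if (nrow(kin)) {
    unname(lapply(split(kin, kin$trial_id)[as.character(sort(unique(kin$trial_id)))],
                  function(d) { rownames(d) <- NULL; d }))
  } else list()
  times <- lapply(units$unit_id, function(j) {
    v <- sp$t_ms[sp$unit_id == j]
    as.numeric(v)
  })
  names(times) <- units$unit_id
  cfg <- meta$config
  cfg$size_classes <- as.character(cfg$size_classes)
  class(cfg) <- "sim_config"
  structure(list(
    traces = traces,
    targets = targets,
    spikes = list(units = units, times = times),
    ground_truth = as.data.frame(meta$ground_truth),
    trials = as.data.frame(meta$trials),
    session_length_ms = meta$session_length_ms,
    config = cfg
  ), class = "cidyn_session")
}
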