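# End-to-end driver: simulate (optional) -> segment -> cross-validated CI
# phase -> timing-model evaluation, with a machine-readable report.

#' Analysis parameters for the full pipeline
#'
#' Defaults are the study's stated operating point: 10-Hz speed filter,
#' 250 px/s peak threshold with 50 percent prominence, 150-px initial
#' distance rule, 30-ms Gaussian rate smoothing, 6 principal components,
#' 3 CI-phase iterations, 5-fold cross-validation, and a -300 to +100 ms
#' evaluation window around each speed peak.
#'
#' @param cutoff_hz speed filter cutoff, Hz.
#' @param peak_threshold minimum peak speed, px/s.
#' @param prom_frac prominence fraction of peak height.
#' @param initial_dist_px movement-end distance for the initial rule, px.
#' @param sigma_ms rate smoothing SD, ms.
#' @param n_pc principal components.
#' @param n_iter CI-phase iterations.
#' @param n_angle_bins,n_phase_bins alignment and phase-averaging bins.
#' @param k cross-validation folds.
#' @param eval_window_ms timing evaluation window, ms.
#' @param ci_window_ms event-aligned averaging window, ms.
#' @param seed seed for fold assignment.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(cutoff_hz = 10, peak_threshold = 250,
                            prom_frac = 0.5, initial_dist_px = 150,
                            sigma_ms = 30, n_pc = 6, n_iter = 3,
                            n_angle_bins = 36, n_phase_bins = 36, k = 5,
                            eval_window_ms = c(-300, 100),
                            ci_window_ms = c(-500, 300), seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Match detected submovements against simulator ground truth
#'
#' Greedy nearest-time matching within \code{tol_ms}.
#'
#' @param submovements segmentation output (accepted classes only are
#'   compared).
#' @param ground_truth simulator ground-truth table.
#' @param tol_ms matching tolerance, default 10 ms (one sample).
#' @return list with \code{precision}, \code{recall},
#'   \code{class_agreement}, \code{mean_abs_dt_ms}, \code{n_detected},
#'   \code{n_true}.
#' @export
match_ground_truth <- function(submovements, ground_truth, tol_ms = 10) {
  det <- submovements[submovements$class %in% c("initial", "corrective"), ]
  nT <- nrow(ground_truth); nD <- nrow(det)
  used <- logical(nT)
  hit <- integer(nD)
  for (i in seq_len(nD)) {
    dt <- abs(ground_truth$peak_time_ms - det$peak_time_ms[i])
    dt[used] <- Inf
    j <- which.min(dt)
    if (length(j) && dt[j] <= tol_ms) { used[j] <- TRUE; hit[i] <- j }
  }
  matched <- hit > 0L
  list(
    precision = if (nD) mean(matched) else NA_real_,
    recall = sum(matched) / nT,
    class_agreement = if (any(matched))
      mean(det$class[matched] == ground_truth$class[hit[matched]]) else NA_real_,
    mean_abs_dt_ms = if (any(matched))
      mean(abs(det$peak_time_ms[matched] -
                 ground_truth$peak_time_ms[hit[matched]])) else NA_real_,
    n_detected = nD, n_true = nT
  )
}

#' Run the full analysis pipeline on a session
#'
#' Segments the cursor data into submovements, computes the
#' cross-validated CI phase, evaluates both timing models on the identical
#' submovement set, and assembles a report. If \code{session} is NULL a
#' synthetic session is simulated from \code{sim_cfg} first, and
#' ground-truth recovery statistics are included.
#'
#' @param session a \code{cidyn_session}, or NULL to simulate.
#' @param sim_cfg a [sim_config()] used when \code{session} is NULL.
#' @param cfg a [pipeline_config()].
#' @param crossval if TRUE (default) the CI phase is 5-fold
#'   cross-validated; otherwise the full-session iterative fit is used.
#' @param out_dir optional directory; when given, submovements, phase
#'   series and the report JSON are written there.
#' @return list with \code{report} (named list of summary numbers),
#'   \code{submovements}, \code{phase}, \code{evals} (both
#'   \code{timing_eval}s), \code{ftests}, \code{speed_phase},
#'   \code{session}.
#' @export
run_pipeline <- function(session = NULL, sim_cfg = sim_config(),
                         cfg = pipeline_config(), crossval = TRUE,
                         out_dir = NULL) {
  if (is.null(session)) session <- simulate_session(sim_cfg)

  subs <- segment_session(session$traces, session$targets,
                          min_height = cfg$peak_threshold,
                          prom_frac = cfg$prom_frac,
                          initial_dist_px = cfg$initial_dist_px,
                          cutoff_hz = cfg$cutoff_hz)
  acc <- subs[subs$class %in% c("initial", "corrective"), ]
  if (nrow(acc) < cfg$k) stop("pipeline stage 'segment': too few submovements")

  rm_ <- bin_smooth_sqrt(session$spikes, session$session_length_ms,
                         sigma_ms = cfg$sigma_ms)
  segs <- trial_segments(rm_, session$trials)
  events <- acc$peak_time_ms

  if (crossval) {
    cv <- crossval_ciphase(rm_, events, session$trials, k = cfg$k,
                           seed = cfg$seed, n_iter = cfg$n_iter,
                           n_phase_bins = cfg$n_phase_bins,
                           n_angle_bins = cfg$n_angle_bins,
                           window_ms = cfg$ci_window_ms, n_pc = cfg$n_pc)
    phase <- cv$phase
  } else {
    fit <- iterate_ciphase(rm_, events, segments = segs,
                           n_iter = cfg$n_iter,
                           n_phase_bins = cfg$n_phase_bins,
                           n_angle_bins = cfg$n_angle_bins,
                           window_ms = cfg$ci_window_ms, n_pc = cfg$n_pc)
    cv <- NULL
    phase <- fit$phase
  }

  reg <- fit_rate_regression(rm_, acc, window_ms = cfg$eval_window_ms,
                             segments = segs)
  ev_rate <- rate_model_predict_times(reg, rm_, acc,
                                      eval_window_ms = cfg$eval_window_ms,
                                      segments = segs)
  ev_phi <- ciphase_predict_times(phase, acc,
                                  eval_window_ms = cfg$eval_window_ms)

  sum_rate <- timing_summary(ev_rate)
  sum_phi <- timing_summary(ev_phi)
  ftests <- lapply(c(all = "all", initial = "initial",
                     corrective = "corrective"), function(cl) {
    cls <- if (cl == "all") NULL else cl
    tryCatch(variance_ratio_test(ev_phi, ev_rate, class = cls),
             error = function(e) NULL)
  })

  speed_bins <- session_speed_bins(rm_, session$traces, cfg$cutoff_hz)
  spc <- speed_phase_correlation(phase, speed_bins, cfg$n_phase_bins)
  phi_at_peak <- phase$ci_phi[match(time_to_col(rm_, acc$peak_time_ms),
                                    phase$col)]
  ray <- rayleigh_test(phi_at_peak[!is.na(phi_at_peak)])
  cm <- circ_mean_sd(phi_at_peak[!is.na(phi_at_peak)])

  gt_match <- if (!is.null(session$ground_truth))
    match_ground_truth(subs, session$ground_truth) else NULL

  pick <- function(s, cl, col) {
    v <- s[s$class == cl, col]
    if (length(v)) v else NA_real_
  }
  report <- list(
    n_trials = nrow(session$trials),
    n_units = length(session$spikes$times),
    n_initial = sum(acc$class == "initial"),
    n_corrective = sum(acc$class == "corrective"),
    detection = gt_match,
    median_fwhm_initial_ms = stats::median(acc$fwhm_ms[acc$class == "initial"]),
    median_fwhm_corrective_ms = stats::median(acc$fwhm_ms[acc$class == "corrective"]),
    sd_ciphase_ms = pick(sum_phi, "all", "sd_offset_ms"),
    sd_rate_ms = pick(sum_rate, "all", "sd_offset_ms"),
    mean_offset_ciphase_ms = pick(sum_phi, "all", "mean_offset_ms"),
    mean_offset_ciphase_initial_ms = pick(sum_phi, "initial", "mean_offset_ms"),
    mean_offset_ciphase_corrective_ms = pick(sum_phi, "corrective", "mean_offset_ms"),
    aligned_frac_ciphase = pick(sum_phi, "all", "aligned_frac"),
    aligned_frac_rate = pick(sum_rate, "all", "aligned_frac"),
    f_ratio = if (!is.null(ftests$all)) ftests$all$F else NA_real_,
    f_p = if (!is.null(ftests$all)) ftests$all$p else NA_real_,
    speed_phase_r = spc$r,
    speed_phase_p = spc$p,
    phase_max_speed_over_pi = spc$phase_max_speed / pi,
    ciphi_at_peak_mean_over_pi = cm$mean / pi,
    ciphi_at_peak_sd_over_pi = cm$sd / pi,
    ciphi_at_peak_rayleigh_p = ray$p,
    rate_regression_r2 = reg$r_squared
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(subs, file.path(out_dir, "submovements.csv"),
                     row.names = FALSE)
    utils::write.csv(phase, file.path(out_dir, "phase_series.csv"),
                     row.names = FALSE)
    utils::write.csv(rbind(cbind(model = "ciphase", sum_phi),
                           cbind(model = "rate", sum_rate)),
                     file.path(out_dir, "timing_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }

  list(report = report, submovements = subs, phase = phase,
       evals = list(ciphase = ev_phi, rate = ev_rate),
       summaries = list(ciphase = sum_phi, rate = sum_rate),
       ftests = ftests, speed_phase = spc, crossval = cv,
       regression = reg, session = session)
}
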