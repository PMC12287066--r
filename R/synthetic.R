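#' Synthetic session configuration
#'
#' Defines the generative model for a complete synthetic session:
#' a 2-min home-cage connection period followed by a 2-min free-exploration
#' trial; per-channel baselines with slow exponential photobleaching; a
#' band-limited motion artifact entering sensor and isosbestic channels
#' with independent positive scalings; double-exponential event-locked
#' transients on the sensor channels only; white measurement noise; and a
#' biased random-walk trajectory that dwells inside the hole zone exactly
#' during the scheduled investigation events.
#'
#' @param duration Total recording duration (s).
#' @param trial_start,trial_end Trial bounds (s) within the recording.
#' @param sampling_rate Photometry rate (Hz).
#' @param frame_rate Video rate (Hz).
#' @param n_events Number of scheduled hole-investigation events.
#' @param event_duration Range `c(min, max)` of event durations (s).
#' @param refractory Minimum gap between events (s).
#' @param event_margin Clearance between events and the trial bounds (s),
#'   so onset-locked windows fit inside the recording.
#' @param baseline Named raw-fluorescence baselines per channel role.
#' @param bleach_tau Photobleaching time constant (s).
#' @param artifact_sd Artifact standard deviation (raw units).
#' @param artifact_bandwidth Artifact low-pass bandwidth (Hz).
#' @param artifact_scale Named per-channel artifact scalings; defaults are
#'   proportional to the channel baselines because coupling-efficiency
#'   fluctuations scale with the fluorescence level of each channel, which
#'   is the regime in which isosbestic regression removes them exactly.
#' @param tau_rise,tau_decay Transient kernel time constants (s).
#' @param amplitude Named per-sensor transient amplitudes (raw units,
#'   kernel peak height).
#' @param amplitude_cv Lognormal coefficient of variation of per-event
#'   amplitudes (0 = identical events).
#' @param noise_sd White noise standard deviation (raw units).
#' @param hole Hole zone, a [zone_disc()].
#' @param step_sd Random-walk step standard deviation (normalized units
#'   per frame).
#' @param gap_rate Fraction of tracking frames lost to missed detections.
#' @param odorant,hedonics,condition,session_id Session metadata.
#' @return A `sim_config` list.
#' @export
sim_config <- function(duration = 250, trial_start = 125, trial_end = 245,
                       sampling_rate = 100, frame_rate = 25,
                       n_events = 8, event_duration = c(0.3, 3),
                       refractory = 2, event_margin = 2,
                       baseline = c(sensor_465 = 2, sensor_565 = 2,
                                    isosbestic_405 = 1.5),
                       bleach_tau = 3000,
                       artifact_sd = 0.05, artifact_bandwidth = 2,
                       artifact_scale = c(sensor_465 = 1, sensor_565 = 1,
                                          isosbestic_405 = 0.75),
                       tau_rise = 0.05, tau_decay = 0.4,
                       amplitude = c(sensor_465 = 0.05, sensor_565 = 0.05),
                       amplitude_cv = 0.3, noise_sd = 0.005,
                       hole = zone_disc(), step_sd = 0.02, gap_rate = 0.02,
                       odorant = "Citro", hedonics = "plea",
                       condition = "Ctrl", session_id = "sim") {
  cfg <- as.list(environment())
  stopifnot(
    duration > 0, sampling_rate > 0, frame_rate > 0,
    trial_start >= 0, trial_start < trial_end, trial_end <= duration,
    bleach_tau > 0, tau_rise > 0, tau_decay > 0, tau_rise < tau_decay,
    artifact_sd >= 0, noise_sd >= 0, n_events >= 0,
    event_duration[1] > 0, event_duration[1] <= event_duration[2]
  )
  structure(cfg, class = "sim_config")
}

#' Peak time of the double-exponential transient kernel
#'
#' The kernel \eqn{k(t) = e^{-t/\tau_d} - e^{-t/\tau_r}} (normalized to a
#' unit peak) peaks at
#' \eqn{t^* = \tau_r \tau_d / (\tau_d - \tau_r) \log(\tau_d / \tau_r)}.
#'
#' @param tau_rise,tau_decay Kernel time constants (s).
#' @return Peak time in seconds after onset.
#' @export
kernel_peak_time <- function(tau_rise, tau_decay) {
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

transient_kernel <- function(t, tau_rise, tau_decay) {
  k <- ifelse(t < 0, 0, exp(-t / tau_decay) - exp(-t / tau_rise))
  peak <- exp(-kernel_peak_time(tau_rise, tau_decay) / tau_decay) -
    exp(-kernel_peak_time(tau_rise, tau_decay) / tau_rise)
  k / peak
}

schedule_events <- function(cfg) {
  n <- cfg$n_events
  lo <- cfg$trial_start + cfg$event_margin
  hi <- cfg$trial_end - cfg$event_margin
  if (n == 0) {
    return(tibble(index = integer(), t_start = numeric(), t_end = numeric()))
  }
  durations <- runif(n, cfg$event_duration[1], cfg$event_duration[2])
  need <- sum(durations) + (n - 1) * cfg$refractory
  avail <- hi - lo
  if (need > avail) {
    abort_parameter(sprintf(
      "event schedule unsatisfiable: %d events + refractory need %.1f s, trial offers %.1f s",
      n, need, avail
    ))
  }
  slack <- sort(runif(n, 0, avail - need))
  starts <- lo + slack +
    c(0, cumsum(durations[-n] + cfg$refractory))
  tibble(index = seq_len(n), t_start = starts, t_end = starts + durations)
}

reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' Simulate a complete synthetic session
#'
#' Generates the three coupled inputs of a behavior-coupled photometry
#' session — photometry recording, behavioral event table, and
#' frame-indexed pixel tracking — together with the ground truth of every
#' injected quantity (event schedule, per-event amplitudes, the shared
#' artifact trace, kernel parameters). Each sensor channel is
#' `baseline * exp(-t / bleach_tau) + scale * artifact + transients +
#' noise`; the isosbestic channel shares the artifact (its own scaling)
#' but carries no transients. Fixing the seed makes the output
#' reproducible byte for byte.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `ph_sim` list: `recording`, `events`, `tracking`,
#'   `ground_truth`.
#' @export
#' @examples
#' sim <- simulate_session(sim_config(duration = 40, trial_start = 5,
#'                                    trial_end = 38, n_events = 3), seed = 1)
#' sim$events
simulate_session <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  fs <- cfg$sampling_rate
  n <- as.integer(round(cfg$duration * fs))
  time <- (seq_len(n) - 1L) / fs

  sched <- schedule_events(cfg)
  sensors <- names(cfg$amplitude)
  amps <- purrr::map(sensors, function(role) {
    base <- cfg$amplitude[[role]]
    if (cfg$amplitude_cv > 0 && nrow(sched) > 0) {
      base * exp(rnorm(nrow(sched), 0, cfg$amplitude_cv))
    } else {
      rep(base, nrow(sched))
    }
  })
  names(amps) <- sensors

  artifact <- if (cfg$artifact_sd > 0) {
    a <- lowpass_filter(rnorm(n), fs, cutoff = cfg$artifact_bandwidth)
    a / sd(a) * cfg$artifact_sd
  } else {
    rep(0, n)
  }

  transients <- purrr::map(sensors, function(role) {
    tr <- rep(0, n)
    for (i in seq_len(nrow(sched))) {
      from <- sched$t_start[i]
      idx <- which(time >= from & time <= from + 12 * cfg$tau_decay)
      tr[idx] <- tr[idx] +
        amps[[role]][i] * transient_kernel(time[idx] - from, cfg$tau_rise, cfg$tau_decay)
    }
    tr
  })
  names(transients) <- sensors

  bleach <- exp(-time / cfg$bleach_tau)
  channels <- purrr::imap(cfg$baseline, function(b0, role) {
    ch <- b0 * bleach + cfg$artifact_scale[[role]] * artifact +
      rnorm(n, 0, cfg$noise_sd)
    if (role %in% sensors) ch <- ch + transients[[role]]
    ch
  })
  recording <- ph_recording(time, as.list(channels), session_id = cfg$session_id)

  events <- event_table(
    t_start = sched$t_start, t_end = sched$t_end, type = cfg$hole$label,
    trial_start = cfg$trial_start, trial_end = cfg$trial_end,
    odorant = cfg$odorant, hedonics = cfg$hedonics, condition = cfg$condition,
    session_id = cfg$session_id
  )

  # trajectory: reflected random walk, pinned inside the hole during events
  n_frames <- as.integer(round(cfg$duration * cfg$frame_rate))
  ft <- (seq_len(n_frames) - 1L) / cfg$frame_rate
  walk_x <- reflect_into(0.7 + cumsum(rnorm(n_frames, 0, cfg$step_sd)), 0.02, 0.98)
  walk_y <- reflect_into(0.3 + cumsum(rnorm(n_frames, 0, cfg$step_sd)), 0.02, 0.98)
  for (i in seq_len(nrow(sched))) {
    inside <- ft >= sched$t_start[i] & ft < sched$t_end[i]
    k <- sum(inside)
    if (k > 0) {
      r <- cfg$hole$radius * 0.6 * sqrt(runif(k))
      th <- runif(k, 0, 2 * pi)
      walk_x[inside] <- cfg$hole$center[1] + r * cos(th)
      walk_y[inside] <- cfg$hole$center[2] + r * sin(th)
    }
  }
  # pixel frame: 400 px square board, image y axis pointing down
  p1 <- c(50, 450)
  p2 <- c(450, 450)
  px <- p1[1] + 400 * walk_x
  py <- p1[2] - 400 * walk_y
  gaps <- runif(n_frames) < cfg$gap_rate
  px[gaps] <- NA_real_
  py[gaps] <- NA_real_
  tracking <- tracking_table(
    frame = seq_len(n_frames) - 1L, x = px, y = py,
    frame_rate = cfg$frame_rate,
    reference_points = list(p1 = p1, p2 = p2),
    session_id = cfg$session_id
  )

  ground_truth <- list(
    schedule = dplyr::bind_cols(
      sched,
      tibble::as_tibble(stats::setNames(amps, paste0("amplitude_", sensors)))
    ),
    artifact = artifact,
    kernel = list(
      tau_rise = cfg$tau_rise, tau_decay = cfg$tau_decay,
      peak_time = kernel_peak_time(cfg$tau_rise, cfg$tau_decay)
    ),
    trajectory = tibble(frame = seq_len(n_frames) - 1L, x = walk_x, y = walk_y,
                        gap = gaps),
    config = cfg
  )
  structure(
    list(recording = recording, events = events, tracking = tracking,
         ground_truth = ground_truth),
    class = "ph_sim"
  )
}

#' @export
print.ph_sim <- function(x, ...) {
  cat(sprintf(
    "<ph_sim> session '%s': %.0f s at %g Hz, %d events\n",
    session_id(x$recording),
    max(x$recording$time), sampling_rate(x$recording), nrow(x$events)
  ))
  invisible(x)
}

#' Write a simulated session to disk in the standard input conventions
#'
#' Writes `photometry.csv`, `events.csv`, `tracking.csv` and
#' `ground_truth.json` into `dir`.
#'
#' @param sim A `ph_sim` from [simulate_session()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_photometry(sim$recording, file.path(dir, "photometry.csv"))
  write_event_table(sim$events, file.path(dir, "events.csv"))
  write_tracking(sim$tracking, file.path(dir, "tracking.csv"))
  gt <- sim$ground_truth
  jsonlite::write_json(
    list(
      schedule = gt$schedule,
      kernel = gt$kernel,
      artifact = gt$artifact,
      config = gt$config[!purrr::map_lgl(gt$config, inherits, "ph_zone")],
      hole = unclass(gt$config$hole)
    ),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

# matched-filter lag estimate: the argmax of a noisy, flat-topped ensemble
# mean is ill-conditioned, so the displacement between the measured response
# and the injected kernel is estimated from the cross-correlation with the
# ground-truth kernel template (both mean-centered), integrating the whole
# transient shape instead of trusting one sample
matched_lag <- function(rel_time, trace, tau_rise, tau_decay, max_lag = 20L) {
  template <- transient_kernel(rel_time, tau_rise, tau_decay)
  x <- trace - mean(trace)
  k <- template - mean(template)
  n <- length(x)
  lags <- seq(-max_lag, max_lag)
  cc <- vapply(lags, function(l) {
    if (l >= 0) sum(x[(1 + l):n] * k[1:(n - l)]) else sum(x[1:(n + l)] * k[(1 - l):n])
  }, numeric(1))
  i <- which.max(cc)
  # parabolic sub-sample refinement on the correlation function
  if (i > 1 && i < length(cc)) {
    denom <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
    frac <- if (denom < 0) 0.5 * (cc[i - 1] - cc[i + 1]) / denom else 0
  } else {
    frac <- 0
  }
  lags[i] + frac # positive = measured response later than the template
}

#' Parameter-recovery report for a simulated session
#'
#' Runs the pipeline on a simulated session and compares its outputs with
#' the injected ground truth: (i) artifact rejection — correlation of the
#' shared artifact with the raw trace versus with the post-regression
#' DF/F; (ii) alignment fidelity — lag of the onset-locked ensemble-mean
#' peak relative to the injected kernel peak; (iii) amplitude ordering —
#' Spearman correlation between injected per-event amplitudes and
#' per-event during-window AUCs.
#'
#' @param sim A `ph_sim`.
#' @param processed Optional precomputed [preprocess_recording()] output.
#' @param sensor Sensor role to report on.
#' @param pre,post Alignment window (s).
#' @param windows An [auc_windows()] for the amplitude-ordering AUC.
#' @return One-row tibble of recovery metrics.
#' @export
recovery_report <- function(sim, processed = NULL, sensor = "sensor_465",
                            pre = 1, post = 2, windows = auc_windows()) {
  processed <- processed %||% preprocess_recording(sim$recording)
  ch <- processed[[sensor]]
  artifact <- sim$ground_truth$artifact
  corr_raw <- cor(sim$recording[[sensor]], artifact)
  corr_dff <- cor(ch$dff, artifact)

  peak_time <- NA_real_
  lag_samples <- NA_real_
  amp_rank_corr <- NA_real_
  n_used <- 0L
  if (nrow(sim$events) > 0) {
    ens <- extract_aligned(ch, sim$events, pre = pre, post = post)
    n_used <- nrow(ens$matrix)
    kern <- sim$ground_truth$kernel
    lag_samples <- matched_lag(ens$rel_time, ens$mean,
                               kern$tau_rise, kern$tau_decay)
    peak_time <- kern$peak_time + lag_samples / attr(ch, "sampling_rate")
    amps <- sim$ground_truth$schedule[[paste0("amplitude_", sensor)]]
    amps <- amps[ens$event_ids$index]
    bd <- before_during(ens, windows)
    if (nrow(bd) >= 3 && sd(amps[seq_len(nrow(bd))]) > 0) {
      amp_rank_corr <- suppressWarnings(
        cor(amps[seq_len(nrow(bd))], bd$auc_during, method = "spearman")
      )
    }
  }
  tibble(
    corr_raw_artifact = corr_raw,
    corr_dff_artifact = corr_dff,
    peak_time = peak_time,
    kernel_peak_time = sim$ground_truth$kernel$peak_time,
    peak_lag_samples = lag_samples,
    amplitude_rank_corr = amp_rank_corr,
    n_events_used = n_used
  )
}
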