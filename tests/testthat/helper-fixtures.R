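# fixtures built in code; all files go to tempdir() via withr-free local paths

make_recording_csv <- function(path, n = 1200, fs = 100) {
  t <- (seq_len(n) - 1) / fs
  df <- data.frame(
    time = t,
    sensor_465 = 2 + 0.01 * sin(2 * pi * 0.5 * t),
    sensor_565 = 2 + 0.01 * cos(2 * pi * 0.5 * t),
    isosbestic_405 = 1.5 + 0.005 * sin(2 * pi * 0.5 * t)
  )
  write.csv(df, path, row.names = FALSE)
  df
}

# one-row event sheet in the start/end + startN/endN convention
make_event_sheet <- function(path, starts, ends, trial = c(0, 120),
                             odorant = "Citro", hedonics = "plea",
                             condition = "Ctrl") {
  row <- data.frame(
    odorant = odorant, hedonics = hedonics, condition = condition,
    start = trial[1], end = trial[2]
  )
  for (i in seq_along(starts)) {
    row[[paste0("start", i)]] <- starts[i]
    row[[paste0("end", i)]] <- ends[i]
  }
  write.csv(row, path, row.names = FALSE)
  row
}

# a small fast simulation used across tests: 40 s session, 3 events
small_config <- function(...) {
  defaults <- list(
    duration = 40, trial_start = 4, trial_end = 38,
    sampling_rate = 50, frame_rate = 25,
    n_events = 3, event_duration = c(0.3, 1.5), refractory = 2
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# tiny session for statistical replicates: 6 events, low rate
stat_config <- function(amplitude_465 = 0, ...) {
  sim_config(
    duration = 36, trial_start = 2, trial_end = 35,
    sampling_rate = 40, frame_rate = 20,
    n_events = 6, event_duration = c(0.4, 1), refractory = 2,
    event_margin = 1.5,
    amplitude = c(sensor_465 = amplitude_465, sensor_565 = 0),
    amplitude_cv = 0,
    ...
  )
}

# synthetic processed channel built directly from a zscore trace
fake_channel <- function(zscore, fs = 100, t0 = 0) {
  n <- length(zscore)
  ch <- tibble::tibble(
    time = t0 + (seq_len(n) - 1) / fs,
    raw = zscore, filtered = zscore, fitted = rep(1, n),
    dff = zscore, zscore = zscore
  )
  structure(ch, class = c("ph_channel", class(ch)),
            role = "sensor_465", a = 1, b = 0, mu = 0, sigma = 1,
            normalization_window = "full", sampling_rate = fs,
            session_id = "fake")
}

# direct closed-form two-parameter least squares (independent of lm)
ols_closed_form <- function(y, x) {
  a <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(a = a, b = mean(y) - a * mean(x))
}
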