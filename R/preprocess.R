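#' Zero-phase low-pass Butterworth filter
#'
#' Smooths a raw photometry trace with a low-pass Butterworth filter
#' (default 10 Hz cutoff, order 2). By default the filter is applied
#' forward and backward (zero-phase), so event-aligned features are not
#' shifted by group delay; the signal is extended by odd reflection at both
#' ends before filtering so that start/end transients die out in the
#' padding, and DC gain is exactly 1.
#'
#' @param x Numeric trace.
#' @param sampling_rate Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz; must be below Nyquist.
#' @param order Filter order.
#' @param zero_phase Apply forward-backward (TRUE, default) or single-pass
#'   causal filtering (FALSE; introduces group delay).
#' @return Filtered trace, same length as `x`.
#' @export
#' @examples
#' fs <- 120
#' t <- seq(0, 5, by = 1 / fs)
#' x <- sin(2 * pi * 1 * t) + sin(2 * pi * 50 * t)
#' y <- lowpass_filter(x, fs) # keeps the 1 Hz tone, removes the 50 Hz tone
lowpass_filter <- function(x, sampling_rate, cutoff = 10, order = 2,
                           zero_phase = TRUE) {
  nyquist <- sampling_rate / 2
  if (cutoff >= nyquist) {
    abort_parameter(sprintf(
      "cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)", cutoff, nyquist
    ))
  }
  if (length(x) <= 3 * order) {
    abort_parameter(sprintf(
      "trace too short to filter: need > %d samples, got %d", 3 * order, length(x)
    ))
  }
  bf <- signal::butter(order, cutoff / nyquist, type = "low")
  n <- length(x)
  # remove the endpoint-matched line first: a zero-phase symmetric filter with
  # unit DC gain passes linear trends exactly, and zero-ended residuals make
  # the odd reflection free of DC jumps (no edge plateaus from 2*x[n] offsets)
  base <- x[1] + (x[n] - x[1]) * (seq_len(n) - 1) / (n - 1)
  xd <- x - base
  # pad so the zero-state transient decays to machine precision inside the pad
  pad <- min(n - 1L, as.integer(ceiling(15 * sampling_rate / cutoff)))
  xp <- c(-xd[seq(pad + 1L, 2L)], xd, -xd[seq(n - 1L, n - pad)])
  yp <- as.numeric(signal::filter(bf, xp))
  if (zero_phase) {
    yp <- rev(as.numeric(signal::filter(bf, rev(yp))))
  }
  yp[seq(pad + 1L, pad + n)] + base
}

#' Least-squares fit of a sensor trace against the isosbestic channel
#'
#' Ordinary least squares of the filtered sensor signal on the filtered
#' isosbestic (405 nm) control: `fitted = a * isosbestic + b`. The fitted
#' trace models non-neuronal fluctuations (motion artifacts, bleaching
#' shared across excitation wavelengths) and is the DF/F baseline. One
#' isosbestic trace serves both sensor channels of a dual-color rig.
#'
#' @param sensor Filtered sensor trace.
#' @param isosbestic Filtered isosbestic trace, same length.
#' @return A `ph_fit` list with elements `a` (slope), `b` (intercept),
#'   `fitted` and `residuals`.
#' @export
fit_isosbestic <- function(sensor, isosbestic) {
  if (length(sensor) != length(isosbestic)) {
    abort_parameter("sensor and isosbestic traces must have equal length")
  }
  if (sd(isosbestic) == 0) {
    abort_validation("isosbestic trace is constant: regression is degenerate")
  }
  fit <- lm(sensor ~ isosbestic)
  structure(
    list(
      a = unname(stats::coef(fit)[2]),
      b = unname(stats::coef(fit)[1]),
      fitted = unname(stats::fitted(fit)),
      residuals = unname(stats::residuals(fit))
    ),
    class = "ph_fit"
  )
}

#' @export
print.ph_fit <- function(x, ...) {
  cat(sprintf("<ph_fit> fitted = %.6g * isosbestic + %.6g (n = %d)\n",
              x$a, x$b, length(x$fitted)))
  invisible(x)
}

#' Fractional fluorescence change (DF/F)
#'
#' Elementwise `(filtered - fitted) / fitted`, where `fitted` is the
#' isosbestic-predicted baseline. The result is dimensionless and
#' invariant to rescaling both traces by a common positive factor.
#'
#' @param filtered Filtered sensor trace.
#' @param fit A `ph_fit` from [fit_isosbestic()], or a numeric baseline
#'   trace of the same length.
#' @param floor Absolute guard on the baseline: any `|fitted|` below it is
#'   an error (DF/F is undefined at a zero baseline). Default
#'   `1e-12 * median(|fitted|)`.
#' @return DF/F trace.
#' @export
compute_dff <- function(filtered, fit, floor = NULL) {
  fitted <- if (inherits(fit, "ph_fit")) fit$fitted else as.numeric(fit)
  if (length(filtered) != length(fitted)) {
    abort_parameter("filtered and fitted traces must have equal length")
  }
  floor <- floor %||% (1e-12 * median(abs(fitted)))
  bad <- which(abs(fitted) < floor)
  if (length(bad)) {
    abort_validation(sprintf(
      "fitted baseline below floor %g at sample %d: DF/F undefined", floor, bad[1]
    ))
  }
  (filtered - fitted) / fitted
}

#' Z-score a DF/F trace
#'
#' `(dff - mu) / sigma` with `mu` and `sigma` (population standard
#' deviation, divide by n) computed either over the full trace (the
#' default, appropriate for short free-exploration sessions without a
#' defined pre-stimulus baseline) or over a baseline window `[t0, t1]`
#' free of stimulation, then applied to the whole trace.
#'
#' @param dff DF/F trace.
#' @param window `"full"` or a numeric `c(t0, t1)` in seconds.
#' @param time Sample times, required for a numeric window.
#' @return List with `zscore`, `mu`, `sigma`, `window`.
#' @export
zscore_trace <- function(dff, window = "full", time = NULL) {
  if (is.character(window) && identical(window, "full")) {
    sel <- rep(TRUE, length(dff))
  } else if (is.numeric(window) && length(window) == 2L) {
    if (is.null(time)) abort_parameter("`time` is required for a numeric window")
    if (window[1] >= window[2]) abort_parameter("window must satisfy t0 < t1")
    if (window[1] > max(time) || window[2] < min(time)) {
      abort_parameter("window lies outside the recorded time span")
    }
    sel <- time >= window[1] & time <= window[2]
    if (!any(sel)) abort_parameter("window contains no samples")
  } else {
    abort_parameter("window must be \"full\" or c(t0, t1)")
  }
  mu <- mean(dff[sel])
  sigma <- sqrt(mean((dff[sel] - mu)^2)) # population sd
  if (sigma == 0) {
    abort_validation("zero variance in the normalization window")
  }
  list(zscore = (dff - mu) / sigma, mu = mu, sigma = sigma, window = window)
}

#' Preprocess a photometry recording
#'
#' Runs each sensor channel through the full chain: low-pass Butterworth
#' filter, least-squares regression against the (equally filtered)
#' isosbestic channel, DF/F against the fitted baseline, and Z-score. The
#' isosbestic channel itself is filtered but carries no DF/F. Both sensor
#' channels share the one filtered isosbestic trace.
#'
#' @param rec A [ph_recording()] containing `isosbestic_405` and at least
#'   one sensor channel.
#' @param cutoff,order,zero_phase Filter settings, see [lowpass_filter()].
#' @param zscore_window `"full"` or `c(t0, t1)` seconds, see
#'   [zscore_trace()].
#' @param regression Fit the isosbestic baseline (default TRUE). With
#'   FALSE, DF/F uses the channel's own mean as a flat baseline.
#' @param dff_floor Baseline guard, see [compute_dff()].
#' @return A `ph_processed` named list of `ph_channel` tibbles (one per
#'   sensor), each with columns `time`, `raw`, `filtered`, `fitted`,
#'   `dff`, `zscore` and attributes `role`, `a`, `b`, `mu`, `sigma`.
#' @export
preprocess_recording <- function(rec, cutoff = 10, order = 2, zero_phase = TRUE,
                                 zscore_window = "full", regression = TRUE,
                                 dff_floor = NULL) {
  roles <- channel_roles(rec)
  iso_role <- "isosbestic_405"
  sensors <- setdiff(roles, iso_role)
  if (!(iso_role %in% roles)) {
    abort_validation("recording has no isosbestic_405 channel")
  }
  if (!length(sensors)) {
    abort_validation("recording has no sensor channel")
  }
  fs <- sampling_rate(rec)
  iso_filtered <- lowpass_filter(rec[[iso_role]], fs, cutoff, order, zero_phase)

  process_one <- function(role) {
    raw <- rec[[role]]
    filtered <- lowpass_filter(raw, fs, cutoff, order, zero_phase)
    if (regression) {
      fit <- fit_isosbestic(filtered, iso_filtered)
    } else {
      fit <- structure(
        list(a = 0, b = mean(filtered),
             fitted = rep(mean(filtered), length(filtered)),
             residuals = filtered - mean(filtered)),
        class = "ph_fit"
      )
    }
    dff <- compute_dff(filtered, fit, floor = dff_floor)
    z <- zscore_trace(dff, window = zscore_window, time = rec$time)
    ch <- tibble(
      time = rec$time, raw = raw, filtered = filtered,
      fitted = fit$fitted, dff = dff, zscore = z$zscore
    )
    structure(
      ch,
      class = c("ph_channel", class(ch)),
      role = role, a = fit$a, b = fit$b, mu = z$mu, sigma = z$sigma,
      normalization_window = z$window, sampling_rate = fs,
      session_id = session_id(rec)
    )
  }

  out <- purrr::map(sensors, function(role) {
    tryCatch(process_one(role), error = function(e) {
      abort(paste0("channel ", role, ": ", conditionMessage(e)),
            class = class(e)[1], parent = e)
    })
  })
  names(out) <- sensors
  structure(out,
    class = "ph_processed",
    isosbestic_filtered = iso_filtered,
    session_id = session_id(rec)
  )
}

#' @export
print.ph_processed <- function(x, ...) {
  cat(sprintf("<ph_processed> session '%s', sensors: %s\n",
              attr(x, "session_id"), paste(names(x), collapse = ", ")))
  invisible(x)
}

#' @export
print.ph_channel <- function(x, ...) {
  cat(sprintf(
    "<ph_channel> %s: a=%.4g b=%.4g mu=%.4g sigma=%.4g (%d samples at %g Hz)\n",
    attr(x, "role"), attr(x, "a"), attr(x, "b"),
    attr(x, "mu"), attr(x, "sigma"), nrow(x), attr(x, "sampling_rate")
  ))
  NextMethod()
}

#' @exportS3Method generics::tidy
tidy.ph_channel <- function(x, ...) {
  tibble::as_tibble(x)[, c("time", "raw", "filtered", "fitted", "dff", "zscore")]
}

#' @exportS3Method generics::glance
glance.ph_channel <- function(x, ...) {
  tibble(
    role = attr(x, "role"),
    a = attr(x, "a"), b = attr(x, "b"),
    mu = attr(x, "mu"), sigma = attr(x, "sigma"),
    sampling_rate = attr(x, "sampling_rate"),
    n = nrow(x)
  )
}

#' @exportS3Method generics::tidy
tidy.ph_processed <- function(x, ...) {
  purrr::map_dfr(x, function(ch) {
    dplyr::mutate(tidy(ch), role = attr(ch, "role"), .before = 1)
  })
}

#' @exportS3Method generics::glance
glance.ph_processed <- function(x, ...) {
  purrr::map_dfr(x, glance)
}

#' DF/F expressed in percent
#'
#' Convenience relative measure `100 * DF/F`, an alternative to Z-scoring
#' when comparing across sessions or animals.
#'
#' @param dff DF/F trace.
#' @return Percent DF/F trace.
#' @export
dff_percent <- function(dff) 100 * dff
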