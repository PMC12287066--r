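#' Photometry recording container
#'
#' A `ph_recording` is a tibble with a `time` column (seconds, uniform grid)
#' and one column per demodulated channel, carrying the channel roles,
#' inferred sampling rate and session id as attributes. Roles follow the
#' dual-color convention: `sensor_465` (dopamine-dependent), `sensor_565`
#' (calcium-dependent) and `isosbestic_405` (motion/artifact reference).
#'
#' @param time Numeric vector of sample times in seconds, strictly
#'   increasing on a uniform grid.
#' @param channels Named list of numeric traces; names are channel roles.
#' @param session_id Free-text session identifier.
#' @param grid_tol Relative tolerance on the uniformity of the time step.
#'
#' @return A `ph_recording` tibble with columns `time` and one per role.
#' @export
#' @examples
#' rec <- ph_recording(
#'   time = seq(0, 1, by = 0.01),
#'   channels = list(sensor_465 = rnorm(101, 2), isosbestic_405 = rnorm(101, 1.5))
#' )
#' sampling_rate(rec)
ph_recording <- function(time, channels, session_id = "session", grid_tol = 1e-6) {
  if (length(time) < 2L) {
    abort_validation("a recording needs at least 2 samples")
  }
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == "")) {
    abort_validation("`channels` must be a named list of traces")
  }
  bad_len <- names(channels)[lengths(channels) != length(time)]
  if (length(bad_len)) {
    abort_validation(paste0(
      "channel trace length differs from time base: ",
      paste(bad_len, collapse = ", ")
    ))
  }
  dt <- diff(time)
  if (any(dt <= 0)) {
    abort_validation("`time` must be strictly increasing")
  }
  step <- median(dt)
  if (max(abs(dt - step)) > grid_tol * step) {
    abort_validation(sprintf(
      "time base is not uniform within relative tolerance %g (max deviation %g of step %g)",
      grid_tol, max(abs(dt - step)), step
    ))
  }
  out <- tibble(time = as.numeric(time))
  for (nm in names(channels)) out[[nm]] <- as.numeric(channels[[nm]])
  structure(
    out,
    class = c("ph_recording", class(out)),
    sampling_rate = 1 / step,
    session_id = session_id,
    channel_roles = names(channels)
  )
}

#' @rdname ph_recording
#' @param x A `ph_recording`.
#' @export
sampling_rate <- function(x) attr(x, "sampling_rate")

#' @rdname ph_recording
#' @export
channel_roles <- function(x) attr(x, "channel_roles")

#' @rdname ph_recording
#' @export
session_id <- function(x) attr(x, "session_id")

#' @export
print.ph_recording <- function(x, ...) {
  cat(sprintf(
    "<ph_recording> session '%s': %d samples at %.6g Hz, channels: %s\n",
    session_id(x), nrow(x), sampling_rate(x),
    paste(channel_roles(x), collapse = ", ")
  ))
  NextMethod()
}
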