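#' Behavioral event table
#'
#' An `event_table` is a tibble with one row per referenced behavioral
#' event (columns `index`, `t_start`, `t_end`, `type`) plus the trial
#' bounds and session-level metadata (odorant, hedonics, condition) as
#' attributes. Times are seconds on the photometry clock; all recording
#' devices are assumed started simultaneously, so no cross-clock offset is
#' applied (see `time_offset` in [read_event_table()] for other rigs).
#'
#' @param t_start,t_end Numeric vectors of event start/end times (seconds).
#' @param type Event type label(s), e.g. `"hole"` (olfactory investigation)
#'   or `"edge"` (escape); recycled to the number of events.
#' @param trial_start,trial_end Trial bounds in seconds.
#' @param odorant,hedonics,condition Free-text session metadata labels.
#' @param session_id Session identifier.
#'
#' @return An `event_table` tibble, events ordered by index.
#' @export
#' @examples
#' ev <- event_table(
#'   t_start = c(10, 30), t_end = c(11.5, 30.4),
#'   trial_start = 0, trial_end = 120,
#'   odorant = "Citro", hedonics = "plea", condition = "Ctrl"
#' )
#' total_event_duration(ev)
event_table <- function(t_start = numeric(), t_end = numeric(), type = "hole",
                        trial_start, trial_end,
                        odorant = NA_character_, hedonics = NA_character_,
                        condition = NA_character_, session_id = "session") {
  if (!is.numeric(trial_start) || !is.numeric(trial_end) || trial_start >= trial_end) {
    abort_validation("trial bounds must satisfy trial_start < trial_end")
  }
  n <- length(t_start)
  if (length(t_end) != n) {
    abort_validation("t_start and t_end must have equal length")
  }
  type <- rep_len(as.character(type), n)
  if (n > 0) {
    bad <- which(!(t_start < t_end))
    if (length(bad)) {
      abort_validation(sprintf("event %d has end <= start", bad[1]))
    }
    out_of_trial <- which(t_start < trial_start | t_end > trial_end)
    if (length(out_of_trial)) {
      abort_validation(sprintf(
        "event %d lies outside trial bounds [%g, %g]",
        out_of_trial[1], trial_start, trial_end
      ))
    }
  }
  out <- tibble(
    index = seq_len(n),
    t_start = as.numeric(t_start),
    t_end = as.numeric(t_end),
    type = type
  )
  structure(
    out,
    class = c("event_table", class(out)),
    trial_start = as.numeric(trial_start),
    trial_end = as.numeric(trial_end),
    odorant = as.character(odorant),
    hedonics = as.character(hedonics),
    condition = as.character(condition),
    session_id = session_id
  )
}

#' @rdname event_table
#' @param x An `event_table`.
#' @export
trial_bounds <- function(x) {
  c(start = attr(x, "trial_start"), end = attr(x, "trial_end"))
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf(
    "<event_table> session '%s' [%g, %g] s, odorant=%s hedonics=%s condition=%s\n",
    attr(x, "session_id"), attr(x, "trial_start"), attr(x, "trial_end"),
    attr(x, "odorant"), attr(x, "hedonics"), attr(x, "condition")
  ))
  NextMethod()
}
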