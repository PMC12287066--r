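#' Select behavioral events by metadata
#'
#' Filters events across one or more sessions by event type, odorant,
#' hedonics and condition labels, then applies a per-session sequence
#' filter ("all", "first", "last", or a vector of event indices). An empty
#' filter leaves that field unrestricted; an empty result is valid.
#'
#' @param tables An [event_table()] or a list of them.
#' @param type,odorant,hedonics,condition Label filters (character vectors
#'   or `NULL` for no restriction).
#' @param sequence `"all"`, `"first"`, `"last"`, or an integer vector of
#'   within-session event positions (after metadata filtering).
#' @return A tibble with columns `session`, `index`, `t_start`, `t_end`,
#'   `type`, `odorant`, `hedonics`, `condition`, ordered by (session,
#'   index).
#' @export
#' @examples
#' ev <- event_table(
#'   t_start = c(10, 20), t_end = c(11, 21), type = c("hole", "edge"),
#'   trial_start = 0, trial_end = 120, odorant = "Citro",
#'   hedonics = "plea", condition = "Ctrl"
#' )
#' select_events(ev, type = "hole")
select_events <- function(tables, type = NULL, odorant = NULL, hedonics = NULL,
                          condition = NULL, sequence = "all") {
  if (inherits(tables, "event_table")) tables <- list(tables)
  flat <- purrr::map_dfr(tables, function(tab) {
    tibble(
      session = attr(tab, "session_id"),
      index = tab$index,
      t_start = tab$t_start,
      t_end = tab$t_end,
      type = tab$type,
      odorant = attr(tab, "odorant"),
      hedonics = attr(tab, "hedonics"),
      condition = attr(tab, "condition")
    )
  })
  if (!nrow(flat)) return(flat)
  keep_if <- function(df, col, values) {
    if (is.null(values)) df else dplyr::filter(df, .data[[col]] %in% values)
  }
  flat <- flat |>
    keep_if("type", type) |>
    keep_if("odorant", odorant) |>
    keep_if("hedonics", hedonics) |>
    keep_if("condition", condition)

  pick <- function(df) {
    if (identical(sequence, "all")) return(df)
    if (identical(sequence, "first")) return(dplyr::slice_head(df, n = 1))
    if (identical(sequence, "last")) return(dplyr::slice_tail(df, n = 1))
    if (is.numeric(sequence)) {
      return(dplyr::slice(df, intersect(as.integer(sequence), seq_len(nrow(df)))))
    }
    abort_parameter("sequence must be \"all\", \"first\", \"last\" or indices")
  }
  flat |>
    dplyr::arrange(.data$session, .data$index) |>
    dplyr::group_by(.data$session) |>
    dplyr::group_modify(~ pick(.x)) |>
    dplyr::ungroup()
}

#' Total duration of selected events
#'
#' Sum of event durations in seconds — e.g. the total odorized-hole
#' exploration time used as the behavioral index of odor hedonics. Zero
#' for an empty selection.
#'
#' @param events A tibble with `t_start` and `t_end` columns (an
#'   [event_table()] or the output of [select_events()]).
#' @return Total duration in seconds.
#' @export
total_event_duration <- function(events) {
  if (!nrow(events)) return(0)
  sum(events$t_end - events$t_start)
}

#' Extract onset-locked signal segments
#'
#' Aligns the Z-scored trace of one processed channel to the onset of each
#' selected event ("time point 0"). The onset is mapped to the nearest
#' sample at or before `t_start` (no interpolation, so no post-onset
#' information leaks into pre-onset samples); each event contributes one
#' row over a fixed window `[-pre, +post]`. Events whose window leaves the
#' recording are dropped and counted, never padded.
#'
#' @param channel A `ph_channel` from [preprocess_recording()].
#' @param events Selected events (tibble with `t_start`, and ideally
#'   `session`/`index` for provenance).
#' @param pre,post Window half-lengths in seconds (both `>= 0`).
#' @return A `ph_ensemble`: list with `rel_time` (seconds, 0 at onset),
#'   `matrix` (events x timepoints of Z-scores), `event_ids` (provenance
#'   tibble), `mean`, `sem`, and `n_dropped`.
#' @export
extract_aligned <- function(channel, events, pre = 2, post = 2) {
  if (pre < 0 || post < 0) abort_parameter("pre and post must be >= 0")
  if (!"zscore" %in% names(channel)) {
    abort_parameter("channel carries no zscore trace")
  }
  fs <- attr(channel, "sampling_rate")
  time <- channel$time
  z <- channel$zscore
  n <- length(z)
  n_pre <- as.integer(round(pre * fs))
  n_post <- as.integer(round(post * fs))
  rel_time <- seq(-n_pre, n_post) / fs

  ids <- tibble(
    session = if ("session" %in% names(events)) events$session else attr(channel, "session_id"),
    index = if ("index" %in% names(events)) events$index else seq_len(nrow(events)),
    t_start = events$t_start
  )
  rows <- list()
  kept <- integer()
  for (i in seq_len(nrow(events))) {
    onset <- findInterval(events$t_start[i], time) # nearest sample at or before
    lo <- onset - n_pre
    hi <- onset + n_post
    if (onset < 1L || lo < 1L || hi > n) next
    rows[[length(rows) + 1L]] <- z[lo:hi]
    kept <- c(kept, i)
  }
  if (!length(rows)) {
    abort_validation(sprintf(
      "all %d events dropped: window [-%g, +%g] s leaves the recording",
      nrow(events), pre, post
    ))
  }
  mat <- do.call(rbind, rows)
  new_ensemble(rel_time, mat, ids[kept, , drop = FALSE],
               n_dropped = nrow(events) - length(kept))
}

new_ensemble <- function(rel_time, mat, event_ids, n_dropped = 0L) {
  m <- colMeans(mat)
  s <- if (nrow(mat) > 1L) apply(mat, 2, sd) / sqrt(nrow(mat)) else rep(0, ncol(mat))
  structure(
    list(
      rel_time = rel_time, matrix = mat, event_ids = event_ids,
      mean = m, sem = s, n_dropped = as.integer(n_dropped)
    ),
    class = "ph_ensemble"
  )
}

#' @export
print.ph_ensemble <- function(x, ...) {
  cat(sprintf(
    "<ph_ensemble> %d events x %d timepoints, rel_time [%g, %g] s (%d dropped)\n",
    nrow(x$matrix), ncol(x$matrix), min(x$rel_time), max(x$rel_time), x$n_dropped
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ph_ensemble <- function(x, ...) {
  events <- nrow(x$matrix)
  tibble(
    session = rep(x$event_ids$session, each = length(x$rel_time)),
    index = rep(x$event_ids$index, each = length(x$rel_time)),
    rel_time = rep(x$rel_time, times = events),
    zscore = as.vector(t(x$matrix))
  )
}

#' @exportS3Method generics::glance
glance.ph_ensemble <- function(x, ...) {
  tibble(
    n_events = nrow(x$matrix),
    n_timepoints = ncol(x$matrix),
    n_dropped = x$n_dropped,
    rel_time_min = min(x$rel_time),
    rel_time_max = max(x$rel_time),
    peak_time = x$rel_time[which.max(x$mean)],
    peak_zscore = max(x$mean)
  )
}

#' Export an ensemble's mean and SEM as a tibble
#'
#' @param x A `ph_ensemble`.
#' @return Tibble with `rel_time`, `mean`, `sem`.
#' @export
ensemble_mean <- function(x) {
  tibble(rel_time = x$rel_time, mean = x$mean, sem = x$sem)
}

#' Average aligned ensembles across sessions
#'
#' Pools onset-locked ensembles from several sessions/animals on a shared
#' relative-time grid. `level = "event"` pools all event rows (sessions
#' with more events weigh more); `level = "animal"` first averages within
#' each session, then across sessions (one row per animal). Group averages
#' can legitimately differ between the two when event counts are unequal.
#'
#' @param ensembles List of `ph_ensemble` objects with identical
#'   `rel_time` grids.
#' @param level `"event"` or `"animal"`.
#' @return A `ph_ensemble`.
#' @export
ensemble_average <- function(ensembles, level = c("event", "animal")) {
  level <- match.arg(level)
  if (inherits(ensembles, "ph_ensemble")) ensembles <- list(ensembles)
  grid <- ensembles[[1]]$rel_time
  same <- purrr::map_lgl(ensembles, ~ isTRUE(all.equal(.x$rel_time, grid)))
  if (!all(same)) {
    abort_validation("ensembles have mismatched rel_time grids")
  }
  if (level == "event") {
    mat <- do.call(rbind, purrr::map(ensembles, "matrix"))
    ids <- purrr::map_dfr(ensembles, "event_ids")
  } else {
    mat <- do.call(rbind, purrr::map(ensembles, ~ colMeans(.x$matrix)))
    ids <- tibble(
      session = purrr::map_chr(ensembles, ~ as.character(.x$event_ids$session[1])),
      index = NA_integer_,
      t_start = NA_real_
    )
  }
  new_ensemble(grid, mat, ids,
               n_dropped = sum(purrr::map_int(ensembles, "n_dropped")))
}
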