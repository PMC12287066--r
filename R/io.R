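#' Read a demodulated photometry export
#'
#' Reads a delimited-text photometry export (one header row, a time column
#' in seconds and one column per demodulated channel) into a
#' [ph_recording()]. The sampling rate is always inferred from the median
#' time step and never trusted from file metadata; a non-uniform time base
#' beyond `grid_tol` is an error.
#'
#' @param path Path to a CSV/TSV file.
#' @param channel_map Named character vector mapping channel roles
#'   (`sensor_465`, `sensor_565`, `isosbestic_405`) to column names in the
#'   file. Every mapped column must be present.
#' @param time_col Name of the time column (seconds).
#' @param grid_tol Relative tolerance on time-step uniformity.
#' @param session_id Session identifier; defaults to the file name.
#'
#' @return A [ph_recording()].
#' @export
read_photometry <- function(path,
                            channel_map = c(
                              sensor_465 = "sensor_465",
                              sensor_565 = "sensor_565",
                              isosbestic_405 = "isosbestic_405"
                            ),
                            time_col = "time",
                            grid_tol = 1e-6,
                            session_id = NULL) {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  df <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab")) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  missing <- setdiff(c(time_col, unname(channel_map)), names(df))
  if (length(missing)) {
    abort_format(paste0(
      "missing column(s) in ", basename(path), ": ",
      paste(missing, collapse = ", ")
    ))
  }
  channels <- purrr::map(unname(channel_map), ~ df[[.x]])
  names(channels) <- names(channel_map)
  ph_recording(
    time = df[[time_col]],
    channels = channels,
    session_id = session_id %||% basename(path),
    grid_tol = grid_tol
  )
}

#' Write a photometry recording as delimited text
#'
#' @param rec A [ph_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_photometry <- function(rec, path) {
  readr::write_csv(as_tibble(rec), path)
  invisible(path)
}

# event spreadsheets ----------------------------------------------------------

#' Read a behavioral event spreadsheet
#'
#' Reads the one-row-per-session spreadsheet convention used to reference
#' behavioral events retrospectively: columns `start`/`end` hold the trial
#' bounds, matched pairs `start1`/`end1`, `start2`/`end2`, ... hold the
#' referenced events in index order, and `odorant`, `hedonics`, `condition`
#' carry session metadata verbatim (e.g. "Citro", "plea", "Ctrl"). A
#' session-level `type` column (default `"hole"`) or per-event `type1`,
#' `type2`, ... columns label the event type. Headers are matched
#' case-insensitively. Both CSV and xlsx are accepted.
#'
#' @param path Path to a CSV or xlsx file.
#' @param sheet Sheet index or name (xlsx only).
#' @param time_offset Constant offset (seconds) added to every time in the
#'   sheet, for rigs whose behavioral clock is not started with the
#'   photometry console. Default 0: all devices start simultaneously.
#' @param session_id Session identifier; defaults to the file name.
#'
#' @return An [event_table()] with events in suffix order.
#' @export
read_event_table <- function(path, sheet = 1, time_offset = 0, session_id = NULL) {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("xlsx", "xls")) {
    readxl::read_excel(path, sheet = sheet)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (nrow(df) < 1L) abort_format("event sheet is empty")
  row <- df[1, , drop = FALSE]
  names(row) <- tolower(names(row))

  get_num <- function(nm) {
    v <- suppressWarnings(as.numeric(row[[nm]]))
    if (is.na(v)) abort_format(paste0("column '", nm, "' is not numeric"))
    v
  }
  if (!"start" %in% names(row) || !"end" %in% names(row)) {
    abort_format("event sheet must contain 'start' and 'end' columns")
  }

  start_idx <- as.integer(sub("^start", "", grep("^start[0-9]+$", names(row), value = TRUE)))
  end_idx <- as.integer(sub("^end", "", grep("^end[0-9]+$", names(row), value = TRUE)))
  unmatched <- sort(c(setdiff(start_idx, end_idx), setdiff(end_idx, start_idx)))
  if (length(unmatched)) {
    abort_format(sprintf(
      "unmatched start/end pair for event index %d", unmatched[1]
    ))
  }
  idx <- sort(start_idx)
  # contiguity of suffixes is not required, but order is: events come out in
  # ascending suffix order and are re-indexed 1..N
  t_start <- vapply(idx, function(i) get_num(paste0("start", i)), numeric(1)) + time_offset
  t_end <- vapply(idx, function(i) get_num(paste0("end", i)), numeric(1)) + time_offset

  meta <- function(nm, default = NA_character_) {
    if (nm %in% names(row)) as.character(row[[nm]]) else default
  }
  type <- if (length(idx)) {
    per_event <- paste0("type", idx)
    if (all(per_event %in% names(row))) {
      vapply(per_event, function(nm) as.character(row[[nm]]), character(1))
    } else {
      meta("type", "hole")
    }
  } else {
    character()
  }

  event_table(
    t_start = t_start, t_end = t_end, type = type,
    trial_start = get_num("start") + time_offset,
    trial_end = get_num("end") + time_offset,
    odorant = meta("odorant"), hedonics = meta("hedonics"),
    condition = meta("condition"),
    session_id = session_id %||% meta("session", basename(path))
  )
}

#' Write an event table in the spreadsheet convention
#'
#' @param events An [event_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  row <- tibble(
    session = attr(events, "session_id"),
    odorant = attr(events, "odorant"),
    hedonics = attr(events, "hedonics"),
    condition = attr(events, "condition"),
    start = attr(events, "trial_start"),
    end = attr(events, "trial_end")
  )
  for (i in seq_len(nrow(events))) {
    row[[paste0("start", i)]] <- events$t_start[i]
    row[[paste0("end", i)]] <- events$t_end[i]
    row[[paste0("type", i)]] <- events$type[i]
  }
  readr::write_csv(row, path)
  invisible(path)
}

# tracking tables -------------------------------------------------------------

#' Read a frame-indexed tracking table
#'
#' Reads a CSV with columns `frame`, `x`, `y` (case-insensitive) into a
#' [tracking_table()]. Rows with missing coordinates are retained as gaps.
#'
#' @param path Path to a CSV file.
#' @param frame_rate Video frame rate in Hz.
#' @param reference_points List with `p1` and `p2` pixel pairs (bottom-left
#'   and bottom-right board corners).
#' @param session_id Session identifier; defaults to the file name.
#'
#' @return A [tracking_table()].
#' @export
read_tracking <- function(path, frame_rate, reference_points, session_id = NULL) {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(df) <- tolower(names(df))
  missing <- setdiff(c("frame", "x", "y"), names(df))
  if (length(missing)) {
    abort_format(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  tracking_table(
    frame = df$frame, x = df$x, y = df$y,
    frame_rate = frame_rate, reference_points = reference_points,
    session_id = session_id %||% basename(path)
  )
}

#' Read DeepLabCut-style multi-header tracking output
#'
#' Adapter for the three-header-row CSV layout (scorer / bodyparts /
#' coords) produced by markerless pose estimation tools: extracts the x/y
#' columns of one bodypart, optionally masking low-likelihood detections
#' as gaps, and returns the same [tracking_table()] as [read_tracking()].
#'
#' @param path Path to the multi-header CSV.
#' @param bodypart Bodypart name to extract; default: the first one.
#' @param likelihood_min If the bodypart has a `likelihood` column,
#'   detections below this value become gaps (NA). `NULL` keeps all.
#' @inheritParams read_tracking
#' @return A [tracking_table()].
#' @export
read_tracking_dlc <- function(path, frame_rate, reference_points,
                              bodypart = NULL, likelihood_min = NULL,
                              session_id = NULL) {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_names = FALSE, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) < 4L) abort_format("not a multi-header tracking file")
  parts <- as.character(unlist(raw[2, -1]))
  coords <- tolower(as.character(unlist(raw[3, -1])))
  body <- raw[-(1:3), , drop = FALSE]
  frame <- suppressWarnings(as.integer(unlist(body[, 1])))
  bodypart <- bodypart %||% parts[1]
  sel <- which(parts == bodypart)
  if (!length(sel)) abort_format(paste0("bodypart not found: ", bodypart))
  col_for <- function(what) {
    j <- sel[coords[sel] == what]
    if (!length(j)) return(NULL)
    suppressWarnings(as.numeric(unlist(body[, j[1] + 1])))
  }
  x <- col_for("x")
  y <- col_for("y")
  if (is.null(x) || is.null(y)) abort_format("bodypart lacks x/y coordinate columns")
  lik <- col_for("likelihood")
  if (!is.null(lik) && !is.null(likelihood_min)) {
    drop <- !is.na(lik) & lik < likelihood_min
    x[drop] <- NA_real_
    y[drop] <- NA_real_
  }
  tracking_table(
    frame = frame, x = x, y = y,
    frame_rate = frame_rate, reference_points = reference_points,
    session_id = session_id %||% basename(path)
  )
}

#' Write a tracking table as CSV
#'
#' @param track A [tracking_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(track, path) {
  readr::write_csv(as_tibble(track), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
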