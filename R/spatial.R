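#' Board-normalized coordinates from pixel tracking
#'
#' Maps the pixel trajectory into board-normalized coordinates in
#' \eqn{[0,1]^2} using the two reference points placed at the bottom
#' corners of the (square) board: P1 (bottom-left) maps to (0, 0), P2
#' (bottom-right) to (1, 0), and y increases upward. Pixel coordinates
#' are assumed image-style (y increasing downward). The transform is
#' affine (translation + rotation + uniform scale), so it is invariant to
#' rigid motions of the camera frame and aligns trajectories across
#' videos. Points outside the unit square are clamped and flagged.
#'
#' @param track A [tracking_table()] carrying P1/P2 reference points.
#' @return A `ph_traj` tibble with columns `frame`, `time`, `x`, `y`
#'   (normalized), `gap`, `clamped`, plus the frame rate and board frame
#'   as attributes.
#' @export
board_transform <- function(track) {
  rp <- attr(track, "reference_points")
  p1 <- rp$p1
  p2 <- rp$p2
  d <- p2 - p1
  scale <- sqrt(sum(d^2))
  if (scale == 0) abort_validation("reference points P1 and P2 coincide")
  e1 <- d / scale
  e2 <- c(e1[2], -e1[1]) # board "up" in image coordinates (pixel y down)

  dx <- track$x - p1[1]
  dy <- track$y - p1[2]
  u <- (dx * e1[1] + dy * e1[2]) / scale
  v <- (dx * e2[1] + dy * e2[2]) / scale
  gap <- is.na(u) | is.na(v)
  clamped <- !gap & (u < 0 | u > 1 | v < 0 | v > 1)
  out <- tibble(
    frame = track$frame,
    time = track$frame / frame_rate(track),
    x = pmin(pmax(u, 0), 1),
    y = pmin(pmax(v, 0), 1),
    gap = gap,
    clamped = clamped
  )
  structure(
    out,
    class = c("ph_traj", class(out)),
    frame_rate = frame_rate(track),
    board = list(p1 = p1, p2 = p2, scale = scale, e1 = e1, e2 = e2),
    session_id = attr(track, "session_id")
  )
}

# zone specifications ---------------------------------------------------------

#' Behavioral zones in board-normalized coordinates
#'
#' `zone_disc()` describes a circular zone such as the odorized hole;
#' `zone_edge()` describes the border band of the board used to define
#' escape events (head over the edge). Defaults: hole at the board center
#' with radius 0.08, edge band of width 0.1, both in normalized units.
#'
#' @param center Disc center `c(x, y)` in normalized coordinates.
#' @param radius Disc radius in normalized units.
#' @param label Event type label attached to detected events.
#' @return A `ph_zone` list.
#' @export
zone_disc <- function(center = c(0.5, 0.5), radius = 0.08, label = "hole") {
  if (radius <= 0) abort_parameter("radius must be > 0")
  structure(list(kind = "disc", center = center, radius = radius, label = label),
            class = "ph_zone")
}

#' @rdname zone_disc
#' @param width Border band width in normalized units.
#' @export
zone_edge <- function(width = 0.1, label = "edge") {
  if (width <= 0 || width >= 0.5) abort_parameter("width must be in (0, 0.5)")
  structure(list(kind = "edge", width = width, label = label), class = "ph_zone")
}

#' Test which trajectory points fall inside a zone
#'
#' @param traj A `ph_traj` (or tibble with normalized `x`, `y`).
#' @param zone A `ph_zone`.
#' @return Logical vector (NA for gap points).
#' @export
in_zone <- function(traj, zone) {
  x <- traj$x
  y <- traj$y
  inside <- switch(zone$kind,
    disc = (x - zone$center[1])^2 + (y - zone$center[2])^2 <= zone$radius^2,
    edge = x < zone$width | x > 1 - zone$width | y < zone$width | y > 1 - zone$width,
    abort_parameter(paste0("unknown zone kind: ", zone$kind))
  )
  if ("gap" %in% names(traj)) inside[traj$gap] <- NA
  inside
}

#' Detect zone-entry events from a trajectory
#'
#' Automated stand-in for manual event referencing: maximal runs of
#' consecutive in-zone frames lasting at least `min_duration` become
#' events with frame-accurate start/end times (`[first_frame / rate,
#' (last_frame + 1) / rate)`). Tracking gaps and missing frames break
#' runs; a single out-of-zone frame separates two events.
#'
#' @param traj A `ph_traj` from [board_transform()].
#' @param zone A `ph_zone`.
#' @param min_duration Minimum event duration in seconds.
#' @param rate Frame rate in Hz; default from the trajectory.
#' @return Tibble with `index`, `t_start`, `t_end`, `type`.
#' @export
detect_zone_events <- function(traj, zone, min_duration = 0, rate = NULL) {
  rate <- rate %||% attr(traj, "frame_rate")
  if (!nrow(traj)) {
    return(tibble(index = integer(), t_start = numeric(), t_end = numeric(),
                  type = character()))
  }
  inside <- in_zone(traj, zone)
  inside[is.na(inside)] <- FALSE
  if (!any(inside)) {
    return(tibble(index = integer(), t_start = numeric(), t_end = numeric(),
                  type = character()))
  }
  # break runs where the frame index jumps (missing detections)
  contiguous <- c(TRUE, diff(traj$frame) == 1L)
  run_id <- cumsum(!contiguous | inside != dplyr::lag(inside, default = !inside[1]))
  runs <- tibble(frame = traj$frame, inside = inside, run = run_id) |>
    dplyr::filter(.data$inside) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      t_start = min(.data$frame) / rate,
      t_end = (max(.data$frame) + 1L) / rate,
      .groups = "drop"
    ) |>
    dplyr::filter(.data$t_end - .data$t_start >= min_duration - 1e-9) |>
    dplyr::arrange(.data$t_start)
  tibble(
    index = seq_len(nrow(runs)),
    t_start = runs$t_start,
    t_end = runs$t_end,
    type = zone$label
  )
}

# maps ------------------------------------------------------------------------

bin_index <- function(coord, grid_n) {
  # half-open bins, top/right edge closed: every point in [0,1] gets one bin
  pmin(as.integer(floor(coord * grid_n)) + 1L, grid_n)
}

#' Occupancy-time presence map
#'
#' Accumulates the time spent in each bin of an `grid_n` x `grid_n` grid
#' over the normalized board. Gap frames contribute nothing, so total
#' occupancy equals (tracked non-gap frames) / frame_rate.
#'
#' @param traj A `ph_traj`.
#' @param grid_n Grid size per axis (>= 2).
#' @param rate Frame rate in Hz; default from the trajectory.
#' @return Numeric `grid_n` x `grid_n` matrix of seconds; `[i, j]` is the
#'   i-th x bin and j-th y bin (bottom row j = 1).
#' @export
presence_map <- function(traj, grid_n = 32, rate = NULL) {
  if (grid_n < 2) abort_parameter("grid_n must be >= 2")
  rate <- rate %||% attr(traj, "frame_rate")
  occ <- matrix(0, grid_n, grid_n)
  ok <- !traj$gap
  if (any(ok)) {
    ix <- bin_index(traj$x[ok], grid_n)
    iy <- bin_index(traj$y[ok], grid_n)
    counts <- table(factor(ix, levels = 1:grid_n), factor(iy, levels = 1:grid_n))
    occ <- occ + as.numeric(counts) / rate
    dim(occ) <- c(grid_n, grid_n)
  }
  occ
}

#' Trajectory-coupled photometry signal maps
#'
#' Combines the trajectory with a processed channel's Z-score trace:
#' every photometry sample is assigned to the spatial bin of its
#' temporally nearest tracking frame. `signal_sum` accumulates Z-scores
#' per bin; `signal_norm` is the occupancy-normalized map — the mean
#' Z-score per sample in the bin, which is independent of how long the
#' animal dwelt there. Unvisited bins are NA, never zero-filled.
#'
#' @param traj A `ph_traj`.
#' @param channel A `ph_channel` with a `zscore` trace.
#' @param grid_n Grid size per axis.
#' @param rate Frame rate in Hz; default from the trajectory.
#' @return A `ph_maps` list with `occupancy`, `signal_sum`,
#'   `signal_norm`, `sample_count`, `visited` matrices and `grid_n`.
#' @export
signal_maps <- function(traj, channel, grid_n = 32, rate = NULL) {
  rate <- rate %||% attr(traj, "frame_rate")
  t_sig <- channel$time
  t_frames <- traj$frame / rate
  overlap <- t_sig >= min(t_frames) - 0.5 / rate & t_sig <= max(t_frames) + 0.5 / rate
  if (!any(overlap)) {
    abort_validation("photometry and tracking time spans do not overlap")
  }
  # nearest tracking row for each photometry sample
  j <- findInterval(t_sig, t_frames)
  j_lo <- pmax(j, 1L)
  j_hi <- pmin(j + 1L, nrow(traj))
  nearer_hi <- abs(t_frames[j_hi] - t_sig) < abs(t_sig - t_frames[j_lo])
  idx <- ifelse(nearer_hi, j_hi, j_lo)

  keep <- overlap & !traj$gap[idx]
  occ <- presence_map(traj, grid_n, rate)
  sig <- matrix(0, grid_n, grid_n)
  cnt <- matrix(0L, grid_n, grid_n)
  if (any(keep)) {
    ix <- bin_index(traj$x[idx[keep]], grid_n)
    iy <- bin_index(traj$y[idx[keep]], grid_n)
    z <- channel$zscore[keep]
    lin <- (iy - 1L) * grid_n + ix
    sig[] <- as.numeric(rowsum(c(z, rep(0, grid_n^2)),
                               c(lin, seq_len(grid_n^2)))[, 1])
    cnt[] <- tabulate(lin, nbins = grid_n^2)
  }
  visited <- occ > 0
  norm <- matrix(NA_real_, grid_n, grid_n)
  norm[visited & cnt > 0] <- sig[visited & cnt > 0] / cnt[visited & cnt > 0]
  structure(
    list(
      occupancy = occ, signal_sum = sig, signal_norm = norm,
      sample_count = cnt, visited = visited, grid_n = grid_n,
      n_samples_dropped = sum(!keep)
    ),
    class = "ph_maps"
  )
}

#' @export
print.ph_maps <- function(x, ...) {
  cat(sprintf(
    "<ph_maps> %dx%d grid: %.4g s occupancy over %d visited bins\n",
    x$grid_n, x$grid_n, sum(x$occupancy), sum(x$visited)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ph_maps <- function(x, ...) {
  g <- x$grid_n
  mids <- (seq_len(g) - 0.5) / g
  tibble(
    x_bin = rep(seq_len(g), times = g),
    y_bin = rep(seq_len(g), each = g),
    x_mid = rep(mids, times = g),
    y_mid = rep(mids, each = g),
    occupancy = as.vector(x$occupancy),
    signal_sum = as.vector(x$signal_sum),
    signal_norm = as.vector(x$signal_norm),
    visited = as.vector(x$visited)
  )
}

#' Write spatial maps as CSV matrices
#'
#' Writes `occupancy`, `signal_sum` and `signal_norm` as plain CSV
#' matrices (rows = y bins from bottom, columns = x bins).
#'
#' @param maps A `ph_maps`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Paths of the written files, invisibly.
#' @export
write_maps <- function(maps, dir, prefix = "map") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in c("occupancy", "signal_sum", "signal_norm")) {
    p <- file.path(dir, paste0(prefix, "_", nm, ".csv"))
    utils::write.table(t(maps[[nm]]), p, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
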