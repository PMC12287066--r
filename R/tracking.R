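#' Frame-indexed tracking table
#'
#' A `tracking_table` holds the x/y pixel coordinates of the tracked animal
#' indexed by video frame (0-based), with the frame rate and the two board
#' reference points P1/P2 (bottom corners of the board) as attributes. Rows
#' with missing coordinates are retained as gaps and counted; missing frame
#' indices are allowed and also treated as gaps downstream.
#'
#' @param frame Integer vector of 0-based frame indices, strictly increasing.
#' @param x,y Pixel coordinates (NA marks a missed detection).
#' @param frame_rate Video frame rate in Hz.
#' @param reference_points List with elements `p1` and `p2`, each an (x, y)
#'   pixel pair marking the bottom-left and bottom-right board corners.
#' @param session_id Session identifier.
#'
#' @return A `tracking_table` tibble with columns `frame`, `x`, `y`.
#' @export
tracking_table <- function(frame, x, y, frame_rate,
                           reference_points = list(p1 = c(0, 1), p2 = c(1, 1)),
                           session_id = "session") {
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    abort_parameter("`frame_rate` must be > 0")
  }
  frame <- as.integer(frame)
  if (any(frame < 0)) {
    abort_format("negative frame index")
  }
  if (anyDuplicated(frame)) {
    abort_format(sprintf("duplicate frame index: %d", frame[duplicated(frame)][1]))
  }
  if (is.unsorted(frame, strictly = TRUE)) {
    abort_format("frame indices must be strictly increasing")
  }
  p1 <- as.numeric(reference_points$p1)
  p2 <- as.numeric(reference_points$p2)
  if (length(p1) != 2L || length(p2) != 2L) {
    abort_parameter("reference points p1/p2 must each be an (x, y) pair")
  }
  if (identical(p1, p2)) {
    abort_validation("reference points P1 and P2 coincide")
  }
  out <- tibble(frame = frame, x = as.numeric(x), y = as.numeric(y))
  structure(
    out,
    class = c("tracking_table", class(out)),
    frame_rate = as.numeric(frame_rate),
    reference_points = list(p1 = p1, p2 = p2),
    n_gaps = sum(is.na(out$x) | is.na(out$y)),
    session_id = session_id
  )
}

#' @rdname tracking_table
#' @param track A `tracking_table`.
#' @export
frame_rate <- function(track) attr(track, "frame_rate")

#' @rdname tracking_table
#' @export
n_gaps <- function(track) attr(track, "n_gaps")

#' @export
print.tracking_table <- function(x, ...) {
  cat(sprintf(
    "<tracking_table> %d frames at %g Hz (%d gaps), P1=(%g,%g) P2=(%g,%g)\n",
    nrow(x), frame_rate(x), n_gaps(x),
    attr(x, "reference_points")$p1[1], attr(x, "reference_points")$p1[2],
    attr(x, "reference_points")$p2[1], attr(x, "reference_points")$p2[2]
  ))
  NextMethod()
}
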