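#' Eye-position trace
#'
#' Container for a contiguous two-dimensional gaze trace sampled at a fixed
#' frame rate, the substrate of all drift analyses in this package. Positions
#' are in arcminutes with x positive rightward and y positive upward; gaps
#' (tracking failures) must be represented by splitting into separate traces
#' before analysis, so every trace is contiguous by construction.
#'
#' @param positions numeric matrix (or two-column data frame) of x/y gaze
#'   positions in arcminutes, one row per video frame.
#' @param frame_rate sampling rate in Hz (default 60, the scanner frame rate).
#' @param valid_mask optional logical vector flagging frames with usable
#'   tracking; defaults to all `TRUE`. Positions must be finite wherever the
#'   mask is `TRUE`.
#' @param trace_id opaque label carried through QC reports and result tables.
#'
#' @return an object of class `eye_trace`: a list with elements `positions`
#'   (n x 2 matrix), `frame_rate`, `valid_mask`, and `trace_id`.
#' @examples
#' tr <- eye_trace(cbind(x = c(0, 1, 2), y = c(0, 0, 1)))
#' n_frames(tr)
#' @export
eye_trace <- function(positions, frame_rate = 60, valid_mask = NULL,
                      trace_id = "trace") {
  pos <- as_positions(positions)
  n <- nrow(pos)
  if (n < 2L) {
    stop("an eye trace needs at least 2 frames", call. = FALSE)
  }
  stopifnot_scalar(frame_rate, "frame_rate")
  if (frame_rate <= 0) {
    stop("`frame_rate` must be positive", call. = FALSE)
  }
  if (is.null(valid_mask)) {
    valid_mask <- rep(TRUE, n)
  }
  valid_mask <- as.logical(valid_mask)
  if (length(valid_mask) != n || anyNA(valid_mask)) {
    stop("`valid_mask` must be a logical vector with one entry per frame",
         call. = FALSE)
  }
  if (any(!is.finite(pos[valid_mask, ]))) {
    stop("positions must be finite wherever `valid_mask` is TRUE",
         call. = FALSE)
  }
  structure(
    list(positions = pos, frame_rate = frame_rate,
         valid_mask = valid_mask, trace_id = as.character(trace_id)),
    class = "eye_trace"
  )
}

#' @export
print.eye_trace <- function(x, ...) {
  cat(sprintf("<eye_trace '%s': %d frames @ %g Hz (%.0f ms), %d valid>\n",
              x$trace_id, n_frames(x), x$frame_rate,
              1000 * (n_frames(x) - 1) / x$frame_rate, sum(x$valid_mask)))
  invisible(x)
}

#' Number of frames in a trace
#' @param trace an [eye_trace()].
#' @return integer frame count.
#' @export
n_frames <- function(trace) {
  nrow(as_positions(trace))
}

#' @export
as.data.frame.eye_trace <- function(x, ...) {
  n <- n_frames(x)
  data.frame(
    frame = seq_len(n),
    t_s = (seq_len(n) - 1) / x$frame_rate,
    x_arcmin = x$positions[, 1],
    y_arcmin = x$positions[, 2],
    valid = as.integer(x$valid_mask)
  )
}

# Per-frame displacement vectors (n-1 x 2).
frame_steps <- function(trace) {
  pos <- as_positions(trace)
  pos[-1L, , drop = FALSE] - pos[-nrow(pos), , drop = FALSE]
}

# Per-frame speeds in arcmin/s (length n-1).
frame_speeds <- function(trace, frame_rate = frame_rate_of(trace)) {
  st <- frame_steps(trace)
  sqrt(rowSums(st^2)) * frame_rate
}
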