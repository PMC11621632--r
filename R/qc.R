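# Quality-control filters: delivery-accuracy screening, microsaccade
# detection, and trace/trial-level exclusion. Filtering is removal-only:
# retained traces are never modified.

#' Stimulus-delivery accuracy of one presentation
#'
#' Summarises how far the delivered stimulus fell from its targeted retinal
#' location over the presentation frames, and screens against a threshold
#' (0.9 arcmin in the study). The default statistic is the total SD of the
#' 2-D misdelivery vector, `sqrt(var(err_x) + var(err_y))`, which measures
#' spread about the mean error: a constant delivery bias contributes
#' nothing, only frame-to-frame scatter does. `method = "magnitude"` instead
#' takes the SD of the per-frame Euclidean misdelivery magnitudes.
#'
#' @param record a [inject_delivery_jitter()] `delivery_record`, or any list
#'   with `targeted`, `delivered`, `presentation_mask`.
#' @param threshold pass/fail criterion on the SD, arcmin.
#' @param method `"vector"` (default) or `"magnitude"`; see Details.
#' @return list with `delivery_sd` (arcmin) and `pass` (TRUE iff
#'   `delivery_sd <= threshold`).
#' @export
delivery_quality <- function(record, threshold = 0.9,
                             method = c("vector", "magnitude")) {
  method <- match.arg(method)
  mask <- record$presentation_mask
  if (sum(mask) < 2L) {
    stop("delivery record needs at least 2 presentation frames",
         call. = FALSE)
  }
  err <- record$delivered[mask, , drop = FALSE] -
    record$targeted[mask, , drop = FALSE]
  if (any(!is.finite(err))) {
    stop("non-finite delivery positions inside the presentation mask",
         call. = FALSE)
  }
  delivery_sd <- switch(
    method,
    vector = sqrt(stats::var(err[, 1L]) + stats::var(err[, 2L])),
    magnitude = stats::sd(sqrt(rowSums(err^2)))
  )
  list(delivery_sd = delivery_sd, pass = delivery_sd <= threshold)
}

#' Trial-level exclusion by majority delivery failure
#'
#' A trial is removed when strictly more than half of its presentations fail
#' the delivery-accuracy screen.
#'
#' @param pass logical vector of per-presentation pass flags (or a list of
#'   [delivery_quality()] results).
#' @return TRUE if the trial should be removed.
#' @export
remove_trial_if_majority_fail <- function(pass) {
  if (is.list(pass)) {
    pass <- vapply(pass, `[[`, logical(1L), "pass")
  }
  if (length(pass) == 0L) stop("no QC reports supplied", call. = FALSE)
  sum(!pass) > length(pass) / 2
}

#' Detect microsaccades by a speed threshold
#'
#' Marks ballistic segments: runs of at least `min_duration_frames`
#' consecutive frame-to-frame speeds above `speed_threshold` become events,
#' padded by one frame on each side and merged when the padding makes them
#' touch. The default threshold of 180 arcmin/s (3 deg/s) sits well above
#' drift speeds but far below microsaccadic peak speeds, so drift-only
#' traces yield essentially no events while injected ballistic segments are
#' recovered reliably.
#'
#' @param trace an [eye_trace()].
#' @param speed_threshold arcmin/s.
#' @param min_duration_frames minimum run length in frames.
#' @return data frame with columns `onset_frame`, `offset_frame` (frame
#'   indices bounding each event, inclusive); zero rows when no event.
#' @export
detect_microsaccades <- function(trace, speed_threshold = 180,
                                 min_duration_frames = 1L) {
  stopifnot(inherits(trace, "eye_trace"))
  sp <- frame_speeds(trace)
  over <- sp > speed_threshold
  runs <- rle(over)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_duration_frames
  if (!any(keep)) {
    return(data.frame(onset_frame = integer(0), offset_frame = integer(0)))
  }
  n <- n_frames(trace)
  # speed index i spans frames i..i+1; pad one frame on each side
  onset <- pmax(starts[keep] - 1L, 1L)
  offset <- pmin(ends[keep] + 1L + 1L, n)
  # merge events whose padded extents touch or overlap
  o <- order(onset)
  onset <- onset[o]
  offset <- offset[o]
  merged_on <- onset[1L]
  merged_off <- offset[1L]
  if (length(onset) > 1L) {
    for (i in seq(2L, length(onset))) {
      if (onset[i] <= merged_off[length(merged_off)] + 1L) {
        merged_off[length(merged_off)] <-
          max(merged_off[length(merged_off)], offset[i])
      } else {
        merged_on <- c(merged_on, onset[i])
        merged_off <- c(merged_off, offset[i])
      }
    }
  }
  data.frame(onset_frame = merged_on, offset_frame = merged_off)
}

#' QC report for one presentation
#'
#' Bundles the delivery screen and the microsaccade scan for one trace, in
#' the per-presentation layout the pipeline exports.
#'
#' @param trace an [eye_trace()].
#' @param record optional `delivery_record` for the presentation; when
#'   absent, delivery fields are `NA` and the delivery screen passes.
#' @param delivery_threshold arcmin.
#' @param speed_threshold,min_duration_frames microsaccade-detector settings.
#' @param delivery_method passed to [delivery_quality()].
#' @return list of class `qc_report` with `trace_id`, `delivery_sd`,
#'   `delivery_pass`, `saccade_events`, `retained`.
#' @export
qc_report <- function(trace, record = NULL, delivery_threshold = 0.9,
                      speed_threshold = 180, min_duration_frames = 1L,
                      delivery_method = "vector") {
  if (is.null(record)) {
    delivery_sd <- NA_real_
    delivery_pass <- TRUE
  } else {
    dq <- delivery_quality(record, delivery_threshold,
                           method = delivery_method)
    delivery_sd <- dq$delivery_sd
    delivery_pass <- dq$pass
  }
  ev <- detect_microsaccades(trace, speed_threshold, min_duration_frames)
  structure(
    list(trace_id = trace$trace_id, delivery_sd = delivery_sd,
         delivery_pass = delivery_pass, saccade_events = ev,
         retained = delivery_pass && nrow(ev) == 0L),
    class = "qc_report"
  )
}

#' @export
as.data.frame.qc_report <- function(x, ...) {
  data.frame(trace_id = x$trace_id, delivery_sd = x$delivery_sd,
             delivery_pass = x$delivery_pass,
             n_saccades = nrow(x$saccade_events), retained = x$retained)
}

#' Drop traces that fail QC
#'
#' Applies the removal-only contract: any trace with at least one detected
#' microsaccade is dropped whole (never excised and spliced, which would
#' bias the random-walk statistics), as is any trace whose presentation
#' failed the delivery screen. Retained traces are returned unmodified.
#'
#' @param traces list of [eye_trace()] objects.
#' @param reports list of [qc_report()] objects aligned with `traces`.
#' @return the retained subset of `traces` (possibly empty).
#' @export
filter_traces <- function(traces, reports) {
  if (length(traces) != length(reports)) {
    stop("`traces` and `reports` must be aligned", call. = FALSE)
  }
  keep <- vapply(reports, `[[`, logical(1L), "retained")
  traces[keep]
}
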