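# Tabular I/O: trace CSVs, walk-library serialisation, result tables, and
# configuration files.

#' Read eye traces from CSV
#'
#' Reads a trace file with columns `frame` (1-based integer), `t_s`
#' (seconds), `x_arcmin`, `y_arcmin`, `valid` (0/1). Because every analysis
#' assumes contiguous saccade-free samples, the file is split into separate
#' traces wherever the frame numbering jumps or a run of invalid frames
#' intervenes; a warning reports each split. Rows must be sorted by frame;
#' positions may be NA only on invalid frames.
#'
#' @param path CSV file path.
#' @param frame_rate Hz (the `t_s` column is informational; timing comes
#'   from `frame` and `frame_rate`).
#' @param min_frames segments shorter than this are dropped (default 8, the
#'   minimum fittable length).
#' @return list of [eye_trace()] objects (possibly length 1).
#' @export
read_trace_csv <- function(path, frame_rate = 60, min_frames = 8L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) stop("empty trace file: ", path, call. = FALSE)
  need <- c("frame", "x_arcmin", "y_arcmin")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("trace CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$valid)) df$valid <- 1L
  if (is.unsorted(df$frame, strictly = TRUE)) {
    stop("`frame` must be strictly increasing in ", path, call. = FALSE)
  }
  bad <- which(df$valid == 1L &
                 (!is.finite(df$x_arcmin) | !is.finite(df$y_arcmin)))
  if (length(bad) > 0L) {
    stop(sprintf("non-finite positions on valid rows (first at line %d) in %s",
                 bad[1L] + 1L, path), call. = FALSE)
  }
  # contiguity: break at frame gaps and at invalid frames
  brk <- c(FALSE, diff(df$frame) != 1L) | df$valid != 1L
  seg <- cumsum(brk)
  seg[df$valid != 1L] <- NA # invalid rows belong to no segment
  segs <- split(which(!is.na(seg)), seg[!is.na(seg)])
  if (length(segs) > 1L) {
    warning(sprintf("%s: split into %d contiguous segments at gaps/invalid frames",
                    basename(path), length(segs)), call. = FALSE)
  }
  base_id <- sub("\\.csv$", "", basename(path))
  out <- list()
  for (k in seq_along(segs)) {
    rows <- segs[[k]]
    if (length(rows) < min_frames) next
    id <- if (length(segs) == 1L) base_id else sprintf("%s#%d", base_id, k)
    out[[length(out) + 1L]] <- eye_trace(
      cbind(df$x_arcmin[rows], df$y_arcmin[rows]),
      frame_rate = frame_rate, trace_id = id
    )
  }
  if (length(out) == 0L) {
    stop("no contiguous segment of at least ", min_frames, " frames in ",
         path, call. = FALSE)
  }
  out
}

#' Write an eye trace (or trajectory set) to CSV
#'
#' Traces round-trip losslessly through [read_trace_csv()] at full double
#' precision. A `trajectory_set` adds `world_x`, `world_y`, `ret_x`,
#' `ret_y` columns.
#'
#' @param x an [eye_trace()] or `trajectory_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise a walk library
#'
#' Writes the retained paths as one long CSV (`step_sd`, `path_id`, `frame`,
#' `x`, `y`) plus a JSON manifest (step grid, analytic diffusion constants,
#' seed, per-path fitted statistics).
#'
#' @param library a [generate_walk_library()] object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_walk_library <- function(library, dir) {
  stopifnot(inherits(library, "walk_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(library$step_lengths), function(i) {
    do.call(rbind, lapply(library$paths[[i]], function(p) {
      n <- nrow(p$positions)
      data.frame(step_sd = library$step_lengths[i], path_id = p$candidate,
                 frame = seq_len(n), x = p$positions[, 1L],
                 y = p$positions[, 2L])
    }))
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "walk_paths.csv"),
                   row.names = FALSE)
  manifest <- list(
    step_lengths = library$step_lengths,
    analytic_D = library$analytic_D,
    duration_frames = library$duration_frames,
    frame_rate = library$frame_rate,
    n_generate = library$n_generate, n_keep = library$n_keep,
    seed = library$seed,
    fitted = lapply(seq_along(library$paths), function(i) {
      lapply(library$paths[[i]], function(p) {
        list(candidate = p$candidate, fitted_D = p$fitted_D,
             fitted_alpha = p$fitted_alpha)
      })
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write experiment result tables to CSV
#'
#' Emits `trials.csv`, `subject_gain.csv`, `ratio_summary.csv`, and
#' `model_curve.csv` in a layout any statistics package can consume.
#' Output is deterministic for a fixed configuration.
#'
#' @param result an [run_experiment()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_tables <- function(result, dir) {
  stopifnot(inherits(result, "experiment_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(result$subject_gain, file.path(dir, "subject_gain.csv"),
                   row.names = FALSE)
  utils::write.csv(result$ratio_summary,
                   file.path(dir, "ratio_summary.csv"), row.names = FALSE)
  utils::write.csv(result$model_curve, file.path(dir, "model_curve.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read an experiment configuration from YAML or JSON
#'
#' Fields mirror the arguments of [experiment_config()]; absent fields keep
#' their defaults. `backgrounds` must be a named mapping of conditions to
#' `D`, `alpha`, `duration_frames`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @param seed optional override of the file's seed.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path, seed = NULL) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- raw[intersect(names(raw), names(formals(experiment_config)))]
  if (!is.null(args$qc)) args$qc <- utils::modifyList(
    formals(experiment_config)$qc |> eval(), args$qc)
  if (!is.null(seed)) args$seed <- seed
  do.call(experiment_config, args)
}
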