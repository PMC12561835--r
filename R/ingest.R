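## Constructors for the two channel containers. Both are lightweight lists
## wrapping a tibble of records, carrying the session labels and the pixel
## bounds of the view they were recorded in.

new_interval_series <- function(date, focal_id, records, interval_s,
                                image_w, image_h) {
  structure(
    list(date = date, focal_id = focal_id, interval_s = interval_s,
         records = records, image_w = image_w, image_h = image_h,
         view = "schematic"),
    class = "interval_series"
  )
}

new_pose_track <- function(date, track_id, fps, n_frames, frames,
                           image_w, image_h) {
  structure(
    list(date = date, track_id = track_id, fps = fps, n_frames = n_frames,
         frames = frames, image_w = image_w, image_h = image_h,
         view = "camera"),
    class = "pose_track"
  )
}

#' @export
print.interval_series <- function(x, ...) {
  cat(sprintf("<interval_series> %s / %s: %d records every %g s\n",
              x$date, x$focal_id, nrow(x$records), x$interval_s))
  invisible(x)
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> %s / %s: %d frames at %g fps (%d node detections)\n",
              x$date, x$track_id, x$n_frames, x$fps, nrow(x$frames)))
  invisible(x)
}

POSE_NODES <- c("head", "shoulder", "hip", "tail1", "tail2")

#' Read interval focal-sampling records from CSV
#'
#' Reads the manual-channel export shape `date,time_s,focal_id,x,y` (schematic
#' pixels) and returns one series per `(date, focal_id)`. Rows outside the
#' schematic image bounds are rejected (their count is reported via a
#' message and the `n_rejected` attribute). The sampling interval is inferred
#' per series as the modal positive time difference, so missed samples remain
#' gaps rather than fractional intervals.
#'
#' @param path CSV file path.
#' @param config An [enclosure_config()] with a `schematic` view.
#' @return A list of `interval_series`, with attribute `n_rejected`.
#' @export
read_interval_csv <- function(path, config) {
  if (!file.exists(path)) {
    zs_abort(paste("no such file:", path), "zoospace_format_error")
  }
  df <- as.data.frame(readr::read_csv(path, show_col_types = FALSE,
                                      progress = FALSE))
  need <- c("date", "time_s", "focal_id", "x", "y")
  if (!all(need %in% names(df))) {
    zs_abort(paste("interval CSV must contain columns:",
                   paste(need, collapse = ", ")), "zoospace_format_error")
  }
  if (nrow(df) == 0) {
    zs_abort("interval CSV contains no records", "zoospace_empty_input")
  }
  v <- config$views$schematic
  if (is.null(v)) {
    zs_abort("config lacks a 'schematic' view", "zoospace_invalid_config")
  }
  ok <- df$x >= 0 & df$x <= v$image_w & df$y >= 0 & df$y <= v$image_h
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    message(sprintf("read_interval_csv: rejected %d out-of-bounds record(s)",
                    n_rejected))
  }
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0) {
    zs_abort("no in-bounds interval records", "zoospace_empty_input")
  }
  keys <- split(df, list(df$date, df$focal_id), drop = TRUE)
  out <- lapply(keys, function(g) {
    g <- g[order(g$time_s), , drop = FALSE]
    new_interval_series(
      date = as.character(g$date[[1]]), focal_id = as.character(g$focal_id[[1]]),
      records = tibble::tibble(time_s = g$time_s, x = g$x, y = g$y),
      interval_s = infer_interval(g$time_s),
      image_w = v$image_w, image_h = v$image_h
    )
  })
  names(out) <- vapply(out, function(s) paste(s$date, s$focal_id, sep = "/"), "")
  attr(out, "n_rejected") <- n_rejected
  out
}

## Modal positive difference between consecutive sample times.
infer_interval <- function(times) {
  d <- diff(sort(unique(times)))
  d <- d[d > 0]
  if (length(d) == 0) return(NA_real_)
  tab <- table(d)
  as.numeric(names(tab)[which.max(tab)])
}

#' Write interval series back to the CSV export shape
#'
#' @param series A single `interval_series` or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_interval_csv <- function(series, path) {
  if (inherits(series, "interval_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    tibble::tibble(date = s$date, time_s = s$records$time_s,
                   focal_id = s$focal_id, x = s$records$x, y = s$records$y)
  })
  readr::write_csv(dplyr::bind_rows(rows), path)
  invisible(path)
}

## Shared builder for both pose dialects: takes the long table
## (date, frame, time_s, track_id, node, x, y, score) and applies the schema
## filters before splitting into per-(date, track) objects.
build_pose_tracks <- function(df, config, source = "pose table") {
  need <- c("date", "frame", "time_s", "track_id", "node", "x", "y", "score")
  if (!all(need %in% names(df))) {
    zs_abort(paste(source, "must contain columns:", paste(need, collapse = ", ")),
             "zoospace_format_error")
  }
  if (nrow(df) == 0) {
    zs_abort(paste(source, "contains no records"), "zoospace_empty_input")
  }
  v <- config$views$camera
  if (is.null(v)) {
    zs_abort("config lacks a 'camera' view", "zoospace_invalid_config")
  }
  known <- df$node %in% POSE_NODES
  n_rejected <- sum(!known)
  if (n_rejected > 0) {
    message(sprintf("%s: rejected %d record(s) with unknown node names",
                    source, n_rejected))
  }
  df <- df[known, , drop = FALSE]
  ## Scores just outside [0,1] by numerical noise are clamped; anything worse
  ## is rejected as corrupt.
  slack <- 1e-6
  bad <- df$score < -slack | df$score > 1 + slack
  if (any(bad)) {
    message(sprintf("%s: rejected %d record(s) with scores outside [0,1]",
                    source, sum(bad)))
    n_rejected <- n_rejected + sum(bad)
    df <- df[!bad, , drop = FALSE]
  }
  clamped <- df$score < 0 | df$score > 1
  if (any(clamped)) {
    warning(sprintf("%s: clamped %d score(s) within 1e-6 of [0,1]",
                    source, sum(clamped)))
    df$score <- clip_range(df$score, 0, 1)
  }
  if (nrow(df) == 0) {
    zs_abort(paste(source, "has no valid records"), "zoospace_empty_input")
  }
  keys <- split(df, list(df$date, df$track_id), drop = TRUE)
  out <- lapply(keys, function(g) {
    g <- g[order(g$frame, g$node), , drop = FALSE]
    fps <- infer_fps(g$frame, g$time_s)
    new_pose_track(
      date = as.character(g$date[[1]]), track_id = as.character(g$track_id[[1]]),
      fps = fps, n_frames = max(g$frame) + 1L,
      frames = tibble::tibble(frame = as.integer(g$frame), time_s = g$time_s,
                              node = as.character(g$node), x = g$x, y = g$y,
                              score = g$score),
      image_w = v$image_w, image_h = v$image_h
    )
  })
  names(out) <- vapply(out, function(t) paste(t$date, t$track_id, sep = "/"), "")
  attr(out, "n_rejected") <- n_rejected
  out
}

infer_fps <- function(frames, times) {
  u <- !duplicated(frames)
  f <- frames[u]; t <- times[u]
  if (length(f) < 2) return(1)
  df <- diff(f); dt <- diff(t)
  keep <- dt > 0
  if (!any(keep)) return(1)
  stats::median(df[keep] / dt[keep])
}

#' Read pose-estimation tracks (CSV or HDF5 dialect)
#'
#' Both dialects carry the same long analysis-export table
#' `date,frame,time_s,track_id,node,x,y,score` — as a CSV, or as a single
#' HDF5 compound table at `/poses`. The two readers yield identical in-memory
#' structures on equivalent content. Unknown node names (outside head,
#' shoulder, hip, tail1, tail2) are rejected with a reported count; scores
#' outside `[0, 1]` by more than 1e-6 are rejected, smaller excursions are
#' clamped with a warning.
#'
#' @param path File path.
#' @param config An [enclosure_config()] with a `camera` view.
#' @return A list of `pose_track`, with attribute `n_rejected`.
#' @export
read_pose_csv <- function(path, config) {
  if (!file.exists(path)) {
    zs_abort(paste("no such file:", path), "zoospace_format_error")
  }
  df <- as.data.frame(readr::read_csv(path, show_col_types = FALSE,
                                      progress = FALSE))
  build_pose_tracks(df, config, source = basename(path))
}

#' @rdname read_pose_csv
#' @export
read_pose_h5 <- function(path, config) {
  if (!file.exists(path)) {
    zs_abort(paste("no such file:", path), "zoospace_format_error")
  }
  df <- as.data.frame(rhdf5::h5read(path, "poses"))
  for (col in c("frame", "time_s", "x", "y", "score")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("date", "track_id", "node")) {
    df[[col]] <- as.character(df[[col]])
  }
  build_pose_tracks(df, config, source = basename(path))
}

pose_long_table <- function(tracks) {
  if (inherits(tracks, "pose_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(t) {
    tibble::tibble(date = t$date, frame = t$frames$frame,
                   time_s = t$frames$time_s, track_id = t$track_id,
                   node = t$frames$node, x = t$frames$x, y = t$frames$y,
                   score = t$frames$score)
  })
  dplyr::bind_rows(rows)
}

#' Write pose tracks to the CSV or HDF5 export shape
#'
#' @param tracks A single `pose_track` or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(tracks, path) {
  readr::write_csv(pose_long_table(tracks), path)
  invisible(path)
}

#' @rdname write_pose_csv
#' @export
write_pose_h5 <- function(tracks, path) {
  df <- as.data.frame(pose_long_table(tracks))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(df, path, "poses")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Split a session around a camera shift
#'
#' Records strictly before `split_time` go to the `pre` segment, the rest to
#' `post`; counts are conserved and the segments' date labels are suffixed
#' `-pre` / `-post`.
#'
#' @param x An `interval_series` or `pose_track`.
#' @param split_time Split time in seconds, within the session span.
#' @return A list with elements `pre` and `post` of the same class as `x`.
#' @export
split_session <- function(x, split_time) UseMethod("split_session")

check_split_time <- function(split_time, span) {
  if (!is.numeric(split_time) || split_time < 0 || split_time > span) {
    zs_abort("split_time must lie within the session span", "zoospace_range_error")
  }
}

#' @export
split_session.interval_series <- function(x, split_time) {
  check_split_time(split_time, max(x$records$time_s))
  pre <- x; post <- x
  sel <- x$records$time_s < split_time
  pre$records <- x$records[sel, , drop = FALSE]
  post$records <- x$records[!sel, , drop = FALSE]
  pre$date <- paste0(x$date, "-pre")
  post$date <- paste0(x$date, "-post")
  list(pre = pre, post = post)
}

#' @export
split_session.pose_track <- function(x, split_time) {
  check_split_time(split_time, x$n_frames / x$fps)
  sel <- x$frames$time_s < split_time
  pre <- x; post <- x
  pre$frames <- x$frames[sel, , drop = FALSE]
  post$frames <- x$frames[!sel, , drop = FALSE]
  pre$n_frames <- length(unique(pre$frames$frame))
  post$n_frames <- x$n_frames - pre$n_frames
  pre$date <- paste0(x$date, "-pre")
  post$date <- paste0(x$date, "-post")
  list(pre = pre, post = post)
}

#' Screen a pose track for camera shifts
#'
#' Reduces the track to best-scored hip/shoulder points, cuts the session
#' into consecutive windows of `window_s` seconds, and flags the boundaries
#' where the displacement of the window mean position exceeds `k` times the
#' median per-window robust spread (median distance of a window's points to
#' the window mean). A stable, locally stationary session yields no
#' candidates.
#'
#' Large genuine relocations of the animal between distant enclosure areas
#' can exceed the same threshold, so candidates are a screening aid to be
#' confirmed (and acted on via [split_session()]) by inspection, not a
#' verdict.
#'
#' @param track A `pose_track`.
#' @param window_s Window length in seconds (session must cover at least two
#'   windows).
#' @param k Threshold multiplier (default 3).
#' @return A `shift_report`: list with `candidate_times` (seconds, window
#'   boundaries), `statistic_trace` (per-window standardized mean shift;
#'   first window 0), `window_s`, `k` and `threshold_px`.
#' @export
detect_shift <- function(track, window_s = 60, k = 3) {
  pts <- reduce_track(track)
  if (nrow(pts) == 0) {
    zs_abort("track has no reducible frames", "zoospace_insufficient_data")
  }
  span <- track$n_frames / track$fps
  nw <- floor(span / window_s)
  if (nw < 2) {
    zs_abort("session shorter than two windows", "zoospace_insufficient_data")
  }
  win <- pmin(floor(pts$time_s / window_s) + 1, nw)
  mx <- tapply(pts$x, factor(win, levels = seq_len(nw)), mean)
  my <- tapply(pts$y, factor(win, levels = seq_len(nw)), mean)
  spread <- vapply(seq_len(nw), function(i) {
    sel <- win == i
    if (!any(sel)) return(NA_real_)
    stats::median(sqrt((pts$x[sel] - mx[i])^2 + (pts$y[sel] - my[i])^2))
  }, numeric(1))
  disp <- sqrt(diff(mx)^2 + diff(my)^2)
  ref <- stats::median(spread, na.rm = TRUE)
  trace <- c(0, if (ref > 0) disp / ref else ifelse(disp > 0, Inf, 0))
  boundary_t <- seq_len(nw - 1) * window_s
  cand <- boundary_t[!is.na(disp) & disp > k * ref]
  structure(
    list(candidate_times = cand, statistic_trace = unname(trace),
         window_s = window_s, k = k, threshold_px = k * ref),
    class = "shift_report"
  )
}

#' @export
print.shift_report <- function(x, ...) {
  if (length(x$candidate_times) == 0) {
    cat("<shift_report> no shift candidates\n")
  } else {
    cat(sprintf("<shift_report> candidate shift(s) at %s s (windows of %g s)\n",
                paste(x$candidate_times, collapse = ", "), x$window_s))
  }
  invisible(x)
}
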