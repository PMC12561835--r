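#' Movement budget of a manual interval series
#'
#' Classifies each pair of consecutive present records exactly one sampling
#' interval apart as movement when the Euclidean displacement exceeds
#' `threshold_px` schematic pixels (strict inequality), in which case the
#' full interval contributes to the movement total. Pairs spanning a gap
#' (missed samples) are counted as unknown and contribute nothing.
#'
#' @param series An `interval_series`.
#' @param threshold_px Displacement threshold in schematic pixels (default 7).
#' @return One-row tibble (`date`, `individual`, `method = "interval"`,
#'   `movement_s`, `session_s`, `n_steps_evaluated`, `n_steps_unknown`).
#' @export
interval_movement <- function(series, threshold_px = 7) {
  r <- series$records
  if (nrow(r) == 0) {
    zs_abort("interval series is empty", "zoospace_empty_input")
  }
  iv <- series$interval_s
  if (nrow(r) == 1 || is.na(iv)) {
    return(activity_record(series$date, series$focal_id, "interval",
                           0, iv %||% 0, 0, 0))
  }
  dt <- diff(r$time_s)
  d <- sqrt(diff(r$x)^2 + diff(r$y)^2)
  adjacent <- abs(dt - iv) < 1e-9
  slots <- round((r$time_s[nrow(r)] - r$time_s[1]) / iv)
  movement_s <- sum(adjacent & d > threshold_px) * iv
  activity_record(series$date, series$focal_id, "interval",
                  movement_s,
                  session_s = r$time_s[nrow(r)] - r$time_s[1] + iv,
                  n_eval = sum(adjacent),
                  n_unknown = slots - sum(adjacent))
}

#' Movement budget of a pose track
#'
#' Reduces each frame to its best-scored hip/shoulder point
#' ([reduce_track()]); each pair of consecutive frames whose reduced points
#' both exist is movement when the Euclidean displacement exceeds
#' `threshold_px` camera pixels (strict inequality), contributing `1/fps`
#' seconds. Steps with a missing endpoint are unknown and contribute nothing.
#'
#' @param track A `pose_track`.
#' @param threshold_px Displacement threshold in camera pixels (default 30).
#' @param fps Frame rate; defaults to the track's own.
#' @return One-row tibble as in [interval_movement()] with
#'   `method = "pose"`.
#' @export
pose_movement <- function(track, threshold_px = 30, fps = track$fps) {
  if (track$n_frames == 0) {
    zs_abort("pose track is empty", "zoospace_empty_input")
  }
  pts <- reduce_track(track)
  slots <- max(track$n_frames - 1, 0)
  if (nrow(pts) < 2) {
    return(activity_record(track$date, track$track_id, "pose",
                           0, track$n_frames / fps, 0, slots))
  }
  consecutive <- diff(pts$frame) == 1
  d <- sqrt(diff(pts$x)^2 + diff(pts$y)^2)
  movement_s <- sum(consecutive & d > threshold_px) / fps
  activity_record(track$date, track$track_id, "pose",
                  movement_s,
                  session_s = track$n_frames / fps,
                  n_eval = sum(consecutive),
                  n_unknown = slots - sum(consecutive))
}

activity_record <- function(date, individual, method, movement_s, session_s,
                            n_eval, n_unknown) {
  tibble::tibble(
    date = date, individual = individual, method = method,
    movement_s = movement_s, session_s = session_s,
    n_steps_evaluated = n_eval, n_steps_unknown = n_unknown
  )
}

#' Paired t-test between two per-day measurement series
#'
#' Two-sided paired Student t-test on `a - b` with sample standard deviation
#' (n - 1 denominator), `df = n - 1`. All-equal differences leave the
#' statistic undefined and raise a degenerate-test error rather than
#' returning a coerced value.
#'
#' @param a,b Equal-length numeric vectors (e.g. daily movement seconds from
#'   each method), `n >= 2`.
#' @return One-row tibble: `t`, `df`, `p`, `n`, `mean_diff`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) {
    zs_abort("paired series must have equal length", "zoospace_pairing_error")
  }
  if (length(a) < 2) {
    zs_abort("need at least two pairs", "zoospace_pairing_error")
  }
  d <- a - b
  if (stats::sd(d) == 0) {
    zs_abort("paired differences are constant; t statistic undefined",
             "zoospace_degenerate_test")
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    n = length(a),
    mean_diff = mean(d)
  )
}

#' Per-day activity comparison between the two methods
#'
#' Computes per-day, per-individual movement budgets for both channels, sums
#' them to daily per-method totals (one value per method per day, the shape
#' in which daily activity is reported and tested), and runs the paired
#' t-test across days on those totals. Days present in only one channel are
#' excluded with a warning.
#'
#' @param interval List of `interval_series` (any days/individuals).
#' @param pose List of `pose_track`.
#' @param interval_threshold_px,pose_threshold_px Displacement thresholds
#'   (defaults 7 and 30 pixels).
#' @return List with `records` (per day x individual x method tibble),
#'   `daily` (per day totals, wide: `interval_s_total`, `pose_s_total`), and
#'   `test` (the [paired_t()] result, or `NULL` with fewer than two days).
#' @export
activity_report <- function(interval, pose,
                            interval_threshold_px = 7,
                            pose_threshold_px = 30) {
  if (inherits(interval, "interval_series")) interval <- list(interval)
  if (inherits(pose, "pose_track")) pose <- list(pose)
  rec_i <- dplyr::bind_rows(lapply(interval, interval_movement,
                                   threshold_px = interval_threshold_px))
  rec_p <- dplyr::bind_rows(lapply(pose, pose_movement,
                                   threshold_px = pose_threshold_px))
  shared <- intersect(unique(rec_i$date), unique(rec_p$date))
  dropped <- setdiff(union(unique(rec_i$date), unique(rec_p$date)), shared)
  if (length(dropped) > 0) {
    warning(sprintf("excluding day(s) present in one channel only: %s",
                    paste(dropped, collapse = ", ")))
  }
  if (length(shared) < 2) {
    zs_abort("need at least two days present in both channels",
             "zoospace_insufficient_data")
  }
  records <- dplyr::bind_rows(rec_i, rec_p)
  records <- records[records$date %in% shared, , drop = FALSE]
  agg <- stats::aggregate(movement_s ~ date + method, data = records, FUN = sum)
  wide <- stats::reshape(agg, idvar = "date", timevar = "method",
                         direction = "wide")
  names(wide) <- sub("^movement_s\\.", "", names(wide))
  daily <- tibble::tibble(
    date = wide$date,
    interval_s_total = wide$interval,
    pose_s_total = wide$pose
  )
  daily <- daily[order(daily$date), , drop = FALSE]
  test <- tryCatch(
    paired_t(daily$interval_s_total, daily$pose_s_total),
    zoospace_degenerate_test = function(e) {
      warning(conditionMessage(e))
      NULL
    }
  )
  list(records = records, daily = daily, test = test)
}
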