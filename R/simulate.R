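#' Simulate a ground-truth enclosure trajectory
#'
#' Runs the switching hotspot-attractor process of a [sim_config()] for one
#' individual and samples the resulting path on a regular 1 Hz grid. Dwell
#' positions are the hotspot plus isotropic Gaussian jitter (clipped to the
#' enclosure); transit positions lie exactly on the straight line between the
#' departing and arriving hotspots. Deterministic given
#' `(config$seed, individual_id)`.
#'
#' @param config A [sim_config()].
#' @param individual_id Label of the simulated individual.
#' @return A `trajectory` object: list with `individual_id` and a tibble
#'   `path` with columns `time_s`, `x`, `y` (metres), `state`
#'   (`"dwelling"`/`"transiting"`) and `hotspot` (index, `NA` in transit).
#' @export
#' @examples
#' tr <- simulate_trajectory(sim_config(duration_s = 300), "ind1")
#' head(tr$path)
simulate_trajectory <- function(config, individual_id = "ind1") {
  validate_sim_config(config)
  if (config$duration_s <= 0) {
    zs_abort("duration_s must be positive", "zoospace_invalid_config")
  }
  n_t <- floor(config$duration_s)
  hx <- config$hotspots$x
  hy <- config$hotspots$y
  w <- config$hotspots$weight

  with_seed(derive_seed(config$seed, "trajectory", individual_id), {
    ## Build the continuous-time segment timeline first, then evaluate it on
    ## the integer-second grid. Segment draws are sequential so the stream is
    ## reproducible regardless of duration rounding.
    seg_type <- integer(0)   # 1 dwell, 2 transit
    seg_from <- integer(0)   # hotspot index (dwell: the hotspot; transit: origin)
    seg_to <- integer(0)     # transit destination
    seg_t0 <- numeric(0)
    seg_t1 <- numeric(0)
    t_cur <- 0
    h_cur <- sample.int(length(w), 1, prob = w)
    while (t_cur < n_t) {
      d_dwell <- stats::rexp(1, rate = 1 / config$mean_dwell)
      seg_type <- c(seg_type, 1L)
      seg_from <- c(seg_from, h_cur)
      seg_to <- c(seg_to, h_cur)
      seg_t0 <- c(seg_t0, t_cur)
      seg_t1 <- c(seg_t1, t_cur + d_dwell)
      t_cur <- t_cur + d_dwell
      h_next <- sample.int(length(w), 1, prob = w)
      if (h_next != h_cur && t_cur < n_t) {
        d <- sqrt((hx[h_next] - hx[h_cur])^2 + (hy[h_next] - hy[h_cur])^2)
        d_tr <- d / config$transit_speed
        seg_type <- c(seg_type, 2L)
        seg_from <- c(seg_from, h_cur)
        seg_to <- c(seg_to, h_next)
        seg_t0 <- c(seg_t0, t_cur)
        seg_t1 <- c(seg_t1, t_cur + d_tr)
        t_cur <- t_cur + d_tr
      }
      h_cur <- h_next
    }

    times <- seq_len(n_t) - 1
    seg_i <- findInterval(times, seg_t0)
    type <- seg_type[seg_i]
    frac <- (times - seg_t0[seg_i]) / (seg_t1[seg_i] - seg_t0[seg_i])
    x <- ifelse(type == 1L, hx[seg_from[seg_i]],
                hx[seg_from[seg_i]] + frac * (hx[seg_to[seg_i]] - hx[seg_from[seg_i]]))
    y <- ifelse(type == 1L, hy[seg_from[seg_i]],
                hy[seg_from[seg_i]] + frac * (hy[seg_to[seg_i]] - hy[seg_from[seg_i]]))
    dwell <- type == 1L
    if (config$local_sigma > 0 && any(dwell)) {
      x[dwell] <- x[dwell] + stats::rnorm(sum(dwell), 0, config$local_sigma)
      y[dwell] <- y[dwell] + stats::rnorm(sum(dwell), 0, config$local_sigma)
    }
    x <- clip_range(x, 0, config$enclosure_width)
    y <- clip_range(y, 0, config$enclosure_height)

    structure(
      list(
        individual_id = individual_id,
        config = config,
        path = tibble::tibble(
          time_s = times, x = x, y = y,
          state = ifelse(dwell, "dwelling", "transiting"),
          hotspot = ifelse(dwell, seg_from[seg_i], NA_integer_)
        )
      ),
      class = "trajectory"
    )
  })
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s: %d s, %.0f%% dwelling\n",
              x$individual_id, nrow(x$path),
              100 * mean(x$path$state == "dwelling")))
  invisible(x)
}

## Linear interpolation of a trajectory at arbitrary times (used when channel
## sampling times do not fall on the 1 Hz grid).
trajectory_at <- function(traj, times) {
  p <- traj$path
  list(
    x = stats::approx(p$time_s, p$x, xout = times, rule = 2)$y,
    y = stats::approx(p$time_s, p$y, xout = times, rule = 2)$y
  )
}

#' Render a trajectory through the manual interval focal-sampling channel
#'
#' Emulates an observer recording the focal's location every `interval_s`
#' seconds on the top-down schematic map: the true position is projected into
#' schematic pixels, perturbed with isotropic Gaussian placement noise
#' (`observer_sigma` pixels) and clipped to the image. Yields
#' `floor(duration / interval_s)` records at times `0, interval_s, ...`.
#'
#' @param traj A [simulate_trajectory()] result.
#' @param proj The schematic [view_projection()].
#' @param config The [sim_config()] used for the trajectory.
#' @param date Session date label attached to the series.
#' @return An `interval_series` object (see [read_interval_csv()]).
#' @export
sample_interval_channel <- function(traj, proj, config, date = "s1") {
  if (!identical(proj$view_id, "schematic")) {
    zs_abort("interval channel requires the schematic view projection",
             "zoospace_view_mismatch")
  }
  dur <- nrow(traj$path)
  n <- floor(dur / config$interval_s)
  times <- (seq_len(n) - 1) * config$interval_s
  pos <- trajectory_at(traj, times)
  px <- project_points(proj, pos$x, pos$y)
  with_seed(derive_seed(config$seed, "interval", date, traj$individual_id), {
    if (config$observer_sigma > 0) {
      px$x <- px$x + stats::rnorm(n, 0, config$observer_sigma)
      px$y <- px$y + stats::rnorm(n, 0, config$observer_sigma)
    }
  })
  new_interval_series(
    date = date, focal_id = traj$individual_id,
    records = tibble::tibble(
      time_s = times,
      x = clip_range(px$x, 0, proj$image_w),
      y = clip_range(px$y, 0, proj$image_h)
    ),
    interval_s = config$interval_s,
    image_w = proj$image_w, image_h = proj$image_h
  )
}

#' Render a trajectory through the automated pose-estimation channel
#'
#' Emulates a pose-estimation export at `pose_fps` frames per second: per
#' frame the projected body centre is jittered by `pose_sigma` camera pixels;
#' each of the five skeleton nodes sits at the centre plus its configured
#' offset plus independent jitter, is dropped with probability `p_miss`, and
#' carries a Beta-distributed confidence score. Yields
#' `floor(duration * pose_fps)` frames (a frame with all nodes dropped is
#' still a frame).
#'
#' @inheritParams sample_interval_channel
#' @param proj The camera [view_projection()].
#' @return A `pose_track` object (see [read_pose_csv()]).
#' @export
sample_pose_channel <- function(traj, proj, config, date = "s1") {
  if (!identical(proj$view_id, "camera")) {
    zs_abort("pose channel requires the camera view projection",
             "zoospace_view_mismatch")
  }
  dur <- nrow(traj$path)
  n <- floor(dur * config$pose_fps)
  frames <- seq_len(n) - 1
  times <- frames / config$pose_fps
  pos <- trajectory_at(traj, times)
  ctr <- project_points(proj, pos$x, pos$y)
  nodes <- names(config$node_offsets)
  k <- length(nodes)
  with_seed(derive_seed(config$seed, "pose", date, traj$individual_id), {
    cx <- ctr$x + stats::rnorm(n, 0, config$pose_sigma)
    cy <- ctr$y + stats::rnorm(n, 0, config$pose_sigma)
    off <- do.call(rbind, config$node_offsets[nodes])
    long <- tibble::tibble(
      frame = rep(frames, each = k),
      time_s = rep(times, each = k),
      node = rep(nodes, times = n),
      x = rep(cx, each = k) + rep(off[, 1], times = n) +
        stats::rnorm(n * k, 0, config$pose_sigma),
      y = rep(cy, each = k) + rep(off[, 2], times = n) +
        stats::rnorm(n * k, 0, config$pose_sigma),
      score = stats::rbeta(n * k, config$score_params[[1]], config$score_params[[2]])
    )
    missing <- stats::runif(n * k) < config$p_miss
    long <- long[!missing, , drop = FALSE]
  })
  long$x <- clip_range(long$x, 0, proj$image_w)
  long$y <- clip_range(long$y, 0, proj$image_h)
  new_pose_track(
    date = date, track_id = traj$individual_id, fps = config$pose_fps,
    n_frames = n, frames = long,
    image_w = proj$image_w, image_h = proj$image_h
  )
}

#' Translate all pose coordinates after a camera shift
#'
#' Emulates an unplanned camera displacement: every node coordinate at times
#' at or after `shift_time` is translated by `offset` pixels and clipped to
#' the image; earlier frames are untouched. The frame count is conserved.
#'
#' @param track A `pose_track`.
#' @param shift_time Shift time in seconds, strictly inside the session.
#' @param offset Numeric `c(dx, dy)` pixel offset.
#' @return The shifted `pose_track`.
#' @export
inject_camera_shift <- function(track, shift_time, offset) {
  dur <- track$n_frames / track$fps
  if (!is.numeric(shift_time) || shift_time <= 0 || shift_time >= dur) {
    zs_abort("shift_time must lie strictly inside the session span",
             "zoospace_range_error")
  }
  sel <- track$frames$time_s >= shift_time
  track$frames$x[sel] <- clip_range(track$frames$x[sel] + offset[[1]],
                                    0, track$image_w)
  track$frames$y[sel] <- clip_range(track$frames$y[sel] + offset[[2]],
                                    0, track$image_h)
  track
}

#' Ground-truth seconds in movement of a simulated trajectory
#'
#' Counts the 1 s steps of the trajectory whose displacement exceeds
#' `speed_threshold` metres per second; the reference value against which the
#' two observation channels' movement budgets are validated.
#'
#' @param traj A [simulate_trajectory()] result.
#' @param speed_threshold Speed threshold in m/s (`>= 0`).
#' @return Seconds in movement (integer-valued numeric).
#' @export
ground_truth_activity <- function(traj, speed_threshold) {
  if (speed_threshold < 0) {
    zs_abort("speed_threshold must be nonnegative", "zoospace_invalid_config")
  }
  p <- traj$path
  dt <- diff(p$time_s)
  d <- sqrt(diff(p$x)^2 + diff(p$y)^2)
  sum(dt[d > speed_threshold * dt])
}

#' Simulate a complete multi-day dual-channel study
#'
#' Generates, for each observation day and individual, a ground-truth
#' trajectory and its renderings through both observation channels, matching
#' the design of the study being emulated: two individuals, six
#' non-consecutive days whose durations have median 62 min, mean 66 min and
#' range 52-90 min, a 12 s interval channel and a 1 fps pose channel.
#' Optionally injects a camera shift into the pose channel of one day.
#'
#' @param config A [sim_config()].
#' @param dates Character vector of day labels.
#' @param durations_s Per-day session durations in seconds (recycled against
#'   `dates`).
#' @param seed Base seed (defaults to `config$seed`); every
#'   day/individual/channel combination draws from its own derived stream.
#' @param shift Optional `list(date =, time_s =, offset = c(dx, dy))`
#'   describing a camera shift injected into that day's pose tracks.
#' @return A list with elements `config`, `projections`, `enclosure`
#'   (a [default_enclosure_config()]), `trajectories`, `interval` and `pose`
#'   (lists keyed `"date/individual"`), `dates`, and `durations_s`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(), dates = c("d1", "d2"),
#'                         durations_s = c(300, 300))
#' names(study$interval)
simulate_study <- function(config = sim_config(),
                           dates = c("2024-10-27", "2024-10-28", "2024-10-31",
                                     "2024-11-01", "2024-11-09", "2024-11-16"),
                           durations_s = c(52, 58, 61, 63, 72, 90) * 60,
                           seed = config$seed,
                           shift = NULL) {
  durations_s <- rep_len(durations_s, length(dates))
  proj <- default_projections(config)
  individuals <- paste0("ind", seq_len(config$n_individuals))
  trajectories <- list()
  interval <- list()
  pose <- list()
  for (i in seq_along(dates)) {
    day_cfg <- config
    day_cfg$duration_s <- durations_s[[i]]
    day_cfg$seed <- derive_seed(seed, "day", dates[[i]])
    for (id in individuals) {
      key <- paste(dates[[i]], id, sep = "/")
      tr <- simulate_trajectory(day_cfg, id)
      trajectories[[key]] <- tr
      interval[[key]] <- sample_interval_channel(tr, proj$schematic, day_cfg,
                                                 date = dates[[i]])
      pt <- sample_pose_channel(tr, proj$camera, day_cfg, date = dates[[i]])
      if (!is.null(shift) && identical(shift$date, dates[[i]])) {
        pt <- inject_camera_shift(pt, shift$time_s, shift$offset)
      }
      pose[[key]] <- pt
    }
  }
  list(
    config = config, projections = proj,
    enclosure = default_enclosure_config(config),
    trajectories = trajectories, interval = interval, pose = pose,
    dates = dates, durations_s = durations_s
  )
}
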