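# Shared fixtures: everything is generated in code at test time.

# A fast config: short session, defaults otherwise.
quick_config <- function(duration_s = 600, ...) {
  sim_config(duration_s = duration_s, ...)
}

# A degenerate config whose trajectory is exactly stationary.
stationary_config <- function(duration_s = 300, x = 6, y = 4,
                              local_sigma = 0, ...) {
  sim_config(
    hotspots = data.frame(x = x, y = y, weight = 1),
    local_sigma = local_sigma, duration_s = duration_s, ...
  )
}

# Build an interval series directly from records (bypassing the simulator).
make_series <- function(time_s, x, y, interval_s = 12, date = "d1",
                        focal_id = "f1", image_w = 400, image_h = 264) {
  zoospace:::new_interval_series(
    date = date, focal_id = focal_id,
    records = tibble::tibble(time_s = time_s, x = x, y = y),
    interval_s = interval_s, image_w = image_w, image_h = image_h
  )
}

# Build a pose track from per-frame reduced positions: one hip node per
# frame with score 1 (so reduction returns exactly these points).
make_track <- function(x, y, fps = 1, date = "d1", track_id = "t1",
                       image_w = 3840, image_h = 2160, node = "hip",
                       score = 1) {
  n <- length(x)
  zoospace:::new_pose_track(
    date = date, track_id = track_id, fps = fps, n_frames = n,
    frames = tibble::tibble(
      frame = seq_len(n) - 1L, time_s = (seq_len(n) - 1) / fps,
      node = node, x = x, y = y, score = score
    ),
    image_w = image_w, image_h = image_h
  )
}

# Random probability vector over k categories.
random_simplex <- function(k, names = paste0("R", seq_len(k))) {
  v <- stats::rexp(k)
  stats::setNames(v / sum(v), names)
}
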