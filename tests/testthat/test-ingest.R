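enc <- default_enclosure_config()

test_that("interval CSV round trip preserves records and rejects bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  s <- make_series(time_s = c(0, 12, 24), x = c(10, 20, 30), y = c(5, 6, 7))
  write_interval_csv(s, path)
  back <- read_interval_csv(path, enc)
  expect_length(back, 1)
  expect_equal(back[[1]]$records, s$records)
  expect_equal(back[[1]]$interval_s, 12)

  # one out-of-bounds row among ten is rejected with a count of one
  df <- data.frame(date = "d1", time_s = seq(0, 108, 12), focal_id = "f1",
                   x = c(rep(50, 9), 1e5), y = 10)
  utils::write.csv(df, path, row.names = FALSE)
  expect_message(back2 <- read_interval_csv(path, enc), "rejected 1")
  expect_equal(nrow(back2[[1]]$records), 9)
  expect_equal(attr(back2, "n_rejected"), 1)
})

test_that("interval reader infers the modal interval and keeps gaps as gaps", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(date = "d1", time_s = c(0, 12, 24, 48), focal_id = "f1",
                   x = 10, y = 10)
  utils::write.csv(df, path, row.names = FALSE)
  s <- read_interval_csv(path, enc)[[1]]
  expect_equal(s$interval_s, 12)
  expect_equal(s$records$time_s, c(0, 12, 24, 48))  # gap at 36 not filled
})

test_that("interval reader enforces schema and non-emptiness", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1, b = 2), path, row.names = FALSE)
  expect_error(read_interval_csv(path, enc), class = "zoospace_format_error")
  utils::write.csv(data.frame(date = character(0), time_s = numeric(0),
                              focal_id = character(0), x = numeric(0),
                              y = numeric(0)), path, row.names = FALSE)
  expect_error(read_interval_csv(path, enc), class = "zoospace_empty_input")
})

test_that("pose CSV and HDF5 dialects read to identical structures", {
  cfg <- quick_config(duration_s = 60, seed = 4)
  tr <- simulate_trajectory(cfg, "ind1")
  pt <- sample_pose_channel(tr, default_projections(cfg)$camera, cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  h5 <- withr::local_tempfile(fileext = ".h5")
  write_pose_csv(pt, csv)
  write_pose_h5(pt, h5)
  from_csv <- read_pose_csv(csv, enc)
  from_h5 <- read_pose_h5(h5, enc)
  expect_equal(names(from_csv), names(from_h5))
  a <- from_csv[[1]]$frames
  b <- from_h5[[1]]$frames
  expect_equal(a$node, b$node)
  expect_equal(a$x, b$x, tolerance = 1e-6)
  expect_equal(a$score, b$score, tolerance = 1e-6)
})

test_that("pose reader applies the node schema and score filters", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(date = "d1", frame = 0:4, time_s = 0:4, track_id = "t1",
                   node = c("hip", "elbow", "shoulder", "hip", "hip"),
                   x = 10, y = 10,
                   score = c(0.5, 0.5, 1 + 5e-7, 2, 0.9))
  utils::write.csv(df, path, row.names = FALSE)
  expect_warning(
    expect_message(tracks <- read_pose_csv(path, enc), "rejected"),
    "clamped"
  )
  fr <- tracks[[1]]$frames
  expect_equal(nrow(fr), 3)               # elbow and score=2 rows rejected
  expect_equal(attr(tracks, "n_rejected"), 2)
  expect_true(all(fr$score <= 1))

  # single frame with all five nodes
  df5 <- data.frame(date = "d1", frame = 0, time_s = 0, track_id = "t1",
                    node = c("head", "shoulder", "hip", "tail1", "tail2"),
                    x = 1:5, y = 1:5, score = 0.5)
  utils::write.csv(df5, path, row.names = FALSE)
  t5 <- read_pose_csv(path, enc)
  expect_length(t5, 1)
  expect_equal(nrow(t5[[1]]$frames), 5)
})

test_that("split_session conserves records, order and labels segments", {
  s <- make_series(time_s = seq(0, 12 * 99, 12), x = runif(100, 0, 400),
                   y = runif(100, 0, 264))
  sp <- split_session(s, 12 * 40)
  expect_equal(nrow(sp$pre$records), 40)
  expect_equal(nrow(sp$post$records), 60)
  expect_equal(sp$pre$date, "d1-pre")
  expect_equal(sp$post$date, "d1-post")

  # boundary: split at zero puts everything in post
  sp0 <- split_session(s, 0)
  expect_equal(nrow(sp0$pre$records), 0)
  expect_equal(nrow(sp0$post$records), 100)

  # conservation for random split times, both channel types
  track <- make_track(runif(80, 0, 3840), runif(80, 0, 2160))
  for (tcut in runif(5, 0, 79)) {
    a <- split_session(s, tcut * 12)
    expect_equal(nrow(a$pre$records) + nrow(a$post$records), 100)
    b <- split_session(track, tcut)
    expect_equal(nrow(b$pre$frames) + nrow(b$post$frames), 80)
  }

  expect_error(split_session(s, 1e6), class = "zoospace_range_error")
  expect_error(split_session(s, -1), class = "zoospace_range_error")
})

test_that("shift screening is quiet on stable sessions and flags injected shifts", {
  # stationary track: no candidates at all
  still <- make_track(rep(500, 600), rep(500, 600))
  rep0 <- detect_shift(still, window_s = 60)
  expect_length(rep0$candidate_times, 0)
  expect_length(rep0$statistic_trace, 10)

  # zero false positives across 20 seeded stable (single-hotspot) sessions
  proj <- default_projections(sim_config())
  fp <- vapply(1:20, function(s) {
    cfg <- stationary_config(duration_s = 600, local_sigma = 0.01, seed = 100 + s)
    tr <- simulate_trajectory(cfg, "ind1")
    pt <- sample_pose_channel(tr, proj$camera, cfg)
    length(detect_shift(pt, window_s = 60)$candidate_times)
  }, numeric(1))
  expect_equal(sum(fp), 0)

  # injected 50 px shift on a noisy stationary session: one candidate,
  # within one window of the truth
  cfg <- stationary_config(duration_s = 600, local_sigma = 0.01, seed = 42)
  tr <- simulate_trajectory(cfg, "ind1")
  pt <- sample_pose_channel(tr, proj$camera, cfg)
  sh <- inject_camera_shift(pt, 305, c(50, 0))
  r1 <- detect_shift(sh, window_s = 60)
  expect_gte(length(r1$candidate_times), 1)
  expect_lte(min(abs(r1$candidate_times - 305)), 60)

  # two injected shifts yield two flagged neighbourhoods
  sh2 <- inject_camera_shift(sh, 455, c(0, 60))
  r2 <- detect_shift(sh2, window_s = 60)
  expect_lte(min(abs(r2$candidate_times - 305)), 60)
  expect_lte(min(abs(r2$candidate_times - 455)), 60)

  # all-missing track cannot be screened
  empty <- make_track(numeric(0), numeric(0))
  empty$n_frames <- 200L
  expect_error(detect_shift(empty, 60), class = "zoospace_insufficient_data")
})

test_that("enclosure config survives YAML and JSON round trips", {
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_enclosure_config(enc, path)
    back <- read_enclosure_config(path)
    expect_equal(names(back$regions), names(enc$regions))
    expect_equal(back$views$camera$image_w, enc$views$camera$image_w)
    expect_equal(back$regions$R2$schematic, enc$regions$R2$schematic,
                 tolerance = 1e-9)
    expect_equal(back$grid, enc$grid)
  }
})

test_that("malformed enclosure configs are rejected", {
  expect_error(
    enclosure_config(
      views = list(v = list(image_w = 10, image_h = 10)),
      regions = list(R1 = list())  # missing polygon for view v
    ),
    class = "zoospace_invalid_config"
  )
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(
    enclosure_config(
      views = list(v = list(image_w = 10, image_h = 10)),
      regions = list(R1 = list(v = bowtie))
    ),
    class = "zoospace_invalid_config"
  )
})
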