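test_that("interval movement applies the 7 px Euclidean rule per 12 s pair", {
  # displacement 10 > 7: one moving pair worth 12 s
  s <- make_series(time_s = c(0, 12), x = c(0, 10), y = c(0, 0))
  expect_equal(interval_movement(s)$movement_s, 12)

  # displacement sqrt(50) ~ 7.07 exceeds 7
  s2 <- make_series(time_s = c(0, 12), x = c(0, 5), y = c(0, 5))
  expect_equal(interval_movement(s2)$movement_s, 12)

  # displacement exactly 7 does not (strict inequality)
  s3 <- make_series(time_s = c(0, 12), x = c(0, 7), y = c(0, 0))
  expect_equal(interval_movement(s3)$movement_s, 0)

  # identical records never move
  s4 <- make_series(time_s = seq(0, 120, 12), x = rep(9, 11), y = rep(9, 11))
  rec <- interval_movement(s4)
  expect_equal(rec$movement_s, 0)
  expect_equal(rec$n_steps_evaluated, 10)

  # a gap makes the spanned slots unknown, contributing nothing
  s5 <- make_series(time_s = c(0, 12, 48), x = c(0, 100, 300), y = c(0, 0, 0))
  rec5 <- interval_movement(s5)
  expect_equal(rec5$movement_s, 12)
  expect_equal(rec5$n_steps_evaluated, 1)
  expect_equal(rec5$n_steps_unknown, 3)

  expect_error(interval_movement(make_series(numeric(0), numeric(0), numeric(0))),
               class = "zoospace_empty_input")
})

test_that("pose movement applies the 30 px rule on reduced points", {
  tk <- make_track(c(0, 31), c(0, 0))
  expect_equal(pose_movement(tk)$movement_s, 1)
  tk2 <- make_track(c(0, 30), c(0, 0))
  expect_equal(pose_movement(tk2)$movement_s, 0)   # strict "> 30"

  # a frame with neither hip nor shoulder makes both adjacent steps unknown
  tk3 <- make_track(c(0, 100, 200, 300), c(0, 0, 0, 0))
  tk3$frames <- tk3$frames[tk3$frames$frame != 1, ]
  rec <- pose_movement(tk3)
  expect_equal(rec$movement_s, 1)                  # only the 2 -> 3 step counts
  expect_equal(rec$n_steps_evaluated, 1)
  expect_equal(rec$n_steps_unknown, 2)
  expect_equal(rec$session_s, 4)
})

test_that("movement seconds never exceed session seconds and are monotone in threshold", {
  set.seed(9)
  proj <- default_projections(sim_config())
  for (i in 1:12) {
    cfg <- sim_config(duration_s = 120 + sample(0:120, 1), seed = 9000 + i,
                      mean_dwell = sample(c(20, 60, 180), 1))
    tr <- simulate_trajectory(cfg, "ind1")
    iv <- sample_interval_channel(tr, proj$schematic, cfg)
    pt <- sample_pose_channel(tr, proj$camera, cfg)
    iv_m <- vapply(c(0, 3, 7, 15, 40), function(th)
      interval_movement(iv, th)$movement_s, numeric(1))
    ps_m <- vapply(c(0, 10, 30, 60, 200), function(th)
      pose_movement(pt, th)$movement_s, numeric(1))
    expect_true(all(diff(iv_m) <= 0))
    expect_true(all(diff(ps_m) <= 0))
    expect_lte(iv_m[1], interval_movement(iv, 0)$session_s)
    expect_lte(ps_m[1], pose_movement(pt, 0)$session_s)
  }
})

test_that("paired t matches the closed form and elementary invariances", {
  set.seed(4)
  for (i in 1:20) {
    a <- rnorm(6, 100, 20)
    b <- rnorm(6, 100, 20)
    res <- paired_t(a, b)
    d <- a - b
    t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
    p_manual <- 2 * pt(abs(t_manual), df = length(d) - 1, lower.tail = FALSE)
    expect_equal(res$t, t_manual, tolerance = 1e-12)
    expect_equal(res$p, p_manual, tolerance = 1e-12)
    expect_equal(res$df, 5)

    swapped <- paired_t(b, a)
    expect_equal(swapped$t, -res$t)
    expect_equal(swapped$p, res$p)
  }

  expect_error(paired_t(1:6, 1:6 + 5), class = "zoospace_degenerate_test")
  expect_error(paired_t(1:3, 1:4), class = "zoospace_pairing_error")
})

test_that("paired t p-value agrees with exact sign-flip randomization", {
  # With n = 6 the randomization distribution has 2^6 = 64 equally likely
  # sign assignments, so agreement is only expected to its 1/64 resolution.
  # Per-dataset agreement is limited both by that resolution and by the
  # genuine difference between the Student and the randomization reference
  # distributions at n = 6 (measured mean discrepancy ~0.03 for normal
  # shifts), so this asserts consistency at that scale, not equality.
  set.seed(21)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 6)))
  diffs <- vapply(1:20, function(i) {
    d <- rnorm(6, 0.3, 1)
    t_obs <- mean(d) / (sd(d) / sqrt(6))
    t_perm <- apply(signs * rep(d, each = 64), 1, function(z) {
      mean(z) / (sd(z) / sqrt(6))
    })
    p_perm <- mean(abs(t_perm) >= abs(t_obs) - 1e-12)
    abs(paired_t(d, rep(0, 6))$p - p_perm)
  }, numeric(1))
  expect_lt(mean(diffs), 0.05)
  expect_lt(max(diffs), 0.15)
})

test_that("the daily activity report aggregates individuals and runs the test", {
  cfg <- sim_config(duration_s = 600)
  st <- simulate_study(cfg, dates = c("d1", "d2", "d3"),
                       durations_s = 600, seed = 12)
  rep <- activity_report(st$interval, st$pose)
  expect_equal(nrow(rep$daily), 3)
  expect_equal(rep$test$df, 2)
  expect_setequal(unique(rep$records$method), c("interval", "pose"))
  # daily totals really are sums over the two individuals
  d1 <- rep$records[rep$records$date == "d1" & rep$records$method == "pose", ]
  expect_equal(sum(d1$movement_s),
               rep$daily$pose_s_total[rep$daily$date == "d1"])

  # a day present in one channel only is excluded with a warning
  expect_warning(
    rep2 <- activity_report(st$interval[1:6], st$pose[1:4]),
    "one channel only"
  )
  expect_equal(nrow(rep2$daily), 2)

  # stationary sessions: all zero movement, degenerate test surfaced
  sts <- lapply(c("a", "b"), function(d) {
    cfgs <- stationary_config(duration_s = 240, observer_sigma = 0,
                              pose_sigma = 0, p_miss = 0)
    tr <- simulate_trajectory(cfgs, "ind1")
    pj <- default_projections(cfgs)
    list(iv = sample_interval_channel(tr, pj$schematic, cfgs, date = d),
         ps = sample_pose_channel(tr, pj$camera, cfgs, date = d))
  })
  expect_warning(
    rep3 <- activity_report(lapply(sts, `[[`, "iv"), lapply(sts, `[[`, "ps")),
    "constant"
  )
  expect_true(all(rep3$records$movement_s == 0))
  expect_null(rep3$test)
})

test_that("neither method systematically out-measures the other", {
  # mean paired difference across 20 seeded days stays within 10% of the
  # methods' own mean level: the regime in which interval sampling and pose
  # tracking gave comparable activity estimates
  cfg <- sim_config()
  res <- vapply(1:20, function(s) {
    st <- simulate_study(cfg, dates = "d1", durations_s = 3600, seed = 400 + s)
    c(sum(vapply(st$interval, function(x) interval_movement(x)$movement_s,
                 numeric(1))),
      sum(vapply(st$pose, function(x) pose_movement(x)$movement_s,
                 numeric(1))))
  }, numeric(2))
  gap <- mean(res[1, ] - res[2, ])
  expect_lt(abs(gap) / mean(res[1, ]), 0.10)
  expect_lt(abs(gap) / mean(res[2, ]), 0.10)
})

test_that("both channels recover ground-truth activity within 20 percent", {
  cfg <- sim_config()
  st <- simulate_study(cfg, dates = c("d1", "d2"), durations_s = c(3120, 3720),
                       seed = 3)
  for (d in c("d1", "d2")) {
    keys <- grep(paste0("^", d, "/"), names(st$interval), value = TRUE)
    truth <- sum(vapply(st$trajectories[keys], ground_truth_activity,
                        numeric(1), speed_threshold = cfg$transit_speed / 2))
    iv <- sum(vapply(st$interval[keys], function(s)
      interval_movement(s)$movement_s, numeric(1)))
    ps <- sum(vapply(st$pose[keys], function(p)
      pose_movement(p)$movement_s, numeric(1)))
    expect_lt(abs(iv - truth) / truth, 0.2)
    expect_lt(abs(ps - truth) / truth, 0.2)
  }
})
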