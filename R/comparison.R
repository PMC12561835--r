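as_proportions <- function(p) {
  if (inherits(p, "region_distribution")) p$proportions else p
}

#' Percentage overlap between two occupancy distributions
#'
#' Histogram intersection expressed as a percentage:
#' `100 * sum_r min(p_r, q_r)` over the shared ordered region (or cell)
#' partition. Symmetric, bounded in `[0, 100]`, and equal to 100 exactly when
#' the distributions coincide. Equivalently
#' `100 - 50 * sum_r |p_r - q_r|` (the total-variation form, used as an
#' independent oracle in the test suite).
#'
#' @param p,q `region_distribution` objects or named probability vectors
#'   over the same ordered categories.
#' @return Overlap percentage in `[0, 100]`.
#' @export
#' @examples
#' overlap_percent(c(R1 = 0.5, R2 = 0.5, R3 = 0, R4 = 0),
#'                 c(R1 = 0.25, R2 = 0.25, R3 = 0.25, R4 = 0.25))
overlap_percent <- function(p, q) {
  pv <- as_proportions(p)
  qv <- as_proportions(q)
  if (length(pv) != length(qv) ||
      (!is.null(names(pv)) && !is.null(names(qv)) &&
       !identical(names(pv), names(qv)))) {
    zs_abort("distributions must share the same ordered regions",
             "zoospace_key_error")
  }
  100 * sum(pmin(pv, qv))
}

#' Pearson correlation between two occupancy distributions
#'
#' Product-moment correlation over the paired region proportions. A constant
#' vector has no defined correlation; that case raises a zero-variance error
#' rather than being silently coerced.
#'
#' @inheritParams overlap_percent
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_between <- function(p, q) {
  pv <- as_proportions(p)
  qv <- as_proportions(q)
  if (length(pv) != length(qv) ||
      (!is.null(names(pv)) && !is.null(names(qv)) &&
       !identical(names(pv), names(qv)))) {
    zs_abort("distributions must share the same ordered regions",
             "zoospace_key_error")
  }
  if (length(pv) < 2) {
    zs_abort("need at least two regions", "zoospace_key_error")
  }
  if (stats::sd(pv) == 0 || stats::sd(qv) == 0) {
    zs_abort("correlation undefined for a constant region vector",
             "zoospace_zero_variance")
  }
  stats::cor(pv, qv)
}

#' Compare the two observation channels for one day
#'
#' Builds each channel's occupancy distribution — interval records in the
#' schematic view, reduced pose points in the camera view — over the shared
#' region partition and reports the percentage overlap and Pearson
#' correlation. Region granularity is the default (and the only granularity
#' available when the channels live in different views); grid granularity is
#' permitted only when both channels share a view.
#'
#' @param interval A single `interval_series` or list of them (one date).
#' @param pose A single `pose_track` or list of them (same date).
#' @param config An [enclosure_config()].
#' @param granularity `"regions"` (default) or `"grid"`.
#' @return One-row tibble: `date`, `overlap_pct`, `pearson_r` (`NA` when
#'   undefined), `r_defined`, `granularity`, `n_units`, `n_interval`,
#'   `n_pose`.
#' @export
compare_day <- function(interval, pose, config, granularity = c("regions", "grid")) {
  granularity <- match.arg(granularity)
  if (inherits(interval, "interval_series")) interval <- list(interval)
  if (inherits(pose, "pose_track")) pose <- list(pose)
  ip <- interval_points(interval)
  pp <- pose_points(pose)
  if (nrow(ip) == 0 || nrow(pp) == 0) {
    zs_abort("both channels must be nonempty for the date", "zoospace_empty_input")
  }
  date <- interval[[1]]$date
  iv_view <- interval[[1]]$view
  ps_view <- pose[[1]]$view
  if (granularity == "grid") {
    if (!identical(iv_view, ps_view)) {
      zs_abort("grid granularity requires both channels in the same view",
               "zoospace_view_mismatch")
    }
    v <- config$views[[iv_view]]
    gp <- bin_points(ip$x, ip$y, v$image_w, v$image_h,
                     config$grid$nx, config$grid$ny, iv_view)
    gq <- bin_points(pp$x, pp$y, v$image_w, v$image_h,
                     config$grid$nx, config$grid$ny, ps_view)
    pv <- as.vector(gp$density)
    qv <- as.vector(gq$density)
    n_units <- length(pv)
  } else {
    dp <- region_distribution(ip$x, ip$y, config, iv_view)
    dq <- region_distribution(pp$x, pp$y, config, ps_view)
    pv <- dp$proportions
    qv <- dq$proportions
    n_units <- length(pv)
  }
  r <- tryCatch(pearson_between(pv, qv), zoospace_zero_variance = function(e) NA_real_)
  tibble::tibble(
    date = date,
    overlap_pct = overlap_percent(pv, qv),
    pearson_r = r,
    r_defined = !is.na(r),
    granularity = granularity,
    n_units = n_units,
    n_interval = nrow(ip),
    n_pose = nrow(pp)
  )
}

#' Inter-observer percent agreement (concordance test)
#'
#' Fraction of paired categorical assignments (typically region ids recorded
#' by two observers scoring the same session) that agree, as a percentage,
#' with a pass flag at a minimum-agreement threshold. The threshold is
#' inclusive: agreement exactly at the threshold passes.
#'
#' @param records_a,records_b Equal-length vectors of categorical labels.
#' @param threshold Minimum agreement percentage to pass (default 85).
#' @return List with `percent`, `passes`, `n_pairs`, `threshold`.
#' @export
observer_agreement <- function(records_a, records_b, threshold = 85) {
  if (length(records_a) != length(records_b)) {
    zs_abort("observer records must have equal length", "zoospace_pairing_error")
  }
  if (length(records_a) < 1) {
    zs_abort("need at least one pair", "zoospace_pairing_error")
  }
  pct <- 100 * mean(records_a == records_b)
  list(percent = pct, passes = pct >= threshold,
       n_pairs = length(records_a), threshold = threshold)
}
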