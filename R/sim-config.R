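#' Simulation configuration for the synthetic dual-channel generator
#'
#' Defines the world (an indoor enclosure rectangle in metres), the attractor
#' process that moves each individual between space-use hotspots, and the
#' observation-noise parameters of the two recording channels: a manual
#' interval focal-sampling channel on a top-down schematic map, and an
#' automated pose-estimation channel in the camera view.
#'
#' The movement model is a switching hotspot-attractor process: the animal
#' dwells at a hotspot for an exponentially distributed duration (mean
#' `mean_dwell` seconds) with isotropic Gaussian positional jitter
#' (`local_sigma` metres), then picks the next hotspot with probability
#' proportional to its weight and, if it differs from the current one,
#' transits there in a straight line at `transit_speed` m/s.
#'
#' Defaults describe a ~97 m2 enclosure (12.1 m x 8 m) with two hotspots
#' (a climbing structure and a feeding-gutter door placed in opposite
#' corners), a 12 s manual sampling interval and a 1 fps pose channel with a
#' five-node skeleton (head, shoulder, hip, tail1, tail2). The travel speed
#' and the three noise scales are calibrated jointly so that both channels'
#' displacement-threshold movement classifiers operate in the regime the
#' emulated study reports (methods agreeing, with no systematic bias between
#' them); the derivation is in the package vignette.
#'
#' @param enclosure_width,enclosure_height Enclosure size in metres.
#' @param hotspots Data frame with columns `x`, `y` (metres) and `weight`
#'   (probabilities summing to 1).
#' @param mean_dwell Mean dwell duration at a hotspot, seconds.
#' @param transit_speed Straight-line transit speed between hotspots, m/s.
#' @param local_sigma Isotropic jitter of the tracked body point while
#'   dwelling, metres.
#' @param interval_s Manual focal-sampling interval, seconds.
#' @param pose_fps Pose-channel frame rate, frames per second.
#' @param duration_s Session duration in seconds.
#' @param n_individuals Number of simulated individuals.
#' @param observer_sigma Observer placement noise on the schematic map,
#'   schematic pixels.
#' @param pose_sigma Pose-estimation jitter, camera pixels.
#' @param node_offsets Named list of `c(dx, dy)` camera-pixel offsets of the
#'   five skeleton nodes from the body centre.
#' @param p_miss Per-node, per-frame probability of a missed detection.
#' @param score_params `c(shape1, shape2)` of the Beta distribution that
#'   confidence scores are drawn from.
#' @param seed Integer seed; all samplers derive deterministic sub-streams
#'   from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(duration_s = 600)
#' cfg$hotspots
sim_config <- function(enclosure_width = 12.1,
                       enclosure_height = 8,
                       hotspots = data.frame(
                         x = c(0.4, 11.7),
                         y = c(7.6, 0.4),
                         weight = c(0.65, 0.35)
                       ),
                       mean_dwell = 180,
                       transit_speed = 0.19,
                       local_sigma = 0.01,
                       interval_s = 12,
                       pose_fps = 1,
                       duration_s = 3720,
                       n_individuals = 2,
                       observer_sigma = 1.2,
                       pose_sigma = 4,
                       node_offsets = list(
                         head = c(0, -25), shoulder = c(0, -12), hip = c(0, 0),
                         tail1 = c(0, 14), tail2 = c(0, 28)
                       ),
                       p_miss = 0.1,
                       score_params = c(shape1 = 8, shape2 = 2),
                       seed = 1L) {
  cfg <- list(
    enclosure_width = enclosure_width, enclosure_height = enclosure_height,
    hotspots = as.data.frame(hotspots), mean_dwell = mean_dwell,
    transit_speed = transit_speed, local_sigma = local_sigma,
    interval_s = interval_s, pose_fps = pose_fps, duration_s = duration_s,
    n_individuals = n_individuals, observer_sigma = observer_sigma,
    pose_sigma = pose_sigma, node_offsets = node_offsets, p_miss = p_miss,
    score_params = score_params, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  h <- cfg$hotspots
  if (!all(c("x", "y", "weight") %in% names(h)) || nrow(h) < 1) {
    zs_abort("hotspots must have columns x, y, weight", "zoospace_invalid_config")
  }
  if (any(h$weight < 0) || abs(sum(h$weight) - 1) > 1e-9) {
    zs_abort("hotspot weights must be nonnegative and sum to 1",
             "zoospace_invalid_config")
  }
  if (any(h$x < 0 | h$x > cfg$enclosure_width |
          h$y < 0 | h$y > cfg$enclosure_height)) {
    zs_abort("hotspots must lie inside the enclosure rectangle",
             "zoospace_invalid_config")
  }
  if (cfg$mean_dwell <= 0 || cfg$transit_speed <= 0 || cfg$duration_s <= 0) {
    zs_abort("mean_dwell, transit_speed and duration_s must be positive",
             "zoospace_invalid_config")
  }
  if (cfg$p_miss < 0 || cfg$p_miss > 1) {
    zs_abort("p_miss must be in [0, 1]", "zoospace_invalid_config")
  }
  if (cfg$local_sigma < 0 || cfg$observer_sigma < 0 || cfg$pose_sigma < 0) {
    zs_abort("noise sigmas must be nonnegative", "zoospace_invalid_config")
  }
  if (cfg$interval_s <= 0 || cfg$pose_fps <= 0) {
    zs_abort("interval_s and pose_fps must be positive", "zoospace_invalid_config")
  }
  required_nodes <- c("head", "shoulder", "hip", "tail1", "tail2")
  if (!setequal(names(cfg$node_offsets), required_nodes)) {
    zs_abort("node_offsets must name exactly head, shoulder, hip, tail1, tail2",
             "zoospace_invalid_config")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  enclosure: %.1f x %.1f m, %d hotspot(s)\n",
              x$enclosure_width, x$enclosure_height, nrow(x$hotspots)))
  cat(sprintf("  dwell %.0f s | transit %.2f m/s | jitter %.3f m\n",
              x$mean_dwell, x$transit_speed, x$local_sigma))
  cat(sprintf("  channels: interval %g s (obs sd %g px) | pose %g fps (sd %g px, p_miss %g)\n",
              x$interval_s, x$observer_sigma, x$pose_fps, x$pose_sigma, x$p_miss))
  invisible(x)
}

#' Affine projection from world metres to a view's pixel frame
#'
#' Maps world coordinates `(x, y)` (metres, origin bottom-left, y up) to view
#' pixels `(a*x + b*y + c, d*x + e*y + f)` with the image convention (origin
#' top-left, y down). The linear part must be invertible.
#'
#' @param view_id View label, conventionally `"schematic"` or `"camera"`
#'   (`"world"` denotes the identity metre frame).
#' @param a,b,c,d,e,f Affine coefficients.
#' @param image_w,image_h View image size in pixels.
#' @return A `view_projection` object.
#' @export
view_projection <- function(view_id, a, b, c, d, e, f, image_w, image_h) {
  det <- a * e - b * d
  if (abs(det) < 1e-12) {
    zs_abort("projection linear part is singular", "zoospace_invalid_config")
  }
  structure(
    list(view_id = view_id, a = a, b = b, c = c, d = d, e = e, f = f,
         image_w = image_w, image_h = image_h),
    class = "view_projection"
  )
}

#' Apply a view projection to world coordinates
#'
#' @param proj A [view_projection()].
#' @param x,y World coordinates (metres).
#' @return A list with pixel vectors `x` and `y`.
#' @export
project_points <- function(proj, x, y) {
  list(x = proj$a * x + proj$b * y + proj$c,
       y = proj$d * x + proj$e * y + proj$f)
}

#' Default projections for the two synthetic observation channels
#'
#' The schematic view renders the enclosure at 33 px/m on a small top-down
#' map; the camera view renders it at 267 px/m into a 4K frame (both
#' y-flipped to image convention, enclosure centred). Both are plain affine
#' maps: the analysis compares channels at region granularity, where
#' perspective realism in the camera view would not change assignments.
#'
#' @param config A [sim_config()] (supplies enclosure size).
#' @return Named list with `schematic`, `camera` and `world` projections.
#' @export
default_projections <- function(config = sim_config()) {
  w <- config$enclosure_width
  h <- config$enclosure_height
  s_sch <- 33
  sch_w <- ceiling(w * s_sch)
  sch_h <- ceiling(h * s_sch)
  s_cam <- 267
  cam_w <- 3840
  cam_h <- 2160
  off_x <- (cam_w - w * s_cam) / 2
  off_y <- (cam_h - h * s_cam) / 2
  list(
    schematic = view_projection("schematic",
                                a = s_sch, b = 0, c = (sch_w - w * s_sch) / 2,
                                d = 0, e = -s_sch, f = sch_h - (sch_h - h * s_sch) / 2,
                                image_w = sch_w, image_h = sch_h),
    camera = view_projection("camera",
                             a = s_cam, b = 0, c = off_x,
                             d = 0, e = -s_cam, f = cam_h - off_y,
                             image_w = cam_w, image_h = cam_h),
    world = view_projection("world",
                            a = 1, b = 0, c = 0, d = 0, e = 1, f = 0,
                            image_w = w, image_h = h)
  )
}
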