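#' Reduce one frame's node detections to a single body point
#'
#' A frame is represented by whichever of the hip and shoulder nodes carries
#' the higher confidence score (ties go to the hip); frames with neither node
#' detected reduce to nothing. Head and tail nodes never represent the body
#' position.
#'
#' @param nodes Data frame / tibble with columns `node`, `x`, `y`, `score`
#'   for a single frame.
#' @return A one-row tibble (`x`, `y`, `source_node`, `score`) or `NULL` when
#'   no eligible node is present.
#' @export
#' @examples
#' reduce_pose(data.frame(node = c("hip", "shoulder"), x = c(1, 2),
#'                        y = c(1, 2), score = c(0.9, 0.7)))
reduce_pose <- function(nodes) {
  el <- nodes[nodes$node %in% c("hip", "shoulder"), , drop = FALSE]
  if (nrow(el) == 0) return(NULL)
  ## order: score descending, hip before shoulder on ties
  el <- el[order(-el$score, el$node != "hip"), , drop = FALSE]
  tibble::tibble(x = el$x[[1]], y = el$y[[1]],
                 source_node = el$node[[1]], score = el$score[[1]])
}

#' Reduce every frame of a pose track
#'
#' Vectorized application of the [reduce_pose()] rule across a track.
#'
#' @param track A `pose_track`.
#' @return Tibble with one row per reducible frame: `frame`, `time_s`, `x`,
#'   `y`, `source_node`, `score`; attribute `n_frames_missing` counts frames
#'   with neither hip nor shoulder (including fully dropped frames).
#' @export
reduce_track <- function(track) {
  f <- track$frames
  el <- f[f$node %in% c("hip", "shoulder"), , drop = FALSE]
  if (nrow(el) == 0) {
    out <- tibble::tibble(frame = integer(0), time_s = numeric(0),
                          x = numeric(0), y = numeric(0),
                          source_node = character(0), score = numeric(0))
    attr(out, "n_frames_missing") <- track$n_frames
    return(out)
  }
  el <- el[order(el$frame, -el$score, el$node != "hip"), , drop = FALSE]
  el <- el[!duplicated(el$frame), , drop = FALSE]
  out <- tibble::tibble(frame = el$frame, time_s = el$time_s,
                        x = el$x, y = el$y,
                        source_node = el$node, score = el$score)
  attr(out, "n_frames_missing") <- track$n_frames - nrow(out)
  out
}

#' Bin points into a grid occupancy heatmap
#'
#' Counts points into an `nx` x `ny` grid over the view image using half-open
#' bins `[x0, x1)` (a point exactly on an interior edge belongs to the higher
#' bin); the last bin in each axis is closed so the image boundary stays in
#' range. Points outside the image are rejected and counted.
#'
#' @param x,y Point coordinates in view pixels.
#' @param image_w,image_h View image size in pixels.
#' @param nx,ny Bin counts (default 50 x 50, enough to resolve enclosure
#'   hotspots without starving cells at typical session sizes of a few
#'   hundred to a few thousand points).
#' @param view_id View label stored on the result.
#' @return An `occupancy_grid`: list with `counts` and `density` matrices
#'   (`nx` rows, `ny` columns), `n_points`, `n_rejected`, `view_id`.
#' @export
bin_points <- function(x, y, image_w, image_h, nx = 50, ny = 50,
                       view_id = "view") {
  if (nx < 1 || ny < 1) {
    zs_abort("nx and ny must be >= 1", "zoospace_invalid_config")
  }
  ok <- x >= 0 & x <= image_w & y >= 0 & y <= image_h
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    message(sprintf("bin_points: rejected %d out-of-bounds point(s)", n_rejected))
  }
  x <- x[ok]; y <- y[ok]
  ix <- pmin(floor(x * nx / image_w) + 1, nx)
  iy <- pmin(floor(y * ny / image_h) + 1, ny)
  counts <- matrix(0L, nx, ny)
  if (length(ix) > 0) {
    tab <- table(factor(ix, levels = seq_len(nx)), factor(iy, levels = seq_len(ny)))
    counts <- matrix(as.integer(tab), nx, ny)
  }
  total <- sum(counts)
  density <- if (total > 0) counts / total else matrix(0, nx, ny)
  structure(
    list(counts = counts, density = density, n_points = total,
         n_rejected = n_rejected, view_id = view_id),
    class = "occupancy_grid"
  )
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("<occupancy_grid> %s: %dx%d bins, %d points (%d rejected)\n",
              x$view_id, nrow(x$counts), ncol(x$counts),
              x$n_points, x$n_rejected))
  invisible(x)
}

## Boundary-inclusive point-in-polygon (sp returns 0 outside, 1 inside,
## 2 on an edge, 3 on a vertex).
point_in_region <- function(x, y, poly) {
  sp::point.in.polygon(x, y, poly[, 1], poly[, 2]) > 0
}

#' Region-level occupancy distribution
#'
#' Assigns each point to the first region (configuration order) whose polygon
#' contains it, boundary inclusive, and returns the proportion of in-region
#' points per region. Points contained by no region are counted in
#' `n_outside` and excluded; proportions are renormalized over in-region
#' points (out-of-region points usually indicate a configuration problem and
#' are surfaced, never snapped to the nearest region).
#'
#' @param x,y Point coordinates in `view` pixels.
#' @param config An [enclosure_config()].
#' @param view View id whose region polygons the points live in.
#' @return A `region_distribution`: list with named `proportions` (ordered as
#'   in the config, summing to 1), `n_points` (in-region), `n_outside`,
#'   `view_id`.
#' @export
region_distribution <- function(x, y, config, view) {
  rids <- names(config$regions)
  if (length(rids) == 0) {
    zs_abort("config defines no regions", "zoospace_invalid_config")
  }
  assigned <- rep(NA_integer_, length(x))
  for (i in seq_along(rids)) {
    poly <- config$regions[[i]][[view]]
    if (is.null(poly)) {
      zs_abort(sprintf("region %s has no polygon for view %s", rids[[i]], view),
               "zoospace_invalid_config")
    }
    todo <- is.na(assigned)
    if (!any(todo)) break
    hit <- point_in_region(x[todo], y[todo], poly)
    assigned[todo][hit] <- i
  }
  n_outside <- sum(is.na(assigned))
  n_in <- length(assigned) - n_outside
  if (n_in == 0) {
    zs_abort("no points fall inside any region", "zoospace_degenerate_distribution")
  }
  counts <- tabulate(assigned[!is.na(assigned)], nbins = length(rids))
  props <- counts / n_in
  names(props) <- rids
  structure(
    list(proportions = props, n_points = n_in, n_outside = n_outside,
         view_id = view),
    class = "region_distribution"
  )
}

#' @export
print.region_distribution <- function(x, ...) {
  cat(sprintf("<region_distribution> %s (n = %d, outside = %d)\n",
              x$view_id, x$n_points, x$n_outside))
  print(round(x$proportions, 4))
  invisible(x)
}

#' Pooled channel points for a set of sessions
#'
#' Convenience extractors pooling the positions of one or more sessions of a
#' channel: interval records as-is, pose tracks reduced via [reduce_track()].
#'
#' @param series A single `interval_series` or a list of them.
#' @return Tibble with columns `x`, `y` (and session labels).
#' @export
interval_points <- function(series) {
  if (inherits(series, "interval_series")) series <- list(series)
  dplyr::bind_rows(lapply(series, function(s) {
    tibble::tibble(date = s$date, id = s$focal_id,
                   time_s = s$records$time_s, x = s$records$x, y = s$records$y)
  }))
}

#' @param tracks A single `pose_track` or a list of them.
#' @rdname interval_points
#' @export
pose_points <- function(tracks) {
  if (inherits(tracks, "pose_track")) tracks <- list(tracks)
  dplyr::bind_rows(lapply(tracks, function(t) {
    r <- reduce_track(t)
    tibble::tibble(date = t$date, id = t$track_id,
                   time_s = r$time_s, x = r$x, y = r$y)
  }))
}

#' Plot an occupancy grid as a heatmap
#'
#' @param grid An `occupancy_grid`.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_occupancy <- function(grid) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    zs_abort("plot_occupancy requires ggplot2", "zoospace_missing_dependency")
  }
  d <- expand.grid(ix = seq_len(nrow(grid$density)),
                   iy = seq_len(ncol(grid$density)))
  d$density <- as.vector(grid$density)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ix, y = .data$iy,
                                  fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "density",
                  title = sprintf("Occupancy (%s)", grid$view_id))
}
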