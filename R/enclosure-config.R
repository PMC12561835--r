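#' Enclosure configuration: views, region partition, grid
#'
#' Holds the pixel dimensions of each observation view, the shared region
#' partition (the same ordered region ids, each with one polygon per view:
#' the only spatial vocabulary the two channels have in common), and the
#' occupancy grid resolution.
#'
#' @param views Named list `view_id -> list(image_w, image_h)`.
#' @param regions Ordered named list `region_id -> list(view_id -> polygon)`,
#'   each polygon a two-column matrix (or list of `c(x, y)` pairs) of vertices
#'   in that view's pixels. Region ids must be identical across views and
#'   polygons must be simple (non-self-intersecting).
#' @param grid List with bin counts `nx`, `ny` (default 50 x 50).
#' @return An `enclosure_config` object.
#' @export
enclosure_config <- function(views, regions, grid = list(nx = 50, ny = 50)) {
  regions <- lapply(regions, function(r) lapply(r, as_polygon_matrix))
  cfg <- structure(list(views = views, regions = regions, grid = grid),
                   class = "enclosure_config")
  validate_enclosure_config(cfg)
  cfg
}

as_polygon_matrix <- function(p) {
  if (is.matrix(p)) {
    m <- p
  } else {
    m <- do.call(rbind, lapply(p, function(v) as.numeric(unlist(v))))
  }
  if (ncol(m) != 2 || nrow(m) < 3) {
    zs_abort("polygons need >= 3 vertices of (x, y)", "zoospace_invalid_config")
  }
  colnames(m) <- c("x", "y")
  m
}

validate_enclosure_config <- function(cfg) {
  if (length(cfg$views) < 1) {
    zs_abort("at least one view is required", "zoospace_invalid_config")
  }
  if (is.null(cfg$grid$nx) || is.null(cfg$grid$ny) ||
      cfg$grid$nx < 1 || cfg$grid$ny < 1) {
    zs_abort("grid nx and ny must be >= 1", "zoospace_invalid_config")
  }
  view_ids <- names(cfg$views)
  for (rid in names(cfg$regions)) {
    r <- cfg$regions[[rid]]
    if (!all(view_ids %in% names(r))) {
      zs_abort(sprintf("region %s lacks a polygon for some view", rid),
               "zoospace_invalid_config")
    }
    for (v in names(r)) {
      if (!polygon_is_simple(r[[v]])) {
        zs_abort(sprintf("region %s polygon in view %s self-intersects", rid, v),
                 "zoospace_invalid_config")
      }
    }
  }
  invisible(cfg)
}

## Simple-polygon check: no two non-adjacent edges may properly intersect.
polygon_is_simple <- function(m) {
  n <- nrow(m)
  a <- m
  b <- m[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through the closing edge
      if (segments_cross(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Default four-region enclosure configuration for the synthetic study
#'
#' Builds the quadrant partition (`R1` upper-left, `R2` upper-right, `R3`
#' lower-left, `R4` lower-right, in world orientation, split at the enclosure
#' centre) projected into the schematic, camera and world views produced by
#' [default_projections()]. The `world` view carries the region polygons in
#' metres so that ground-truth trajectories can be assigned to the same
#' partition as the two observation channels.
#'
#' @param config A [sim_config()].
#' @param centre Optional world `c(x, y)` of the partition crossing point
#'   (defaults to the enclosure centre).
#' @return An [enclosure_config()].
#' @export
default_enclosure_config <- function(config = sim_config(), centre = NULL) {
  proj <- default_projections(config)
  w <- config$enclosure_width
  h <- config$enclosure_height
  c_xy <- centre %||% c(w / 2, h / 2)
  quads <- list(
    R1 = rbind(c(0, c_xy[2]), c(c_xy[1], c_xy[2]), c(c_xy[1], h), c(0, h)),
    R2 = rbind(c(c_xy[1], c_xy[2]), c(w, c_xy[2]), c(w, h), c(c_xy[1], h)),
    R3 = rbind(c(0, 0), c(c_xy[1], 0), c(c_xy[1], c_xy[2]), c(0, c_xy[2])),
    R4 = rbind(c(c_xy[1], 0), c(w, 0), c(w, c_xy[2]), c(c_xy[1], c_xy[2]))
  )
  regions <- lapply(quads, function(q) {
    lapply(proj, function(p) {
      px <- project_points(p, q[, 1], q[, 2])
      cbind(x = px$x, y = px$y)
    })
  })
  views <- lapply(proj, function(p) list(image_w = p$image_w, image_h = p$image_h))
  enclosure_config(views = views, regions = regions)
}

#' Read or write an enclosure configuration (YAML or JSON)
#'
#' The on-disk shape mirrors the constructor: `views` (per-view image sizes),
#' `regions` (per-region, per-view vertex lists) and `grid`. The format is
#' chosen from the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path File path.
#' @return [read_enclosure_config()] returns an [enclosure_config()];
#'   `write_enclosure_config()` returns `path` invisibly.
#' @export
read_enclosure_config <- function(path) {
  if (!file.exists(path)) {
    zs_abort(paste("no such file:", path), "zoospace_format_error")
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  if (is.null(raw$views) || is.null(raw$regions)) {
    zs_abort("config must contain 'views' and 'regions'", "zoospace_format_error")
  }
  enclosure_config(
    views = raw$views,
    regions = raw$regions,
    grid = raw$grid %||% list(nx = 50, ny = 50)
  )
}

#' @param config An [enclosure_config()] to serialize.
#' @rdname read_enclosure_config
#' @export
write_enclosure_config <- function(config, path) {
  out <- list(
    views = config$views,
    regions = lapply(config$regions, function(r) {
      lapply(r, function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ])))
    }),
    grid = config$grid
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(out, path)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @export
print.enclosure_config <- function(x, ...) {
  cat(sprintf("<enclosure_config> %d view(s): %s | regions: %s | grid %dx%d\n",
              length(x$views), paste(names(x$views), collapse = ", "),
              paste(names(x$regions), collapse = ", "),
              x$grid$nx, x$grid$ny))
  invisible(x)
}
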