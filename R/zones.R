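#' Time and distance occupancy of a region
#'
#' `time_fraction` is the frame-weighted dwell time in the region divided by
#' the window duration. `distance_fraction` assigns each step to the region
#' containing its midpoint (steps are not split), and divides the in-region
#' path length by the total path length in the window. Both indices are
#' invariant to time-reversal of the trajectory.
#'
#' @param traj A [trajectory()].
#' @param reg An [region()] inside the trajectory's arena.
#' @param window `c(t0, t1)` in seconds; default is the full span.
#' @return An object of class `zone_occupancy` with fields `region`,
#'   `time_fraction`, `distance_fraction`, `dwell_s`, `window`.
#' @export
zone_occupancy <- function(traj, reg, window = NULL) {
  stopifnot(inherits(traj, "swim_trajectory"), inherits(reg, "arena_region"))
  sp <- traj_span(traj)
  if (is.null(window)) window <- sp
  if (window[1] >= window[2] || window[1] < sp[1] - 1e-9 ||
      window[2] > sp[2] + 1e-9)
    stop("window outside trajectory span")
  inw <- traj$t_s >= window[1] & traj$t_s <= window[2] & !traj$missing
  n_inw <- sum(inw)
  tf <- if (n_inw == 0) NA_real_ else
    sum(region_contains(reg, traj$x_mm[inw], traj$y_mm[inw])) / n_inw
  st <- step_table(traj)
  frac <- if (nrow(st))
    pmax(0, pmin(window[2], st$b) - pmax(window[1], st$a)) / (st$b - st$a)
  else numeric(0)
  tot <- sum(st$d * frac)
  din <- if (nrow(st))
    sum(st$d * frac * region_contains(reg, st$mx, st$my)) else 0
  structure(list(region = reg$name,
                 time_fraction = tf,
                 distance_fraction = if (tot > 0) din / tot else NA_real_,
                 dwell_s = if (is.na(tf)) NA_real_ else
                   tf * (window[2] - window[1]),
                 window = window),
            class = "zone_occupancy")
}

#' @export
print.zone_occupancy <- function(x, ...) {
  cat(sprintf("<zone_occupancy> region '%s': time %.3f, distance %.3f over [%g, %g] s\n",
              x$region, x$time_fraction, x$distance_fraction,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Social-preference occupancy
#'
#' Occupancy of the social strip of the mating tank (the region named
#' `"social"` in the arena). Both the in-region indices and their "away"
#' complements are returned: the published "distance spent away from the
#' social area" is mirrored here as `1 - distance_fraction`.
#'
#' @param traj A [trajectory()] recorded in an arena with a `"social"` region.
#' @param window `c(t0, t1)` in seconds; default full span.
#' @return A `social_preference` object: a [zone_occupancy()] plus
#'   `away_time_fraction` and `away_distance_fraction`.
#' @export
social_preference <- function(traj, window = NULL) {
  stopifnot(inherits(traj, "swim_trajectory"))
  soc <- traj$arena$regions[["social"]]
  if (is.null(soc))
    stop(sprintf("arena '%s' has no 'social' region; use make_standard_arena('mating_tank')",
                 traj$arena$arena_id))
  occ <- zone_occupancy(traj, soc, window)
  occ$away_time_fraction <- 1 - occ$time_fraction
  occ$away_distance_fraction <- 1 - occ$distance_fraction
  class(occ) <- c("social_preference", class(occ))
  occ
}

#' Dwell-time occupancy heatmap
#'
#' Accumulates frame dwell time (seconds) on a square grid covering the
#' arena bounding box. Multiple trajectories accumulate into the same grid;
#' total cell mass equals the summed recording durations to within one frame
#' interval per trajectory.
#'
#' @param trajs A [trajectory()] or list of them sharing one arena.
#' @param grid_mm Cell edge in mm (>= 1); the conventional defaults are 5 mm
#'   for tanks and 0.5 mm for wells (pass explicitly for wells).
#' @return An object of class `occupancy_heatmap`: `cell_mm`, `origin`,
#'   `dwell_s` (matrix, rows = y from bottom, cols = x from left),
#'   `arena_id`.
#' @export
occupancy_heatmap <- function(trajs, grid_mm = 5) {
  if (inherits(trajs, "swim_trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1,
            all(vapply(trajs, inherits, logical(1), "swim_trajectory")))
  if (grid_mm < 1) stop("grid_mm must be >= 1 mm")
  arena <- trajs[[1]]$arena
  bb <- arena_bbox(arena)
  nx <- ceiling((bb["x1"] - bb["x0"]) / grid_mm - 1e-9)
  ny <- ceiling((bb["y1"] - bb["y0"]) / grid_mm - 1e-9)
  m <- matrix(0, nrow = ny, ncol = nx)
  for (tr in trajs) {
    if (!identical(tr$arena$arena_id, arena$arena_id))
      stop("all trajectories must share one arena")
    dt <- 1 / tr$frame_rate_hz
    ok <- !tr$missing
    ix <- pmin(pmax(floor((tr$x_mm[ok] - bb["x0"]) / grid_mm), 0), nx - 1)
    iy <- pmin(pmax(floor((tr$y_mm[ok] - bb["y0"]) / grid_mm), 0), ny - 1)
    cell <- iy + ny * ix + 1
    agg <- rowsum(rep(dt, length(cell)), cell)
    m[as.integer(rownames(agg))] <- m[as.integer(rownames(agg))] + agg[, 1]
  }
  structure(list(cell_mm = grid_mm, origin = c(bb["x0"], bb["y0"]),
                 dwell_s = m, arena_id = arena$arena_id),
            class = "occupancy_heatmap")
}

#' @export
print.occupancy_heatmap <- function(x, ...) {
  cat(sprintf("<occupancy_heatmap> arena '%s': %d x %d cells of %g mm, total %.1f s\n",
              x$arena_id, ncol(x$dwell_s), nrow(x$dwell_s), x$cell_mm,
              sum(x$dwell_s)))
  invisible(x)
}

#' Write a heatmap as a plain-text matrix
#'
#' First line is a `#`-prefixed header with the grid spec; the matrix follows
#' as tab-separated dwell seconds, rows from the top of the arena down (image
#' convention).
#'
#' @param hm An [occupancy_heatmap()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(hm, path) {
  stopifnot(inherits(hm, "occupancy_heatmap"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# occupancy_heatmap arena=%s cell_mm=%g x0=%g y0=%g nx=%d ny=%d",
                     hm$arena_id, hm$cell_mm, hm$origin[1], hm$origin[2],
                     ncol(hm$dwell_s), nrow(hm$dwell_s)), con)
  m <- hm$dwell_s[rev(seq_len(nrow(hm$dwell_s))), , drop = FALSE]
  utils::write.table(format(m, trim = TRUE, digits = 10), con,
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @export
plot.occupancy_heatmap <- function(x, ...) {
  nx <- ncol(x$dwell_s); ny <- nrow(x$dwell_s)
  graphics::image(x = x$origin[1] + (0:nx) * x$cell_mm,
                  y = x$origin[2] + (0:ny) * x$cell_mm,
                  z = t(x$dwell_s), xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("dwell time (s), arena %s", x$arena_id),
                  useRaster = TRUE, asp = 1, ...)
  invisible(x)
}
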