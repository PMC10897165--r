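# Independent oracles and small fixture builders shared across tests.

# A large rectangular arena for free-space trajectory fixtures.
big_arena <- function() {
  arena_geometry("bigbox", "rectangle", width_mm = 1000, height_mm = 1000,
                 edge_band_mm = 35)
}

# Build a trajectory from raw coordinate vectors at a fixed frame rate.
mk_traj <- function(x, y, fps = 25, arena = big_arena(), fish_id = "f1") {
  trajectory(fish_id, arena, t_s = (seq_along(x) - 1) / fps,
             x_mm = x, y_mm = y, frame_rate_hz = fps)
}

# Constant-speed straight-line trajectory.
straight_traj <- function(speed_mm_s, duration_s, fps = 25,
                          origin = c(100, 100), dir = c(1, 0),
                          arena = big_arena()) {
  n <- round(duration_s * fps)
  t <- (0:n) / fps
  mk_traj(origin[1] + speed_mm_s * t * dir[1],
          origin[2] + speed_mm_s * t * dir[2], fps, arena)
}

# Trajectory moving on a circle of given radius/angular speed, centred in
# its own circular arena (used for chord-sum checks and circling tests).
circle_traj <- function(radius, omega, duration_s, fps = 25,
                        arena = NULL, center = c(0, 0), phase = 0) {
  if (is.null(arena))
    arena <- arena_geometry("disc", "circle", radius_mm = radius + 5,
                            edge_band_mm = min(radius, 4.9))
  n <- round(duration_s * fps)
  th <- phase + omega * (0:n) / fps
  trajectory("f1", arena, (0:n) / fps,
             center[1] + radius * cos(th), center[2] + radius * sin(th),
             frame_rate_hz = fps)
}

# Brute-force chord-sum oracle for path distance of an analytic circle.
chord_sum_oracle <- function(radius, omega, duration_s, fps) {
  n <- round(duration_s * fps)
  n * 2 * radius * abs(sin(omega / fps / 2))
}

# O(n^2) all-pairs greedy oracle for stereotypic bouts: computes the full
# distance matrix and grows windows left to right with exact spans.
oracle_stereo <- function(ts, xs, ys, max_span = 30, min_dur = 5) {
  n <- length(ts)
  D <- as.matrix(stats::dist(cbind(xs, ys)))
  res <- list()
  s <- 1L; e <- 1L
  span_cur <- 0
  while (e < n) {
    cand <- max(span_cur, max(D[s:e, e + 1]))
    if (cand < max_span) {
      span_cur <- cand
      e <- e + 1L
      next
    }
    if (ts[e] - ts[s] > min_dur) {
      res[[length(res) + 1]] <- c(start = ts[s], end = ts[e])
      s <- e + 1L
    } else {
      while (max(D[s:(e + 1), s:(e + 1)]) >= max_span) s <- s + 1L
    }
    e <- e + 1L
    span_cur <- if (e > s) max(D[s:e, s:e]) else 0
  }
  if (e <= n && e > s && ts[e] - ts[s] > min_dur)
    res[[length(res) + 1]] <- c(start = ts[s], end = ts[e])
  if (!length(res)) return(data.frame(start_s = numeric(), end_s = numeric()))
  m <- do.call(rbind, res)
  data.frame(start_s = m[, 1], end_s = m[, 2])
}

# Winding-number oracle: total signed angle about a centre, summed from
# wrapped atan2 increments.
winding_total <- function(xs, ys, cx = 0, cy = 0) {
  th <- atan2(ys - cy, xs - cx)
  d <- diff(th)
  d <- ((d + pi) %% (2 * pi)) - pi
  sum(d)
}

# Random correlated walk coordinates (no arena interaction) for property
# tests.
random_walk_xy <- function(n, step_scale, start = c(500, 500)) {
  h <- cumsum(stats::rnorm(n, 0, 0.4))
  st <- abs(stats::rnorm(n, step_scale, step_scale / 3))
  x <- start[1] + cumsum(st * cos(h))
  y <- start[2] + cumsum(st * sin(h))
  list(x = c(start[1], x), y = c(start[2], y))
}
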