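#' Agent parameters for the swim simulator
#'
#' Parameters of the correlated-random-walk agent. Speeds are drawn per frame
#' from a gamma distribution with the given mean and shape; the heading
#' receives wrapped-normal noise each step and is steered by convex blending
#' toward the tangential/approach direction of the nearest wall (weight
#' `wall_bias`), toward the social-region centre (weight `social_weight`) and,
#' in shoals, toward the group centroid (weight `cohesion`). Speed is
#' multiplied by `dark_multiplier` during dark epochs. `bout_rates` are
#' Poisson rates (events per minute) of injected repetitive-behavior bouts.
#'
#' The boundary reflects the position; after a wall contact the heading is
#' redirected toward the arena interior with angular scatter of SD
#' `wall_scatter_rad` (a collision-avoidance turn). Fish do not bounce like
#' billiard balls, and specular or tangential boundary schemes make the
#' walk retrace itself along walls far more often than animals do.
#'
#' @param mean_speed_mm_s Mean swim speed, mm/s.
#' @param speed_shape Gamma shape of the per-frame speed distribution.
#' @param turn_sd_rad Per-step heading noise SD, radians.
#' @param wall_bias Wall-following weight in `[0, 1]` (0 ignores walls,
#'   1 is hard wall-following).
#' @param dark_multiplier Speed factor applied in dark epochs (> 0).
#' @param social_weight Attraction weight toward the social region, `[0, 1]`.
#' @param cohesion Attraction weight toward the shoal centroid, `[0, 1]`.
#' @param wall_scatter_rad SD of the extra heading scatter applied on wall
#'   reflection, radians (default 0.8).
#' @param bout_rates Named numeric vector, events/min, names among
#'   `back_and_forth`, `stereotypic`, `large_circle`.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(mean_speed_mm_s = 40, speed_shape = 4,
                         turn_sd_rad = 0.3, wall_bias = 0.2,
                         dark_multiplier = 1, social_weight = 0,
                         cohesion = 0, wall_scatter_rad = 0.8,
                         bout_rates = c(back_and_forth = 0, stereotypic = 0,
                                        large_circle = 0)) {
  chk01 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      stop(sprintf("%s must lie in [0, 1]", nm))
  }
  if (mean_speed_mm_s <= 0) stop("mean_speed_mm_s must be > 0")
  if (speed_shape <= 0) stop("speed_shape must be > 0")
  if (turn_sd_rad < 0) stop("turn_sd_rad must be >= 0")
  if (wall_scatter_rad < 0) stop("wall_scatter_rad must be >= 0")
  chk01(wall_bias, "wall_bias")
  chk01(social_weight, "social_weight")
  chk01(cohesion, "cohesion")
  if (dark_multiplier <= 0) stop("dark_multiplier must be > 0")
  br <- c(back_and_forth = 0, stereotypic = 0, large_circle = 0)
  if (length(bout_rates)) {
    if (is.null(names(bout_rates)) ||
        !all(names(bout_rates) %in% names(br)))
      stop("bout_rates must be named among back_and_forth, stereotypic, large_circle")
    if (any(bout_rates < 0)) stop("bout_rates must be >= 0")
    br[names(bout_rates)] <- bout_rates
  }
  structure(list(mean_speed_mm_s = mean_speed_mm_s, speed_shape = speed_shape,
                 turn_sd_rad = turn_sd_rad, wall_bias = wall_bias,
                 dark_multiplier = dark_multiplier,
                 social_weight = social_weight, cohesion = cohesion,
                 wall_scatter_rad = wall_scatter_rad, bout_rates = br),
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf(paste0("<agent_params> speed %g mm/s (shape %g), turn sd %g rad, ",
                     "wall bias %g, dark x%g, social %g, cohesion %g, ",
                     "bout rates/min [bnf %g, stereo %g, circle %g]\n"),
              x$mean_speed_mm_s, x$speed_shape, x$turn_sd_rad, x$wall_bias,
              x$dark_multiplier, x$social_weight, x$cohesion,
              x$bout_rates["back_and_forth"], x$bout_rates["stereotypic"],
              x$bout_rates["large_circle"]))
  invisible(x)
}

arena_cpp_args <- function(arena) {
  if (arena$shape == "circle")
    list(shape = 0L, R = arena$radius_mm, W = 0, H = 0)
  else
    list(shape = 1L, R = 0, W = arena$width_mm, H = arena$height_mm)
}

region_center <- function(reg) {
  p <- reg$params
  switch(reg$kind,
         disk = c(p$cx, p$cy),
         annulus = c(p$cx, p$cy),
         rectangle = c((p$x0 + p$x1) / 2, (p$y0 + p$y1) / 2),
         stop("no centre defined for region kind ", reg$kind))
}

draw_speeds <- function(n, params) {
  stats::rgamma(n, shape = params$speed_shape,
                rate = params$speed_shape / params$mean_speed_mm_s)
}

random_start <- function(arena) {
  if (arena$shape == "circle") {
    r <- sqrt(stats::runif(1)) * 0.8 * arena$radius_mm
    a <- stats::runif(1, -pi, pi)
    c(r * cos(a), r * sin(a))
  } else {
    c(stats::runif(1, 0.1, 0.9) * arena$width_mm,
      stats::runif(1, 0.1, 0.9) * arena$height_mm)
  }
}

# ---- injected-bout path generators ---------------------------------------
# Each returns positions of the new frames (start position excluded), truth
# rows as index ranges into those frames, and the final heading.

gen_transit <- function(from, to, v, dt) {
  d <- sqrt(sum((to - from)^2))
  if (d < 1e-9) return(list(x = numeric(0), y = numeric(0)))
  m <- max(1L, ceiling(d / (v * dt)))
  f <- seq_len(m) / m
  list(x = from[1] + f * (to[1] - from[1]),
       y = from[2] + f * (to[2] - from[2]))
}

gen_bout_stereotypic <- function(pos, h, arena, params, dt, mode) {
  disk_r <- if (mode == "clear") 7 else 14
  dur <- if (mode == "clear") stats::runif(1, 10, 15) else stats::runif(1, 5.2, 6.5)
  # keep the confined disk clear of the edge band when the arena is large
  # enough, so stereotypic bouts do not double as wall events
  margin <- disk_r + 1
  half <- if (arena$shape == "circle") arena$radius_mm
          else min(arena$width_mm, arena$height_mm) / 2
  pref <- arena$edge_band_mm + disk_r + 1
  if (half > pref + 5) margin <- pref
  ctr <- pos
  if (arena$shape == "circle") {
    rr <- sqrt(sum(ctr^2))
    lim <- arena$radius_mm - margin
    if (rr > lim && rr > 0) ctr <- ctr * lim / rr
  } else {
    ctr[1] <- min(max(ctr[1], margin), arena$width_mm - margin)
    ctr[2] <- min(max(ctr[2], margin), arena$height_mm - margin)
  }
  tran <- gen_transit(pos, ctr, params$mean_speed_mm_s, dt)
  ns <- max(2L, round(dur / dt))
  sp <- stats::rgamma(ns, 4, rate = 4 / 15)
  tu <- stats::rnorm(ns, 0, 0.8)
  sc <- stats::rnorm(ns, 0, 0.8)
  res <- crw_path_cpp(0, 0, stats::runif(1, -pi, pi), sp, tu, sc, dt,
                      0, 0, 0, 0, 0L, disk_r, 0, 0, disk_r)
  bx <- res$x[-1] + ctr[1]
  by <- res$y[-1] + ctr[2]
  x <- c(tran$x, bx); y <- c(tran$y, by)
  i0 <- length(tran$x) + 1L
  list(x = x, y = y,
       truth = data.frame(label = "stereotypic", i0 = i0, i1 = length(x)),
       h_end = res$h)
}

inset_rect_corners <- function(arena, inset) {
  rbind(c(inset, inset),
        c(arena$width_mm - inset, inset),
        c(arena$width_mm - inset, arena$height_mm - inset),
        c(inset, arena$height_mm - inset))          # ccw
}

# closed ccw polyline utilities for the inset rectangle
perim_lengths <- function(corners) {
  nxt <- rbind(corners[-1, , drop = FALSE], corners[1, , drop = FALSE])
  sqrt(rowSums((nxt - corners)^2))
}

perim_point <- function(corners, s) {
  lens <- perim_lengths(corners)
  P <- sum(lens)
  cum <- c(0, cumsum(lens))
  sm <- s %% P
  idx <- pmin(findInterval(sm, cum, rightmost.closed = TRUE), length(lens))
  nxt <- rbind(corners[-1, , drop = FALSE], corners[1, , drop = FALSE])
  f <- (sm - cum[idx]) / lens[idx]
  cbind(corners[idx, 1] + f * (nxt[idx, 1] - corners[idx, 1]),
        corners[idx, 2] + f * (nxt[idx, 2] - corners[idx, 2]))
}

perim_nearest <- function(corners, p) {
  lens <- perim_lengths(corners)
  cum <- c(0, cumsum(lens))
  nxt <- rbind(corners[-1, , drop = FALSE], corners[1, , drop = FALSE])
  best <- c(Inf, 0)
  for (i in seq_len(nrow(corners))) {
    a <- corners[i, ]; b <- nxt[i, ]
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    q <- a + t * ab
    d <- sum((p - q)^2)
    if (d < best[1]) best <- c(d, cum[i] + t * lens[i])
  }
  best[2]
}

gen_bout_circle <- function(pos, h, arena, params, dt, mode) {
  inset <- arena$edge_band_mm / 2
  v <- params$mean_speed_mm_s
  n_loops <- if (mode == "clear") sample(1:2, 1) else 1L
  dir <- sample(c(1, -1), 1)
  lab <- if (dir > 0) "large_circle_ccw" else "large_circle_cw"
  # travel a fraction of a lap beyond the logged loops so a one-loop bout
  # still completes a full 2*pi accumulation after any reversal backlash
  # carried in from the preceding walk
  over <- 0.4
  if (arena$shape == "circle") {
    rp <- arena$radius_mm - inset
    a0 <- atan2(pos[2], pos[1])
    start <- c(rp * cos(a0), rp * sin(a0))
    P <- 2 * pi * rp
    m <- max(4L, round(n_loops * P / (v * dt)))
    mo <- round((n_loops + over) * P / (v * dt))
    ang <- a0 + dir * (seq_len(mo) / mo) * (n_loops + over) * 2 * pi
    bx <- rp * cos(ang); by <- rp * sin(ang)
  } else {
    corners <- inset_rect_corners(arena, inset)
    P <- sum(perim_lengths(corners))
    s0 <- perim_nearest(corners, pos)
    start <- as.numeric(perim_point(corners, s0))
    m <- max(4L, round(n_loops * P / (v * dt)))
    mo <- round((n_loops + over) * P / (v * dt))
    sv <- s0 + dir * (seq_len(mo) / mo) * (n_loops + over) * P
    pts <- perim_point(corners, sv)
    bx <- pts[, 1]; by <- pts[, 2]
  }
  tran <- gen_transit(pos, start, v, dt)
  off <- length(tran$x)
  truth <- do.call(rbind, lapply(seq_len(n_loops), function(j) {
    data.frame(label = lab,
               i0 = off + floor((j - 1) * m / n_loops) + 1L,
               i1 = off + floor(j * m / n_loops))
  }))
  x <- c(tran$x, bx); y <- c(tran$y, by)
  nn <- length(x)
  hend <- atan2(y[nn] - if (nn > 1) y[nn - 1] else pos[2],
                x[nn] - if (nn > 1) x[nn - 1] else pos[1])
  list(x = x, y = y, truth = truth, h_end = hend)
}

walk_polyline <- function(pts, step_len) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  total <- sum(seg)
  m <- max(1L, ceiling(total / step_len))
  sv <- pmin(seq_len(m) * step_len, total)
  cum <- c(0, cumsum(seg))
  idx <- pmin(findInterval(sv, cum, rightmost.closed = TRUE), length(seg))
  f <- (sv - cum[idx]) / seg[idx]
  cbind(pts[idx, 1] + f * (pts[idx + 1, 1] - pts[idx, 1]),
        pts[idx, 2] + f * (pts[idx + 1, 2] - pts[idx, 2]))
}

gen_bout_bnf <- function(pos, h, arena, params, dt, mode) {
  if (arena$shape != "rectangle")
    stop("back-and-forth bouts are injected in rectangular arenas only")
  W <- arena$width_mm; H <- arena$height_mm
  band <- arena$edge_band_mm
  inset <- band / 2
  v <- params$mean_speed_mm_s
  leg <- if (mode == "clear") 100 else 55
  end_gap <- if (mode == "clear") 0 else 12
  # nearest wall: 1 left, 2 right, 3 bottom, 4 top
  wdist <- c(pos[1], W - pos[1], pos[2], H - pos[2])
  wall <- which.min(wdist)
  nrm <- switch(wall, c(1, 0), c(-1, 0), c(0, 1), c(0, -1))   # inward normal
  tng <- switch(wall, c(0, 1), c(0, 1), c(1, 0), c(1, 0))     # along wall
  along <- sum((pos - c(0, 0)) * tng)
  wall_len <- if (wall <= 2) H else W
  # start clear of corners when the wall allows, so the approach is
  # perpendicular and the excursion hugs a single wall
  lo <- min(inset + 40, wall_len / 2)
  hi <- max(wall_len - inset - 40, wall_len / 2)
  along <- min(max(along, lo), hi)
  start <- switch(wall,
                  c(inset, along), c(W - inset, along),
                  c(along, inset), c(along, H - inset))
  dirn <- if (wall_len - inset - along >= along - inset) 1 else -1
  room <- if (dirn > 0) wall_len - inset - along else along - inset
  if (room >= leg) {
    out_pts <- rbind(start, start + dirn * leg * tng)
  } else {
    # turn at the inset-frame corner onto the adjacent wall; walking away
    # from the corner along that wall is movement along the inward normal
    # of the original wall
    corner <- start + dirn * room * tng
    rem <- min(leg - room, (if (wall <= 2) W else H) - 2 * inset)
    out_pts <- rbind(start, corner, corner + rem * nrm)
  }
  back_pts <- out_pts[rev(seq_len(nrow(out_pts))), , drop = FALSE]
  if (end_gap > 0)
    back_pts[nrow(back_pts), ] <- start + dirn * end_gap * tng
  w_pt <- start + nrm * (band * 1.3 - inset)
  tran1 <- gen_transit(pos, w_pt, v, dt)
  tran2 <- gen_transit(w_pt, start, v, dt)
  path <- rbind(out_pts, back_pts[-1, , drop = FALSE])
  bw <- walk_polyline(path, v * dt)
  exit_pts <- gen_transit(as.numeric(back_pts[nrow(back_pts), ]), w_pt, v, dt)
  x <- c(tran1$x, tran2$x, bw[, 1], exit_pts$x)
  y <- c(tran1$y, tran2$y, bw[, 2], exit_pts$y)
  i0 <- length(tran1$x) + length(tran2$x) + 1L
  i1 <- length(tran1$x) + length(tran2$x) + nrow(bw)
  nn <- length(x)
  hend <- atan2(y[nn] - if (nn > 1) y[nn - 1] else pos[2],
                x[nn] - if (nn > 1) x[nn - 1] else pos[1])
  list(x = x, y = y,
       truth = data.frame(label = "back_and_forth", i0 = i0, i1 = i1),
       h_end = hend)
}

# ---- single-fish simulation ----------------------------------------------

#' Simulate one fish
#'
#' Discrete-time correlated random walk in an arena, with optional light/dark
#' schedule (dark epochs multiply speed by `dark_multiplier`), wall bias,
#' social attraction, and injected ground-truth repetitive-behavior bouts
#' whose kinematics temporarily override the walk (confined jitter for
#' stereotypic bouts, wall-following constant-sign angular motion for
#' circling, an edge out-and-back for back-and-forth). Fully reproducible
#' from the integer seed.
#'
#' @param params An [agent_params()].
#' @param arena An [arena_geometry()].
#' @param schedule Optional [light_schedule()]; when supplied, `duration_s`
#'   defaults to its span.
#' @param duration_s Simulated duration in seconds.
#' @param seed Integer seed.
#' @param frame_rate_hz Frames per second, default 25.
#' @param bout_mode `"clear"` injects bouts at least 2x clear of the
#'   classifier thresholds; `"hard"` generates near-threshold bouts for
#'   sensitivity analyses.
#' @param fish_id Identifier for the resulting trajectory.
#' @return List with elements `trajectory` (a [trajectory()]) and `truth`
#'   (a `ground_truth_log`: `bouts` data.frame, `params`, `seed`).
#' @export
simulate_fish <- function(params, arena, schedule = NULL, duration_s = NULL,
                          seed = 1, frame_rate_hz = 25,
                          bout_mode = c("clear", "hard"), fish_id = "fish1") {
  bout_mode <- match.arg(bout_mode)
  stopifnot(inherits(params, "agent_params"),
            inherits(arena, "arena_geometry"))
  if (is.null(duration_s)) {
    if (is.null(schedule)) stop("need duration_s or a schedule")
    duration_s <- schedule_span(schedule)
  }
  if (duration_s <= 0) stop("duration_s must be > 0")
  dt <- 1 / frame_rate_hz
  n_steps <- round(duration_s * frame_rate_hz)
  if (n_steps < 2) stop("duration too short for the frame rate")
  set.seed(as.integer(seed))

  mult <- rep(1, n_steps)
  if (!is.null(schedule)) {
    mids <- (seq_len(n_steps) - 0.5) * dt
    dark <- !is.na(epoch_at(schedule, mids, "condition")) &
      epoch_at(schedule, mids, "condition") == "dark"
    mult[dark] <- params$dark_multiplier
  }
  soc <- c(0, 0); socw <- params$social_weight
  if (socw > 0) {
    reg <- arena$regions[["social"]]
    if (is.null(reg))
      stop("social_weight > 0 requires an arena with a 'social' region")
    soc <- region_center(reg)
  }
  ac <- arena_cpp_args(arena)

  # injected-bout requests (Poisson per label, rates per minute)
  ev <- data.frame(label = character(), t_req = numeric())
  for (lab in names(params$bout_rates)) {
    lam <- params$bout_rates[[lab]] / 60 * duration_s
    if (lam > 0) {
      k <- stats::rpois(1, lam)
      if (k > 0)
        ev <- rbind(ev, data.frame(label = lab,
                                   t_req = sort(stats::runif(k, 0, duration_s))))
    }
  }
  ev <- ev[order(ev$t_req), , drop = FALSE]

  x <- numeric(n_steps + 1); y <- numeric(n_steps + 1)
  p0 <- random_start(arena)
  x[1] <- p0[1]; y[1] <- p0[2]
  h <- stats::runif(1, -pi, pi)
  cur <- 1L
  truth <- list()

  sim_bg <- function(i1) {
    ns <- i1 - cur
    if (ns <= 0) return(invisible())
    sp <- draw_speeds(ns, params) * mult[cur:(i1 - 1)]
    tu <- stats::rnorm(ns, 0, params$turn_sd_rad)
    sc <- stats::rnorm(ns, 0, params$wall_scatter_rad)
    res <- crw_path_cpp(x[cur], y[cur], h, sp, tu, sc, dt,
                        params$wall_bias, socw, soc[1], soc[2],
                        ac$shape, ac$R, ac$W, ac$H, arena$edge_band_mm)
    x[cur:i1] <<- res$x
    y[cur:i1] <<- res$y
    h <<- res$h
    cur <<- i1
    invisible()
  }

  for (r in seq_len(nrow(ev))) {
    ev_frame <- floor(ev$t_req[r] / dt) + 1L
    if (ev_frame <= cur) next
    sim_bg(ev_frame)
    bp <- switch(ev$label[r],
                 stereotypic = gen_bout_stereotypic(c(x[cur], y[cur]), h,
                                                    arena, params, dt, bout_mode),
                 large_circle = gen_bout_circle(c(x[cur], y[cur]), h,
                                                arena, params, dt, bout_mode),
                 back_and_forth = gen_bout_bnf(c(x[cur], y[cur]), h,
                                               arena, params, dt, bout_mode))
    m <- length(bp$x)
    if (cur + m > n_steps + 1) next      # bout does not fit before the end
    x[(cur + 1):(cur + m)] <- bp$x
    y[(cur + 1):(cur + m)] <- bp$y
    if (nrow(bp$truth)) {
      tr <- bp$truth
      tr$start_s <- (cur - 1 + tr$i0 - 1) * dt
      tr$end_s <- (cur - 1 + tr$i1) * dt
      tr$fish_id <- fish_id
      truth[[length(truth) + 1]] <- tr[, c("fish_id", "label", "start_s", "end_s")]
    }
    cur <- cur + m
    h <- bp$h_end
  }
  sim_bg(n_steps + 1L)

  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(fish_id = character(), label = character(),
               start_s = numeric(), end_s = numeric())
  rownames(truth_df) <- NULL
  traj <- trajectory(fish_id, arena, (0:n_steps) * dt, x, y, frame_rate_hz)
  list(trajectory = traj,
       truth = structure(list(bouts = truth_df, params = params,
                              seed = as.integer(seed)),
                         class = "ground_truth_log"))
}

#' @export
print.ground_truth_log <- function(x, ...) {
  cat(sprintf("<ground_truth_log> seed %d: %d injected bout(s)\n",
              x$seed, nrow(x$bouts)))
  invisible(x)
}

#' Simulate a shoal of coupled fish
#'
#' `k` agents share the arena; each heading is additionally steered toward
#' the instantaneous group centroid with weight `cohesion` (from `params`).
#' No bouts are injected.
#'
#' @param k Number of fish (>= 2).
#' @param params An [agent_params()] shared by all agents.
#' @param arena An [arena_geometry()].
#' @param duration_s Duration in seconds.
#' @param seed Integer seed.
#' @param frame_rate_hz Frames per second, default 25.
#' @param fish_prefix Prefix for fish ids (`<prefix>1` ... `<prefix>k`).
#' @return List with `trajectories` (list of k [trajectory()]) and `truth`
#'   (a `ground_truth_log` without bouts).
#' @export
simulate_shoal <- function(k, params, arena, duration_s, seed = 1,
                           frame_rate_hz = 25, fish_prefix = "fish") {
  stopifnot(inherits(params, "agent_params"),
            inherits(arena, "arena_geometry"))
  if (k < 2) stop("a shoal needs k >= 2 fish")
  dt <- 1 / frame_rate_hz
  n_steps <- round(duration_s * frame_rate_hz)
  set.seed(as.integer(seed))
  x0 <- numeric(k); y0 <- numeric(k)
  for (j in seq_len(k)) {
    p <- random_start(arena)
    x0[j] <- p[1]; y0[j] <- p[2]
  }
  h0 <- stats::runif(k, -pi, pi)
  sp <- matrix(draw_speeds(n_steps * k, params), n_steps, k)
  tu <- matrix(stats::rnorm(n_steps * k, 0, params$turn_sd_rad), n_steps, k)
  sc <- matrix(stats::rnorm(n_steps * k, 0, params$wall_scatter_rad),
               n_steps, k)
  ac <- arena_cpp_args(arena)
  res <- crw_shoal_cpp(x0, y0, h0, sp, tu, sc, dt, params$wall_bias,
                       params$cohesion, ac$shape, ac$R, ac$W, ac$H,
                       arena$edge_band_mm)
  t_s <- (0:n_steps) * dt
  trajs <- lapply(seq_len(k), function(j)
    trajectory(paste0(fish_prefix, j), arena, t_s,
               res$x[, j], res$y[, j], frame_rate_hz))
  names(trajs) <- vapply(trajs, `[[`, character(1), "fish_id")
  list(trajectories = trajs,
       truth = structure(list(bouts = data.frame(fish_id = character(),
                                                 label = character(),
                                                 start_s = numeric(),
                                                 end_s = numeric()),
                              params = params, seed = as.integer(seed)),
                         class = "ground_truth_log"))
}

#' Default two-group study designs for each assay
#'
#' Returns the arena, schedule, duration, group sizes and wild-type/mutant
#' agent parameters emulating each assay's published design: reduced larval
#' locomotion with stronger first-cycle photomotor response and higher
#' thigmotaxis in mutants (`pmr_7dpf`), adult hyperactivity (`open_field`),
#' reduced social-area attraction (`social_preference`), looser shoals
#' (`shoaling`), and elevated repetitive-bout rates (`repetitive`).
#'
#' @param assay One of `pmr_7dpf`, `open_field`, `social_preference`,
#'   `shoaling`, `repetitive`.
#' @return List with `arena`, `schedule` (or `NULL`), `duration_s`,
#'   `n_per_group`, `shoal_size`, `wt_params`, `mut_params`.
#' @export
cohort_defaults <- function(assay = c("pmr_7dpf", "open_field",
                                      "social_preference", "shoaling",
                                      "repetitive")) {
  assay <- match.arg(assay)
  switch(assay,
    pmr_7dpf = list(
      arena = make_standard_arena("well24_7dpf"),
      schedule = make_pmr_schedule("figure"),
      duration_s = schedule_span(make_pmr_schedule("figure")),
      n_per_group = 48, shoal_size = 1,
      wt_params = agent_params(mean_speed_mm_s = 3, speed_shape = 3,
                               turn_sd_rad = 0.7, wall_bias = 0.05,
                               dark_multiplier = 2),
      mut_params = agent_params(mean_speed_mm_s = 2, speed_shape = 3,
                                turn_sd_rad = 0.7, wall_bias = 0.12,
                                dark_multiplier = 2.6)),
    open_field = list(
      arena = make_standard_arena("tank300_open"), schedule = NULL,
      duration_s = 1800, n_per_group = 16, shoal_size = 1,
      wt_params = agent_params(mean_speed_mm_s = 60, turn_sd_rad = 0.25,
                               wall_bias = 0.3),
      mut_params = agent_params(mean_speed_mm_s = 85, turn_sd_rad = 0.25,
                                wall_bias = 0.3)),
    social_preference = list(
      arena = make_standard_arena("mating_tank"), schedule = NULL,
      duration_s = 1800, n_per_group = 20, shoal_size = 1,
      wt_params = agent_params(mean_speed_mm_s = 50, turn_sd_rad = 0.4,
                               wall_bias = 0.1, social_weight = 0.5),
      mut_params = agent_params(mean_speed_mm_s = 50, turn_sd_rad = 0.4,
                                wall_bias = 0.1, social_weight = 0.05)),
    shoaling = list(
      arena = make_standard_arena("tank300_open"), schedule = NULL,
      duration_s = 1800, n_per_group = 4, shoal_size = 6,
      wt_params = agent_params(mean_speed_mm_s = 60, turn_sd_rad = 0.3,
                               wall_bias = 0.1, cohesion = 0.6),
      mut_params = agent_params(mean_speed_mm_s = 60, turn_sd_rad = 0.3,
                                wall_bias = 0.1, cohesion = 0.15)),
    repetitive = list(
      arena = make_standard_arena("tank300_open"), schedule = NULL,
      duration_s = 1800, n_per_group = 16, shoal_size = 1,
      wt_params = agent_params(mean_speed_mm_s = 60, turn_sd_rad = 0.3,
                               wall_bias = 0,
                               bout_rates = c(back_and_forth = 0.05,
                                              stereotypic = 0.05,
                                              large_circle = 0.05)),
      mut_params = agent_params(mean_speed_mm_s = 60, turn_sd_rad = 0.3,
                                wall_bias = 0,
                                bout_rates = c(back_and_forth = 1.2,
                                               stereotypic = 0.6,
                                               large_circle = 0.5))))
}

#' Simulate a two-group cohort and write tracking files
#'
#' Simulates `n_per_group` replicates per group (wild-type-like and
#' mutant-like parameter sets) for one assay, writes one tracking CSV and one
#' ground-truth CSV per replicate, and returns the objects. Per-replicate
#' seeds are derived from the single cohort seed by fixed splitting, so the
#' cohort is reproducible independent of group size.
#'
#' @param n_per_group Replicates per group (fish, or shoals for `shoaling`).
#' @param wt_params,mut_params [agent_params()] for the two groups; defaults
#'   from [cohort_defaults()].
#' @param assay Assay name, see [cohort_defaults()].
#' @param seed Integer cohort seed.
#' @param dir Output directory (created if needed); `NULL` skips writing.
#' @param duration_s Override the assay's default duration.
#' @param frame_rate_hz Frames per second, default 25.
#' @return Invisibly, a list: `manifest` (data.frame group/replicate/paths/
#'   seed), `trajectories` (named list; for shoaling a list of lists),
#'   `truths`, `arena`, `schedule`, `assay`.
#' @export
make_cohort <- function(n_per_group, wt_params = NULL, mut_params = NULL,
                        assay = c("pmr_7dpf", "open_field",
                                  "social_preference", "shoaling",
                                  "repetitive"),
                        seed = 1, dir = NULL, duration_s = NULL,
                        frame_rate_hz = 25) {
  assay <- match.arg(assay)
  defs <- cohort_defaults(assay)
  if (is.null(wt_params)) wt_params <- defs$wt_params
  if (is.null(mut_params)) mut_params <- defs$mut_params
  if (is.null(duration_s)) duration_s <- defs$duration_s
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  groups <- list(wt = wt_params, mut = mut_params)
  manifest <- list(); trajs <- list(); truths <- list()
  for (gi in seq_along(groups)) {
    gname <- names(groups)[gi]
    for (i in seq_len(n_per_group)) {
      rep_seed <- (as.integer(seed) + 104729L * gi + 7919L * i) %% .Machine$integer.max
      rid <- sprintf("%s_%02d", gname, i)
      if (defs$shoal_size > 1) {
        sim <- simulate_shoal(defs$shoal_size, groups[[gi]], defs$arena,
                              duration_s, seed = rep_seed,
                              frame_rate_hz = frame_rate_hz,
                              fish_prefix = paste0(rid, "_f"))
        tr_obj <- sim$trajectories
      } else {
        sim <- simulate_fish(groups[[gi]], defs$arena, defs$schedule,
                             duration_s, seed = rep_seed,
                             frame_rate_hz = frame_rate_hz,
                             fish_id = rid)
        tr_obj <- sim$trajectory
      }
      tpath <- NA_character_; gpath <- NA_character_
      if (!is.null(dir)) {
        tpath <- file.path(dir, sprintf("tracking_%s.csv", rid))
        gpath <- file.path(dir, sprintf("truth_%s.csv", rid))
        write_tracking(if (defs$shoal_size > 1) tr_obj else list(tr_obj), tpath)
        utils::write.csv(sim$truth$bouts, gpath, row.names = FALSE,
                         quote = FALSE)
      }
      manifest[[length(manifest) + 1]] <-
        data.frame(group = gname, replicate = i, seed = rep_seed,
                   tracking = tpath, truth = gpath,
                   stringsAsFactors = FALSE)
      trajs[[rid]] <- tr_obj
      truths[[rid]] <- sim$truth
    }
  }
  invisible(list(manifest = do.call(rbind, manifest), trajectories = trajs,
                 truths = truths, arena = defs$arena,
                 schedule = defs$schedule, assay = assay))
}
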