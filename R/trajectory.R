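#' Centroid trajectory of a single fish
#'
#' Per-frame centroid positions (mm) with explicit timestamps, bound to an
#' arena. Frames where the tracker lost the fish carry `NA` positions and are
#' flagged in the `missing` mask.
#'
#' @param fish_id Fish identifier.
#' @param arena The [arena_geometry()] the fish was recorded in.
#' @param t_s Strictly increasing timestamps in seconds (length >= 2).
#' @param x_mm,y_mm Positions in mm; `NA` marks missing frames.
#' @param frame_rate_hz Nominal frame rate, default 25 fps.
#' @return An object of class `swim_trajectory`.
#' @export
trajectory <- function(fish_id, arena, t_s, x_mm, y_mm, frame_rate_hz = 25) {
  stopifnot(inherits(arena, "arena_geometry"))
  n <- length(t_s)
  if (n < 2 || length(x_mm) != n || length(y_mm) != n)
    stop("t_s, x_mm, y_mm must have equal length >= 2")
  if (any(diff(t_s) <= 0))
    stop(sprintf("timestamps must be strictly increasing (fish '%s')", fish_id))
  miss <- is.na(x_mm) | is.na(y_mm)
  x_mm[miss] <- NA_real_
  y_mm[miss] <- NA_real_
  structure(list(fish_id = as.character(fish_id), arena = arena,
                 frame_rate_hz = frame_rate_hz,
                 t_s = as.numeric(t_s), x_mm = as.numeric(x_mm),
                 y_mm = as.numeric(y_mm), missing = miss),
            class = "swim_trajectory")
}

#' @export
print.swim_trajectory <- function(x, ...) {
  cat(sprintf("<swim_trajectory> fish '%s' in arena '%s': %d frames, %.1f s, %d missing\n",
              x$fish_id, x$arena$arena_id, length(x$t_s),
              max(x$t_s) - min(x$t_s), sum(x$missing)))
  invisible(x)
}

#' @export
as.data.frame.swim_trajectory <- function(x, ...) {
  data.frame(fish_id = x$fish_id, frame = seq_along(x$t_s) - 1L,
             t_s = x$t_s, x_mm = x$x_mm, y_mm = x$y_mm,
             arena_id = x$arena$arena_id, stringsAsFactors = FALSE)
}

#' Trajectory time span
#' @param traj A [trajectory()].
#' @return `c(t_min, t_max)` in seconds.
#' @export
traj_span <- function(traj) {
  stopifnot(inherits(traj, "swim_trajectory"))
  range(traj$t_s)
}

TRACKING_HEADER <- c("fish_id", "frame", "t_s", "x_mm", "y_mm", "arena_id")

#' Read a tracking file
#'
#' Tracking files are plain CSV with the exact header
#' `fish_id,frame,t_s,x_mm,y_mm,arena_id`, one row per frame, any number of
#' fish. Positions up to `clamp_tol_mm` outside the arena are clamped onto the
#' boundary (tracking overshoot); positions further out are flagged as missing
#' with a warning.
#'
#' @param path Path to the CSV file.
#' @param arena The [arena_geometry()] all `arena_id`s in the file refer to.
#' @param clamp_tol_mm Out-of-arena tolerance, default 0.5 mm.
#' @param max_gap_frames Longest run of missing frames repaired by linear
#'   interpolation (default 5); longer gaps stay missing.
#' @return Named list of [trajectory()] objects, one per fish, time-sorted.
#' @export
read_tracking <- function(path, arena, clamp_tol_mm = 0.5, max_gap_frames = 5) {
  stopifnot(inherits(arena, "arena_geometry"))
  if (!file.exists(path)) stop(sprintf("tracking file not found: %s", path))
  hdr <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  if (!identical(trimws(hdr), TRACKING_HEADER)) {
    missing_cols <- setdiff(TRACKING_HEADER, trimws(hdr))
    stop(sprintf("malformed tracking header; missing columns: %s",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(fish_id = "character",
                                       frame = "integer", t_s = "numeric",
                                       x_mm = "numeric", y_mm = "numeric",
                                       arena_id = "character"))
  out <- list()
  for (id in unique(df$fish_id)) {
    d <- df[df$fish_id == id, , drop = FALSE]
    d <- d[order(d$t_s), , drop = FALSE]
    if (any(diff(d$t_s) <= 0))
      stop(sprintf("non-monotone or duplicated timestamps for fish '%s'", id))
    x <- d$x_mm; y <- d$y_mm
    ok <- !is.na(x) & !is.na(y)
    wd <- rep(Inf, length(x))
    wd[ok] <- wall_distance(arena, x[ok], y[ok])
    far <- ok & wd < -clamp_tol_mm
    if (any(far)) {
      warning(sprintf("fish '%s': %d point(s) more than %.2g mm outside arena '%s' flagged as missing",
                      id, sum(far), clamp_tol_mm, arena$arena_id))
      x[far] <- NA_real_; y[far] <- NA_real_
    }
    near <- ok & !far & wd < 0
    if (any(near)) {
      cl <- clamp_to_arena(arena, x[near], y[near])
      x[near] <- cl$x; y[near] <- cl$y
    }
    tr <- trajectory(id, arena, d$t_s, x, y,
                     frame_rate_hz = infer_frame_rate(d$t_s))
    out[[id]] <- fill_gaps(tr, max_gap_frames = max_gap_frames)
  }
  out
}

infer_frame_rate <- function(t_s) {
  dt <- stats::median(diff(t_s))
  if (!is.finite(dt) || dt <= 0) 25 else 1 / dt
}

#' Write trajectories to a tracking file
#'
#' Deterministic column order and number formatting (positions to 1e-6 mm),
#' so a write/read round trip preserves values and identical inputs produce
#' byte-identical files.
#'
#' @param trajs A [trajectory()] or list of them (must share a frame rate).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(trajs, path) {
  if (inherits(trajs, "swim_trajectory")) trajs <- list(trajs)
  stopifnot(all(vapply(trajs, inherits, logical(1), "swim_trajectory")))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(TRACKING_HEADER, collapse = ","), con)
  if (length(trajs)) {
    rates <- vapply(trajs, `[[`, numeric(1), "frame_rate_hz")
    if (max(rates) - min(rates) > 1e-9)
      stop("trajectories must share a frame rate")
    for (tr in trajs) {
      lines <- sprintf("%s,%d,%.6f,%s,%s,%s",
                       tr$fish_id, seq_along(tr$t_s) - 1L, tr$t_s,
                       num_or_na(tr$x_mm), num_or_na(tr$y_mm),
                       tr$arena$arena_id)
      writeLines(lines, con)
    }
  }
  invisible(path)
}

num_or_na <- function(v) ifelse(is.na(v), "NA", sprintf("%.6f", v))

#' Repair short tracking dropouts
#'
#' Linearly interpolates runs of up to `max_gap_frames` consecutive missing
#' frames between valid neighbours. Longer gaps are left missing so that
#' downstream bout/segment analyses split rather than fabricate motion.
#'
#' @param traj A [trajectory()].
#' @param max_gap_frames Longest repairable gap, default 5 frames.
#' @return A [trajectory()] with short gaps filled.
#' @export
fill_gaps <- function(traj, max_gap_frames = 5) {
  stopifnot(inherits(traj, "swim_trajectory"))
  miss <- traj$missing
  if (!any(miss)) return(traj)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  x <- traj$x_mm; y <- traj$y_mm
  for (i in which(r$values)) {
    if (r$lengths[i] > max_gap_frames) next
    a <- starts[i] - 1; b <- ends[i] + 1
    if (a < 1 || b > length(x)) next          # gap touches an end
    ts <- traj$t_s
    f <- (ts[starts[i]:ends[i]] - ts[a]) / (ts[b] - ts[a])
    x[starts[i]:ends[i]] <- x[a] + f * (x[b] - x[a])
    y[starts[i]:ends[i]] <- y[a] + f * (y[b] - y[a])
  }
  trajectory(traj$fish_id, traj$arena, traj$t_s, x, y, traj$frame_rate_hz)
}

#' Suppress sub-threshold tracking jitter
#'
#' Re-expresses the tracker's unit-less detection threshold as a physical
#' displacement deadband: while the fish stays within `min_step_mm` of the
#' last accepted position, the position is held there, so centroid noise does
#' not accumulate into spurious travelled distance. The operation never
#' increases total path length and is idempotent.
#'
#' @param traj A [trajectory()].
#' @param min_step_mm Deadband radius in mm (default 0.2, suitable for
#'   larval centroid noise); 0 is the identity.
#' @return A [trajectory()] with held positions.
#' @export
suppress_jitter <- function(traj, min_step_mm = 0.2) {
  stopifnot(inherits(traj, "swim_trajectory"))
  if (!is.numeric(min_step_mm) || min_step_mm < 0)
    stop("min_step_mm must be >= 0")
  if (min_step_mm == 0) return(traj)
  x <- traj$x_mm; y <- traj$y_mm
  hx <- NA_real_; hy <- NA_real_
  thr2 <- min_step_mm^2
  for (i in seq_along(x)) {
    if (is.na(x[i])) { hx <- NA_real_; hy <- NA_real_; next }
    if (is.na(hx)) { hx <- x[i]; hy <- y[i]; next }
    if ((x[i] - hx)^2 + (y[i] - hy)^2 < thr2) {
      x[i] <- hx; y[i] <- hy
    } else {
      hx <- x[i]; hy <- y[i]
    }
  }
  trajectory(traj$fish_id, traj$arena, traj$t_s, x, y, traj$frame_rate_hz)
}
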