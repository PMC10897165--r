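BOUT_LABELS <- c("back_and_forth", "stereotypic", "large_circle_cw",
                 "large_circle_ccw")

empty_bouts <- function() {
  data.frame(fish_id = character(), label = character(),
             start_s = numeric(), end_s = numeric(),
             max_span_mm = numeric(), net_winding_rad = numeric(),
             path_mm = numeric(), stringsAsFactors = FALSE)
}

bout_row <- function(fish_id, label, start_s, end_s,
                     max_span_mm = NA_real_, net_winding_rad = NA_real_,
                     path_mm = NA_real_) {
  data.frame(fish_id = fish_id, label = label, start_s = start_s,
             end_s = end_s, max_span_mm = max_span_mm,
             net_winding_rad = net_winding_rad, path_mm = path_mm,
             stringsAsFactors = FALSE)
}

rbind_bouts <- function(lst) {
  lst <- lst[vapply(lst, function(b) !is.null(b) && nrow(b) > 0, logical(1))]
  if (!length(lst)) return(empty_bouts())
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out[order(out$start_s), , drop = FALSE]
}

#' Segment continuous swimming
#'
#' Maximal intervals where the smoothed instantaneous speed stays at or above
#' a threshold; brief sub-threshold dips shorter than `bridge_s` are bridged.
#' Missing frames always split intervals.
#'
#' @param traj A [trajectory()].
#' @param speed_threshold_mm_s Swimming threshold, default 1 mm/s.
#' @param smooth_s Width of the centred moving-average speed smoother in
#'   seconds (default 0.2).
#' @param bridge_s Gaps shorter than this are bridged (default 0.2 s).
#' @return data.frame with columns `start_s`, `end_s`.
#' @export
segment_swimming <- function(traj, speed_threshold_mm_s = 1,
                             smooth_s = 0.2, bridge_s = 0.2) {
  stopifnot(inherits(traj, "swim_trajectory"))
  if (speed_threshold_mm_s < 0) stop("speed threshold must be >= 0")
  t <- traj$t_s
  n <- length(t)
  dtv <- diff(t)
  dx <- diff(traj$x_mm); dy <- diff(traj$y_mm)
  sp <- sqrt(dx^2 + dy^2) / dtv             # speed of step i, NA at gaps
  w <- max(1L, round(smooth_s * traj$frame_rate_hz))
  if (w > 1 && length(sp) >= w) {
    sm <- stats::filter(sp, rep(1 / w, w), sides = 2)
    sm <- as.numeric(sm)
    sm[is.na(sm) & !is.na(sp)] <- sp[is.na(sm) & !is.na(sp)]
  } else sm <- sp
  moving <- !is.na(sm) & sm >= speed_threshold_mm_s
  if (!any(moving)) return(data.frame(start_s = numeric(), end_s = numeric()))
  r <- rle(moving)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  iv <- data.frame(start_s = t[starts[r$values]],
                   end_s = t[pmin(ends[r$values] + 1L, n)])
  # bridge short stops
  if (nrow(iv) > 1) {
    keep_start <- iv$start_s[1]; out <- list()
    cur_end <- iv$end_s[1]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv$start_s[i] - cur_end < bridge_s) {
        cur_end <- iv$end_s[i]
      } else {
        out[[length(out) + 1]] <- c(keep_start, cur_end)
        keep_start <- iv$start_s[i]; cur_end <- iv$end_s[i]
      }
    }
    out[[length(out) + 1]] <- c(keep_start, cur_end)
    iv <- as.data.frame(do.call(rbind, out))
    names(iv) <- c("start_s", "end_s")
  }
  iv
}

max_pair_span <- function(x, y) {
  if (length(x) < 2) return(0)
  max(stats::dist(cbind(x, y)))
}

#' Detect stereotypic (small-circling) bouts
#'
#' Implements the confined-swimming rule: within a continuous swimming
#' interval, a stereotypic bout is a maximal sub-interval longer than
#' `min_dur_s` whose spatial span (maximum pairwise distance among its
#' positions) stays below `max_span_mm`. The published thresholds are
#' 30 mm and 5 s. Bouts are grown greedily left to right; when adding a frame
#' would push the span to `max_span_mm` the bout is truncated before the
#' violating frame.
#'
#' @param traj A [trajectory()].
#' @param max_span_mm Span threshold, default 30 mm.
#' @param min_dur_s Minimum (strict) duration, default 5 s.
#' @param swim Optional precomputed [segment_swimming()] table.
#' @param speed_threshold_mm_s Passed to [segment_swimming()] when `swim` is
#'   not supplied.
#' @return Bout data.frame (`fish_id`, `label`, `start_s`, `end_s`,
#'   `max_span_mm`, `net_winding_rad`, `path_mm`), label `"stereotypic"`.
#' @export
detect_stereotypic <- function(traj, max_span_mm = 30, min_dur_s = 5,
                               swim = NULL, speed_threshold_mm_s = 1) {
  stopifnot(inherits(traj, "swim_trajectory"))
  if (max_span_mm <= 0 || min_dur_s <= 0) stop("thresholds must be > 0")
  if (is.null(swim)) swim <- segment_swimming(traj, speed_threshold_mm_s)
  bouts <- list()
  for (k in seq_len(nrow(swim))) {
    idx <- which(traj$t_s >= swim$start_s[k] & traj$t_s <= swim$end_s[k] &
                 !traj$missing)
    if (length(idx) < 2) next
    ts <- traj$t_s[idx]; xs <- traj$x_mm[idx]; ys <- traj$y_mm[idx]
    n <- length(idx)
    s <- 1L; e <- 1L; span <- 0
    emit <- function(s, e, span) {
      if (ts[e] - ts[s] > min_dur_s) {
        seg <- s:e
        bout_row(traj$fish_id, "stereotypic", ts[s], ts[e],
                 max_span_mm = span,
                 path_mm = sum(sqrt(diff(xs[seg])^2 + diff(ys[seg])^2)))
      } else NULL
    }
    while (e < n) {
      dnew <- sqrt((xs[s:e] - xs[e + 1])^2 + (ys[s:e] - ys[e + 1])^2)
      dmax <- max(dnew)
      if (max(span, dmax) < max_span_mm) {
        span <- max(span, dmax)
        e <- e + 1L
        next
      }
      b <- emit(s, e, span)
      if (!is.null(b)) {
        bouts[[length(bouts) + 1]] <- b
        s <- e + 1L; e <- e + 1L; span <- 0
      } else {
        s <- s + max(which(dnew >= max_span_mm))
        e <- e + 1L
        span <- max_pair_span(xs[s:e], ys[s:e])
      }
    }
    b <- emit(s, e, span)
    if (!is.null(b)) bouts[[length(bouts) + 1]] <- b
  }
  rbind_bouts(bouts)
}

wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi)
  a[a < 0] <- a[a < 0] + 2 * pi
  a - pi
}

#' Detect large circling along the arena walls
#'
#' Accumulates the signed angle of the fish about the arena centre over
#' frames inside the edge band. Every monotone accumulation reaching a full
#' turn (2*pi) emits one loop event, labelled `large_circle_ccw` for positive
#' (counterclockwise, mathematical orientation) and `large_circle_cw` for
#' negative winding. The accumulation resets when the direction reverses by
#' more than `reversal_tol_rad` or the fish leaves the band for longer than
#' `exit_grace_s`.
#'
#' @param traj A [trajectory()].
#' @param arena The [arena_geometry()] (defaults to the trajectory's arena).
#' @param min_loops Minimum consecutive loops an accumulation run must
#'   complete for its loops to be reported (default 1).
#' @param band_mm Edge-band width, default the arena's `edge_band_mm`.
#' @param reversal_tol_rad Tolerated counter-rotation before reset
#'   (default pi/2).
#' @param exit_grace_s Tolerated time outside the band (default 0.5 s).
#' @param restrict_band Set `FALSE` to accumulate over the whole arena
#'   (sensitivity analysis).
#' @return Bout data.frame, one row per completed loop, with
#'   `net_winding_rad` of +/- 2*pi.
#' @export
detect_large_circle <- function(traj, arena = traj$arena, min_loops = 1,
                                band_mm = arena$edge_band_mm,
                                reversal_tol_rad = pi / 2,
                                exit_grace_s = 0.5, restrict_band = TRUE) {
  stopifnot(inherits(traj, "swim_trajectory"),
            inherits(arena, "arena_geometry"))
  ctr <- arena_center(arena)
  ok <- !traj$missing
  if (restrict_band)
    ok <- ok & wall_distance(arena, traj$x_mm, traj$y_mm) <= band_mm
  idx <- which(ok)
  if (length(idx) < 2) return(empty_bouts())
  tt <- traj$t_s[idx]
  th <- atan2(traj$y_mm[idx] - ctr[2], traj$x_mm[idx] - ctr[1])
  runs <- split(seq_along(idx),
                cumsum(c(0, diff(tt) > exit_grace_s)))
  bouts <- list()
  for (rn in runs) {
    if (length(rn) < 2) next
    dth <- wrap_angle(diff(th[rn]))
    tr <- tt[rn]
    prog <- 0; peak <- 0; start_t <- tr[1]
    run_loops <- list()
    flush <- function() {
      if (length(run_loops) >= min_loops)
        bouts[length(bouts) + seq_along(run_loops)] <<- run_loops
      run_loops <<- list()
    }
    for (j in seq_along(dth)) {
      prog <- prog + dth[j]
      dirn <- if (peak != 0) sign(peak) else sign(prog)
      if (dirn != 0) {
        if (prog * dirn >= peak * dirn) {
          peak <- prog
        } else if ((peak - prog) * dirn > reversal_tol_rad) {
          flush()
          prog <- 0; peak <- 0; start_t <- tr[j + 1]
          next
        }
      }
      if (abs(prog) >= 2 * pi) {
        lab <- if (prog > 0) "large_circle_ccw" else "large_circle_cw"
        run_loops[[length(run_loops) + 1]] <-
          bout_row(traj$fish_id, lab, start_t, tr[j + 1],
                   net_winding_rad = sign(prog) * 2 * pi)
        prog <- prog - 2 * pi * sign(prog)
        peak <- prog
        start_t <- tr[j + 1]
      }
    }
    flush()
  }
  rbind_bouts(bouts)
}

#' Detect back-and-forth wall excursions
#'
#' An event is an excursion within the edge band of a rectangular arena that
#' (a) stays in the band, (b) visits one wall or two adjacent walls (nearest
#' -wall assignment per frame), (c) actually travels along the wall and away
#' from its origin: the displacement from the excursion origin projected on
#' the wall tangent (either axis for adjacent-wall excursions) reaches
#' `min_leg_mm`, as does the path length, after leaving the
#' `return_radius_mm` disk around the origin, and (d) comes back within
#' `return_radius_mm` of the origin, and (e) hugs the wall: at least
#' `min_hug_fraction` of its frames lie within the inner half of the band.
#' The tangential-displacement and wall-hugging requirements keep wall
#' bounces and oblique band crossings (which traverse the band without
#' travelling on the edge) from counting as edge excursions.
#' The "one time" character of the published definition (a single out-and-
#' back rather than prolonged meandering that happens to close a loop) is
#' encoded as a tortuosity cap: the excursion's path length may not exceed
#' `max_tortuosity` times its maximum displacement from the origin (a clean
#' out-and-back has tortuosity 2). Excursions crossing two opposite walls
#' (or three or more walls) do not qualify and restart the search at the
#' disqualifying frame.
#'
#' @param traj A [trajectory()].
#' @param arena Rectangular [arena_geometry()] (defaults to the
#'   trajectory's arena).
#' @param return_radius_mm Return tolerance around the excursion origin,
#'   default 15 mm.
#' @param min_leg_mm Minimum path length and along-wall extent of the
#'   excursion, default 50 mm.
#' @param band_mm Edge-band width, default the arena's `edge_band_mm`.
#' @param max_tortuosity Maximum path length relative to the excursion's
#'   deepest displacement, default 3.
#' @param min_hug_fraction Minimum fraction of excursion frames within
#'   `band_mm / 2` of the wall, default 0.7.
#' @return Bout data.frame with label `"back_and_forth"`.
#' @export
detect_back_and_forth <- function(traj, arena = traj$arena,
                                  return_radius_mm = 15, min_leg_mm = 50,
                                  band_mm = arena$edge_band_mm,
                                  max_tortuosity = 3,
                                  min_hug_fraction = 0.7) {
  stopifnot(inherits(traj, "swim_trajectory"),
            inherits(arena, "arena_geometry"))
  if (arena$shape != "rectangle")
    stop("back-and-forth detection is defined for rectangular arenas")
  W <- arena$width_mm; H <- arena$height_mm
  ok <- !traj$missing &
    wall_distance(arena, traj$x_mm, traj$y_mm) <= band_mm
  idx <- which(ok)
  if (length(idx) < 2) return(empty_bouts())
  # nearest wall: 1 left, 2 right, 3 bottom, 4 top (first wins on ties)
  dmat <- cbind(traj$x_mm[idx], W - traj$x_mm[idx],
                traj$y_mm[idx], H - traj$y_mm[idx])
  edge <- max.col(-dmat, ties.method = "first")
  opposite <- function(es) setequal(es, c(1, 2)) || setequal(es, c(3, 4))
  runs <- split(seq_along(idx), cumsum(c(0, diff(idx) > 1)))
  bouts <- list()
  for (rn in runs) {
    if (length(rn) < 2) next
    xs <- traj$x_mm[idx[rn]]; ys <- traj$y_mm[idx[rn]]; tsv <- traj$t_s[idx[rn]]
    ed <- edge[rn]
    hug <- wall_distance(arena, xs, ys) <= band_mm / 2
    n_hug <- 0L
    a <- 1L; cum <- 0; left_disk <- FALSE; edges <- ed[1]; max_disp <- 0
    mdx <- 0; mdy <- 0            # max |tangential displacement| from anchor
    along_ok <- function() {
      if (length(edges) == 1) {
        (if (edges <= 2) mdy else mdx) >= min_leg_mm
      } else max(mdx, mdy) >= min_leg_mm
    }
    for (j in 2:length(rn)) {
      cum <- cum + sqrt((xs[j] - xs[j - 1])^2 + (ys[j] - ys[j - 1])^2)
      edges <- union(edges, ed[j])
      mdx <- max(mdx, abs(xs[j] - xs[a])); mdy <- max(mdy, abs(ys[j] - ys[a]))
      n_hug <- n_hug + hug[j]
      if (length(edges) > 2 || (length(edges) == 2 && opposite(edges))) {
        a <- j; cum <- 0; left_disk <- FALSE; edges <- ed[j]
        max_disp <- 0; mdx <- 0; mdy <- 0; n_hug <- 0L
        next
      }
      disp <- sqrt((xs[j] - xs[a])^2 + (ys[j] - ys[a])^2)
      max_disp <- max(max_disp, disp)
      if (disp > return_radius_mm) {
        left_disk <- TRUE
      } else if (left_disk && cum >= min_leg_mm && along_ok() &&
                 cum <= max_tortuosity * max_disp &&
                 n_hug >= min_hug_fraction * (j - a)) {
        bouts[[length(bouts) + 1]] <-
          bout_row(traj$fish_id, "back_and_forth", tsv[a], tsv[j],
                   path_mm = cum)
        a <- j; cum <- 0; left_disk <- FALSE; edges <- ed[j]
        max_disp <- 0; mdx <- 0; mdy <- 0; n_hug <- 0L
      }
    }
  }
  rbind_bouts(bouts)
}

#' Summarise repetitive-behavior bouts
#'
#' @param bouts A bout data.frame from the detectors (rows outside the window
#'   are an error; the detectors only emit within the recording).
#' @param window `c(t0, t1)` analysis window in seconds.
#' @return A `repetitive_summary` data.frame: one row per label with
#'   `n_events` and `total_duration_s`; attribute `window`.
#' @export
summarize_repetitive <- function(bouts, window) {
  stopifnot(is.data.frame(bouts), length(window) == 2)
  if (nrow(bouts) &&
      any(bouts$start_s < window[1] - 1e-9 | bouts$end_s > window[2] + 1e-9))
    stop("bouts outside the analysis window")
  out <- data.frame(label = BOUT_LABELS,
                    n_events = 0L, total_duration_s = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_along(BOUT_LABELS)) {
    sel <- bouts$label == BOUT_LABELS[i]
    out$n_events[i] <- sum(sel)
    out$total_duration_s[i] <- sum(bouts$end_s[sel] - bouts$start_s[sel])
  }
  attr(out, "window") <- window
  class(out) <- c("repetitive_summary", "data.frame")
  out
}

#' Write bouts as CSV
#' @param bouts Bout data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bouts <- function(bouts, path) {
  utils::write.csv(bouts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Score detected bouts against ground truth
#'
#' Matches detector output to simulator ground-truth intervals and reports
#' per-label recall and precision. For interval labels (`stereotypic`,
#' `back_and_forth`) a truth bout is recalled when some detection overlaps
#' it by at least half the shorter duration, and a detection is correct when
#' some truth bout overlaps it likewise (overlap-based event scoring; a
#' detection split into two segments over one truth bout is not penalised).
#' Circling labels are scored by loop count: truth laps are grouped into
#' circling runs and detected loops are credited to a run when their
#' midpoint falls inside it (with a small margin), counting at most the
#' run's true lap number.
#'
#' @param detected Bout data.frame from the detectors.
#' @param truth Ground-truth bout data.frame (label, start_s, end_s).
#' @param margin_s Temporal margin for circling-loop assignment, default 2 s.
#' @return data.frame with columns `label`, `n_truth`, `n_detected`,
#'   `matched`, `recall`, `precision` (NA when undefined).
#' @export
score_detection <- function(detected, truth, margin_s = 2) {
  res <- list()
  for (lab in BOUT_LABELS) {
    det <- detected[detected$label == lab, , drop = FALSE]
    tru <- truth[truth$label == lab, , drop = FALSE]
    if (lab %in% c("large_circle_cw", "large_circle_ccw")) {
      matched <- 0L
      used <- rep(FALSE, nrow(det))
      if (nrow(tru)) {
        grp <- cumsum(c(0, diff(tru$start_s) -
                          (tru$end_s[-nrow(tru)] - tru$start_s[-nrow(tru)]) > margin_s))
        for (g in unique(grp)) {
          sel <- grp == g
          r0 <- min(tru$start_s[sel]) - margin_s
          r1 <- max(tru$end_s[sel]) + margin_s
          mid <- (det$start_s + det$end_s) / 2
          cand <- which(!used & mid >= r0 & mid <= r1)
          take <- utils::head(cand, sum(sel))
          used[take] <- TRUE
          matched <- matched + length(take)
        }
      }
      rec <- if (nrow(tru)) matched / nrow(tru) else NA_real_
      prec <- if (nrow(det)) matched / nrow(det) else NA_real_
      n_match <- matched
    } else {
      hit <- function(qs, qe, rs, re) {
        # does interval (qs, qe) overlap any (rs, re) by >= half the
        # shorter duration?
        vapply(seq_along(qs), function(i) {
          ov <- pmin(qe[i], re) - pmax(qs[i], rs)
          any(ov >= 0.5 * pmin(qe[i] - qs[i], re - rs))
        }, logical(1))
      }
      tru_hit <- if (nrow(tru)) hit(tru$start_s, tru$end_s,
                                    det$start_s, det$end_s) else logical(0)
      det_hit <- if (nrow(det)) hit(det$start_s, det$end_s,
                                    tru$start_s, tru$end_s) else logical(0)
      n_match <- sum(tru_hit)
      rec <- if (nrow(tru)) mean(tru_hit) else NA_real_
      prec <- if (nrow(det)) mean(det_hit) else NA_real_
    }
    res[[lab]] <- data.frame(label = lab, n_truth = nrow(tru),
                             n_detected = nrow(det), matched = n_match,
                             recall = rec, precision = prec,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
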