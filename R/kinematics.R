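#' Path distance over a time window
#'
#' Sum of Euclidean step lengths between consecutive non-missing frames whose
#' step interval `[t_i, t_{i+1})` overlaps `[t0, t1)`; steps straddling a
#' window edge contribute in proportion to the overlapped fraction of their
#' duration. Steps adjacent to an unrepaired tracking gap contribute nothing.
#'
#' @param traj A [trajectory()].
#' @param t0_s,t1_s Window bounds in seconds, `t0_s < t1_s`, inside the
#'   trajectory span.
#' @return Distance in mm.
#' @export
path_distance <- function(traj, t0_s = NULL, t1_s = NULL) {
  stopifnot(inherits(traj, "swim_trajectory"))
  sp <- traj_span(traj)
  if (is.null(t0_s)) t0_s <- sp[1]
  if (is.null(t1_s)) t1_s <- sp[2]
  if (t0_s >= t1_s) stop("window must have t0_s < t1_s")
  if (t0_s < sp[1] - 1e-9 || t1_s > sp[2] + 1e-9)
    stop(sprintf("window [%g, %g] outside trajectory span [%g, %g]",
                 t0_s, t1_s, sp[1], sp[2]))
  st <- step_table(traj)
  if (!nrow(st)) return(0)
  frac <- pmax(0, pmin(t1_s, st$b) - pmax(t0_s, st$a)) / (st$b - st$a)
  sum(st$d * frac)
}

# Internal: one row per valid step (both endpoints non-missing).
step_table <- function(traj) {
  n <- length(traj$t_s)
  i <- seq_len(n - 1)
  ok <- !traj$missing[i] & !traj$missing[i + 1]
  i <- i[ok]
  data.frame(a = traj$t_s[i], b = traj$t_s[i + 1],
             d = sqrt((traj$x_mm[i + 1] - traj$x_mm[i])^2 +
                      (traj$y_mm[i + 1] - traj$y_mm[i])^2),
             mx = (traj$x_mm[i] + traj$x_mm[i + 1]) / 2,
             my = (traj$y_mm[i] + traj$y_mm[i + 1]) / 2)
}

#' Bin locomotor activity over a light/dark schedule
#'
#' Pools travelled distance into fixed-width time bins (1 min by default, the
#' standard pooling for the larval assay) and labels each bin with the epoch
#' covering its midpoint. Bins are left-closed right-open; a trailing partial
#' bin (when the schedule span is not a bin multiple) is dropped.
#'
#' @param traj A [trajectory()]; distances are usually computed on
#'   jitter-suppressed trajectories (see [suppress_jitter()]).
#' @param schedule A [light_schedule()] spanning the trajectory.
#' @param bin_s Bin width in seconds, default 60; must not exceed the
#'   shortest epoch (labels would be ambiguous).
#' @return A `binned_activity` data.frame with columns `fish_id`,
#'   `bin_start_s`, `bin_end_s`, `epoch`, `condition`, `cycle`, `distance_mm`.
#' @export
bin_activity <- function(traj, schedule, bin_s = 60) {
  stopifnot(inherits(traj, "swim_trajectory"),
            inherits(schedule, "light_schedule"))
  if (bin_s <= 0) stop("bin_s must be > 0")
  if (bin_s > min(schedule$end_s - schedule$start_s))
    stop("bin_s longer than the shortest epoch; bin labels would be ambiguous")
  span <- schedule_span(schedule)
  if (max(traj$t_s) < span - bin_s)
    warning("trajectory ends well before the schedule span; trailing bins empty")
  n_bins <- floor(span / bin_s + 1e-9)
  dist <- numeric(n_bins)
  st <- step_table(traj)
  if (nrow(st)) {
    if (max(st$b - st$a) > bin_s)
      stop("frame interval exceeds bin_s")
    ia <- pmin(floor(st$a / bin_s), n_bins - 1)
    frac1 <- pmin(1, ((ia + 1) * bin_s - st$a) / (st$b - st$a))
    add <- function(idx, val) {
      keep <- idx >= 0 & idx < n_bins & val > 0
      if (any(keep)) {
        agg <- rowsum(val[keep], idx[keep])
        dist[as.integer(rownames(agg)) + 1] <<-
          dist[as.integer(rownames(agg)) + 1] + agg[, 1]
      }
    }
    add(ia, st$d * frac1)
    add(ia + 1, st$d * (1 - frac1))
  }
  mid <- (seq_len(n_bins) - 0.5) * bin_s
  out <- data.frame(fish_id = traj$fish_id,
                    bin_start_s = (seq_len(n_bins) - 1) * bin_s,
                    bin_end_s = seq_len(n_bins) * bin_s,
                    epoch = epoch_at(schedule, mid, "label"),
                    condition = epoch_at(schedule, mid, "condition"),
                    cycle = schedule$cycle[findInterval(mid, schedule$start_s)],
                    distance_mm = dist,
                    stringsAsFactors = FALSE)
  attr(out, "bin_s") <- bin_s
  class(out) <- c("binned_activity", "data.frame")
  out
}

#' Mean distance moved per minute within an epoch
#'
#' @param binned A [bin_activity()] result.
#' @param epoch_label Epoch to average over (e.g. `"L0"`).
#' @return Mean distance in mm/min.
#' @export
mean_distance_per_min <- function(binned, epoch_label) {
  stopifnot(inherits(binned, "binned_activity"))
  sel <- !is.na(binned$epoch) & binned$epoch == epoch_label
  if (!any(sel))
    stop(sprintf("no bins labelled '%s' in the binned activity", epoch_label))
  mean(binned$distance_mm[sel]) * 60 / attr(binned, "bin_s")
}

#' Photomotor light/dark response ratio for one cycle
#'
#' Ratio of the mean per-minute distance moved in the dark phase to the mean
#' in the preceding light phase of the same transition cycle. A zero
#' light-phase mean makes the ratio undefined; it is then reported as `NA`
#' with `undefined = TRUE` rather than raising an error.
#'
#' @param binned A [bin_activity()] result.
#' @param cycle Cycle index (1 or 2 in the standard protocol).
#' @return An object of class `cycle_response` with fields `cycle`,
#'   `mean_dark_mm_per_min`, `mean_light_mm_per_min`, `ratio`, `undefined`.
#' @export
light_dark_ratio <- function(binned, cycle) {
  stopifnot(inherits(binned, "binned_activity"))
  sel <- !is.na(binned$cycle) & binned$cycle == cycle
  if (!any(sel & binned$condition == "light") ||
      !any(sel & binned$condition == "dark"))
    stop(sprintf("cycle %s needs at least one light and one dark bin", cycle))
  k <- 60 / attr(binned, "bin_s")
  ml <- mean(binned$distance_mm[sel & binned$condition == "light"]) * k
  md <- mean(binned$distance_mm[sel & binned$condition == "dark"]) * k
  undef <- ml <= 0
  structure(list(cycle = cycle, mean_dark_mm_per_min = md,
                 mean_light_mm_per_min = ml,
                 ratio = if (undef) NA_real_ else md / ml,
                 undefined = undef),
            class = "cycle_response")
}

#' @export
print.cycle_response <- function(x, ...) {
  cat(sprintf("<cycle_response> cycle %s: dark %.2f / light %.2f mm/min, ratio %s\n",
              x$cycle, x$mean_dark_mm_per_min, x$mean_light_mm_per_min,
              if (x$undefined) "undefined" else sprintf("%.3f", x$ratio)))
  invisible(x)
}
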