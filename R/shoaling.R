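#' Interindividual distance of a shoal
#'
#' Per frame, the mean over all k(k-1)/2 pairwise Euclidean distances among
#' the shoal members; the scalar index is the time-average of that series
#' over the window. Frames in which any fish is missing are dropped (pairwise
#' means over partial frames are biased) and the dropped fraction is
#' reported.
#'
#' @param trajs List of >= 2 [trajectory()] objects recorded together; their
#'   timestamps must agree within one frame interval.
#' @param window `c(t0, t1)` in seconds; default the common span.
#' @return An object of class `iid_result`: `mean_mm`, `series` (data.frame
#'   `t_s`, `iid_mm`), `n_fish`, `frac_dropped`.
#' @export
interindividual_distance <- function(trajs, window = NULL) {
  stopifnot(is.list(trajs), length(trajs) >= 2,
            all(vapply(trajs, inherits, logical(1), "swim_trajectory")))
  k <- length(trajs)
  n <- length(trajs[[1]]$t_s)
  t_ref <- trajs[[1]]$t_s
  dt <- 1 / trajs[[1]]$frame_rate_hz
  for (tr in trajs[-1]) {
    if (length(tr$t_s) != n || max(abs(tr$t_s - t_ref)) > dt + 1e-9)
      stop("trajectories are not synchronized (timestamps differ by more than one frame)")
  }
  if (is.null(window)) window <- range(t_ref)
  sel <- t_ref >= window[1] & t_ref <= window[2]
  X <- sapply(trajs, function(tr) tr$x_mm[sel])
  Y <- sapply(trajs, function(tr) tr$y_mm[sel])
  complete <- rowSums(is.na(X) | is.na(Y)) == 0
  pairs <- utils::combn(k, 2)
  acc <- numeric(nrow(X))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    acc <- acc + sqrt((X[, i] - X[, j])^2 + (Y[, i] - Y[, j])^2)
  }
  iid <- acc / ncol(pairs)
  iid[!complete] <- NA_real_
  structure(list(mean_mm = mean(iid[complete]),
                 series = data.frame(t_s = t_ref[sel], iid_mm = iid),
                 n_fish = k,
                 frac_dropped = 1 - mean(complete)),
            class = "iid_result")
}

#' @export
print.iid_result <- function(x, ...) {
  cat(sprintf("<iid_result> %d fish: mean interindividual distance %.2f mm (%.1f%% frames dropped)\n",
              x$n_fish, x$mean_mm, 100 * x$frac_dropped))
  invisible(x)
}
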