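#' Significance stars
#'
#' Star convention used throughout the report tables: `*` p < 0.05,
#' `**` p < 0.01, `***` p < 0.001, `****` p < 0.0001; `ns` otherwise.
#'
#' @param p Numeric p values.
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[p < 0.0001] <- "****"
  out[is.na(p)] <- NA_character_
  out
}

#' Unpaired two-group comparison
#'
#' Unpaired two-sided Student's t test (equal-variance pooling by default,
#' matching the usual reporting of behavioral panels; set `welch = TRUE` for
#' the unequal-variance form), with group means and SEMs. Zero pooled
#' variance with equal means yields t = 0, p = 1 rather than an error.
#'
#' @param values_a,values_b Numeric vectors (each n >= 2, finite).
#' @param labels Character length-2 group labels.
#' @param welch Use Welch's correction instead of pooling.
#' @return An object of class `group_comparison`: `labels`, `n`, `mean`,
#'   `sem`, `t`, `df`, `p`, `stars`.
#' @export
compare_groups <- function(values_a, values_b, labels = c("a", "b"),
                           welch = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs n >= 2")
  if (!all(is.finite(values_a)) || !all(is.finite(values_b)))
    stop("group values must be finite")
  na <- length(values_a); nb <- length(values_b)
  ma <- mean(values_a); mb <- mean(values_b)
  va <- stats::var(values_a); vb <- stats::var(values_b)
  if (va == 0 && vb == 0) {
    tt <- if (ma == mb)
      list(statistic = c(t = 0), parameter = c(df = na + nb - 2), p.value = 1)
    else
      list(statistic = c(t = sign(ma - mb) * Inf),
           parameter = c(df = na + nb - 2), p.value = 0)
  } else {
    tt <- stats::t.test(values_a, values_b, var.equal = !welch)
  }
  structure(list(labels = labels, n = c(na, nb), mean = c(ma, mb),
                 sem = c(sqrt(va / na), sqrt(vb / nb)),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, stars = significance_stars(tt$p.value)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (n=%d): %.4g +/- %.3g vs %s (n=%d): %.4g +/- %.3g\n",
              x$labels[1], x$n[1], x$mean[1], x$sem[1],
              x$labels[2], x$n[2], x$mean[2], x$sem[2]))
  cat(sprintf("  t = %.4g, df = %.4g, p = %.4g %s\n", x$t, x$df, x$p, x$stars))
  invisible(x)
}

#' @export
as.data.frame.group_comparison <- function(x, ..., metric = NA_character_) {
  data.frame(metric = metric,
             group_a = x$labels[1], group_b = x$labels[2],
             n_a = x$n[1], n_b = x$n[2],
             mean_a = x$mean[1], mean_b = x$mean[2],
             sem_a = x$sem[1], sem_b = x$sem[2],
             t = x$t, df = x$df, p = x$p, stars = x$stars,
             stringsAsFactors = FALSE)
}
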