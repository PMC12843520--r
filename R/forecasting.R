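#' Composite investment-interest score
#'
#' Unweighted mean of the five 7-point interest items.
#'
#' @param items Numeric vector (or matrix/data frame with 5 columns, one
#'   row per observation) of item scores in `[1, 7]`.
#' @param missing How to handle `NA` items: `"drop"` averages the
#'   remaining items, `"error"` fails. Missingness is reported via a
#'   message.
#' @return Numeric composite score(s).
#' @export
composite_interest <- function(items, missing = c("drop", "error")) {
  composite_scale(items, k = 5, missing = match.arg(missing))
}

#' Composite dynamic-capabilities score
#'
#' Unweighted mean of the fourteen 7-point DC items (sensing, seizing,
#' transforming).
#'
#' @inheritParams composite_interest
#' @return Numeric composite score(s).
#' @export
composite_dc <- function(items, missing = c("drop", "error")) {
  composite_scale(items, k = 14, missing = match.arg(missing))
}

composite_scale <- function(items, k, missing) {
  x <- if (is.null(dim(items))) matrix(as.numeric(items), nrow = 1) else as.matrix(items)
  if (ncol(x) != k) stop("expected ", k, " items", call. = FALSE)
  if (any(x < 1 | x > 7, na.rm = TRUE)) {
    stop("item scores must lie in [1, 7]", call. = FALSE)
  }
  n_miss <- sum(is.na(x))
  if (n_miss) {
    if (missing == "error") stop("missing item scores", call. = FALSE)
    message(n_miss, " missing item score(s) dropped from composites")
  }
  out <- rowMeans(x, na.rm = TRUE)
  if (nrow(x) == 1) out[[1]] else out
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a multi-item scale:
#' `alpha = k / (k - 1) * (1 - sum(item variances) / var(total))`.
#'
#' @param items Matrix or data frame, observations x items.
#' @return Numeric alpha.
#' @export
cronbach_alpha <- function(items) {
  x <- as.matrix(items)
  k <- ncol(x)
  if (k < 2) stop("need >= 2 items", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(x, 2, var)) / var(rowSums(x)))
}

#' Moment-to-moment forecasting of a per-video outcome
#'
#' Correlates a group-level windowed neural series with a per-video
#' outcome, one correlation per window across videos. Binary (0/1)
#' outcomes with `method = "pearson"` yield the point-biserial
#' correlation (identical to Pearson on the 0/1 coding);
#' `method = "spearman"` gives the rank-ordered variant. Windows where
#' either side is constant across videos are flagged undefined; windows
#' with fewer than 4 distinct outcome values are reported but flagged.
#'
#' @param metric Matrix of the group metric, windows x videos (or a data
#'   frame coercible to one).
#' @param outcome Numeric per-video outcome (length = number of videos).
#' @param windows Optional [make_windows()] grid supplying `start`/`end`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param metric_name Label stored in the result (e.g. "FAA", "ISC").
#' @return Data frame of class `forecast_result`: `window`, `start`,
#'   `end`, `metric`, `method`, `r`, `p`, `n_videos`, `flagged`.
#' @export
momentwise_forecast <- function(metric, outcome, windows = NULL,
                                method = c("pearson", "spearman"),
                                metric_name = "metric") {
  method <- match.arg(method)
  m <- as.matrix(metric)
  if (ncol(m) != length(outcome)) {
    stop("outcome length must match the number of videos", call. = FALSE)
  }
  if (ncol(m) < 4) stop("need >= 4 videos", call. = FALSE)
  binary <- all(outcome %in% c(0, 1))
  used <- if (binary && method == "pearson") "point-biserial" else method
  nw <- nrow(m)
  r <- p <- rep(NA_real_, nw)
  flagged <- rep(FALSE, nw)
  for (k in seq_len(nw)) {
    x <- m[k, ]
    if (sd(x) == 0 || sd(outcome) == 0) {
      flagged[k] <- TRUE
      next
    }
    ct <- suppressWarnings(cor.test(x, outcome, method = method,
                                    exact = FALSE))
    r[k] <- unname(ct$estimate)
    p[k] <- ct$p.value
    if (length(unique(outcome)) < 4 && !binary) flagged[k] <- TRUE
  }
  out <- data.frame(
    window = seq_len(nw),
    start = if (!is.null(windows)) windows$start else seq_len(nw) - 1,
    end = if (!is.null(windows)) windows$end else seq_len(nw),
    metric = metric_name, method = used, r = r, p = p,
    n_videos = ncol(m), flagged = flagged
  )
  class(out) <- c("forecast_result", "data.frame")
  out
}

#' Percentile bootstrap CI for a video-level correlation
#'
#' Resamples videos (the forecasting unit) with replacement, recomputes
#' the correlation, and returns the 2.5/97.5 percentiles. Degenerate
#' resamples (zero variance on either side) are redrawn and counted.
#'
#' @param metric,outcome Per-video vectors (>= 4 videos).
#' @param n_boot Bootstrap iterations (>= 100; default 5000).
#' @param seed Seed for the resampling stream.
#' @param method Correlation method.
#' @param conf Confidence level (default 0.95).
#' @return Numeric `c(lo, hi)`; `attr(, "n_redrawn")` counts redraws,
#'   `attr(, "r")` the point estimate.
#' @export
bootstrap_ci <- function(metric, outcome, n_boot = 5000, seed = NULL,
                         method = c("pearson", "spearman"), conf = 0.95) {
  method <- match.arg(method)
  if (length(metric) < 4) stop("need >= 4 videos", call. = FALSE)
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  with_seed(seed, {
    n <- length(metric)
    rs <- numeric(n_boot)
    redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (sd(metric[idx]) > 0 && sd(outcome[idx]) > 0) break
        redrawn <- redrawn + 1L
      }
      rs[b] <- cor(metric[idx], outcome[idx], method = method)
    }
    a <- (1 - conf) / 2
    ci <- unname(quantile(rs, c(a, 1 - a)))
    attr(ci, "n_redrawn") <- redrawn
    attr(ci, "r") <- cor(metric, outcome, method = method)
    ci
  })
}

#' Significant windows of a forecast
#'
#' Windows with `p < alpha`. Unadjusted by default, matching per-window
#' reporting conventions; `adjust = "fdr"` applies Benjamini-Hochberg
#' across windows for honest multiplicity control.
#'
#' @param results A [momentwise_forecast()] result.
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"fdr"`.
#' @return Integer vector of significant window indices.
#' @export
significance_mask <- function(results, alpha = 0.05,
                              adjust = c("none", "fdr")) {
  adjust <- match.arg(adjust)
  p <- results$p
  if (adjust == "fdr") p <- stats::p.adjust(p, method = "BH")
  which(!is.na(p) & p < alpha)
}

#' @export
print.forecast_result <- function(x, ...) {
  sig <- significance_mask(x)
  cat(sprintf("<forecast_result> %s vs outcome (%s), %d windows, %d videos\n",
              x$metric[1], x$method[1], nrow(x), x$n_videos[1]))
  if (all(is.na(x$r))) {
    cat("  undefined at every window (constant metric or outcome)\n")
  } else {
    k <- which.max(abs(x$r))
    cat(sprintf("  peak r = %+.3f at window [%g, %g) s; %d window(s) with p < 0.05\n",
                x$r[k], x$start[k], x$end[k], length(sig)))
  }
  invisible(x)
}

#' Plot a moment-to-moment forecast
#'
#' Correlation per window start with the significant windows shaded.
#'
#' @param x A `forecast_result`.
#' @param alpha Significance level for shading.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.forecast_result <- function(x, alpha = 0.05, ...) {
  graphics::plot(x$start, x$r, type = "l", xlab = "window start (s)",
                 ylab = "correlation r", ylim = c(-1, 1), ...)
  graphics::abline(h = 0, lty = 3)
  sig <- significance_mask(x, alpha)
  if (length(sig)) {
    graphics::points(x$start[sig], x$r[sig], pch = 16, col = "firebrick")
  }
  invisible(x)
}
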