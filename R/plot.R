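#' Double plot of a fitted seasonal rhythm
#'
#' Plots two concatenated annual cycles: observed outcome means (+/- SEM)
#' in 2-month bins, overlaid with the fitted cosine curve evaluated at the
#' fit's covariate means.  The repetition makes the rhythm visually
#' continuous across the year boundary.
#'
#' @param fit a `seasonal_fit` from [fit_cosinor()].
#' @param bin_months width of the summary bins in months (default 2).
#' @param file optional output path; `.svg` or `.png` by extension.  NULL
#'   draws on the active device.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the data frame of bin summaries.
#' @export
plot_double <- function(fit, bin_months = 2, file = NULL, ...) {
  stopifnot(inherits(fit, "seasonal_fit"))
  d <- fit$data
  y <- d[[fit$outcome]]
  doy <- angle_to_doy(date_to_angle(d[[fit$date_col]], fit$period_days),
                      fit$period_days)
  nb <- ceiling(12 / bin_months)
  bin <- pmin(floor((doy - 1) / (fit$period_days / nb)) + 1, nb)
  mids <- (seq_len(nb) - 0.5) * fit$period_days / nb
  agg <- data.frame(
    mid = mids,
    mean = tapply(y, factor(bin, levels = seq_len(nb)), mean),
    sem = tapply(y, factor(bin, levels = seq_len(nb)),
                 function(v) stats::sd(v) / sqrt(length(v))))

  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 7, height = 4.5)
    else grDevices::png(file, width = 840, height = 540)
    on.exit(grDevices::dev.off())
  }
  xx <- c(agg$mid, agg$mid + fit$period_days)
  yy <- rep(agg$mean, 2L)
  ss <- rep(agg$sem, 2L)
  curve_x <- seq(0, 2 * fit$period_days, length.out = 400)
  level <- mean(y)
  curve_y <- level + fit$amplitude *
    cos(2 * pi * curve_x / fit$period_days -
          fit$acrophase_rad + 2 * pi / fit$period_days)
  graphics::plot(xx, yy, pch = 16, xlab = "Day (two cycles)",
                 ylab = fit$outcome,
                 ylim = range(c(yy - ss, yy + ss, curve_y), na.rm = TRUE),
                 ...)
  graphics::arrows(xx, yy - ss, xx, yy + ss, angle = 90, code = 3,
                   length = 0.03)
  graphics::lines(curve_x, curve_y, lty = 2)
  graphics::abline(v = fit$period_days, col = "grey80")
  invisible(agg)
}

#' @export
plot.seasonal_fit <- function(x, ...) plot_double(x, ...)
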