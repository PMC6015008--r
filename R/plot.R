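# Figures: condition time courses and per-bin statistics ------------------

#' Plot the mean relative pupil change per condition
#'
#' Mean +/- 1 SE ribbon per condition across the 86 bins, for one age
#' group.
#'
#' @param tc An `sp_timecourse` from [preprocess_dataset()].
#' @param age_group Which group to plot.
#' @param file Optional PNG path; when `NULL`, draws on the active device.
#' @return The file path (or `NULL`), invisibly.
#' @export
plot_timecourse <- function(tc, age_group, file = NULL) {
  Y <- tc$age_groups[[age_group]]$array
  if (is.null(Y)) stop("no such age group: ", age_group, call. = FALSE)
  t <- tc$bin_times_ms
  cols <- c(familiar = "#4477AA", switched = "#EE6677", novel = "#228833")
  if (!is.null(file)) grDevices::png(file, width = 900, height = 500)
  n <- dim(Y)[1]
  means <- apply(Y, c(2, 3), mean)
  ses <- apply(Y, c(2, 3), sd) / sqrt(n)
  graphics::plot(range(t), range(means + ses, means - ses),
                 type = "n", xlab = "Time after sound onset (ms)",
                 ylab = "Relative pupil change (mm)",
                 main = sprintf("%s (n = %d)", age_group, n))
  graphics::abline(h = 0, col = "grey70")
  for (ci in seq_len(nrow(means))) {
    cond <- rownames(means)[ci]
    graphics::polygon(c(t, rev(t)),
                      c(means[ci, ] + ses[ci, ], rev(means[ci, ] - ses[ci, ])),
                      col = grDevices::adjustcolor(cols[[cond]], 0.2),
                      border = NA)
    graphics::lines(t, means[ci, ], col = cols[[cond]], lwd = 2)
  }
  graphics::legend("topleft", legend = rownames(means),
                   col = cols[rownames(means)], lwd = 2, bty = "n")
  if (!is.null(file)) grDevices::dev.off()
  invisible(file)
}

#' Plot per-bin F values and partial eta-squared
#'
#' F trace with the parametric critical value as a dashed line, and the
#' effect-size trace below it.
#'
#' @param analysis An `sp_analysis` from [analyze_timecourse()].
#' @param file Optional PNG path.
#' @return The file path (or `NULL`), invisibly.
#' @export
plot_bin_stats <- function(analysis, file = NULL) {
  b <- analysis$bins
  crit <- qf(1 - analysis$alpha, analysis$df[1], analysis$df[2])
  if (!is.null(file)) grDevices::png(file, width = 900, height = 700)
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit({ graphics::par(old); if (!is.null(file)) grDevices::dev.off() },
          add = TRUE)
  graphics::plot(b$time_ms, b$F, type = "l", lwd = 2,
                 xlab = "Time after sound onset (ms)", ylab = "F")
  graphics::abline(h = crit, lty = 2)
  if (any(b$significant_rule)) {
    graphics::points(b$time_ms[b$significant_rule], b$F[b$significant_rule],
                     pch = 16, col = "#EE6677")
  }
  graphics::plot(b$time_ms, b$eta_p2, type = "l", lwd = 2,
                 xlab = "Time after sound onset (ms)",
                 ylab = expression(eta[p]^2), ylim = c(0, 1))
  invisible(file)
}
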