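#' Plot one reach trial: trajectory and speed profile
#'
#' Left panel: the display items, start position, and hand path. Right
#' panel: the per-step hand speed with its fitted polynomial curve.
#'
#' @param x a \code{crt_trace}.
#' @param display optional \code{crt_display} to draw the items from.
#' @param poly_degree degree for the fitted speed curve.
#' @param ... ignored.
#' @export
plot.crt_trace <- function(x, display = NULL, poly_degree = 10, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  n <- max(30, ceiling(max(x$positions)))
  graphics::plot(NA, xlim = c(1, n), ylim = c(n, 1), asp = 1,
                 xlab = "column (px)", ylab = "row (px)",
                 main = paste0("trajectory '", x$code, "'"))
  if (!is.null(display)) {
    it <- display$config$items
    graphics::symbols(it$centroid_col, it$centroid_row,
                      circles = sqrt(it$area / pi), inches = FALSE,
                      add = TRUE, fg = "grey40")
  }
  graphics::points(x$target_centroid[2], x$target_centroid[1], pch = 3,
                   col = "red")
  graphics::lines(x$positions[, 2], x$positions[, 1], col = "blue")
  graphics::points(x$positions[1, 2], x$positions[1, 1], pch = 16)
  graphics::plot(x$speeds, type = "l", col = "blue",
                 xlab = "step", ylab = "speed (px/step)",
                 main = "speed profile")
  if (length(x$speeds) >= 3) {
    fc <- fit_speed_curve(x$speeds, poly_degree)
    graphics::lines(fc$t, fc$y, col = "orange", lwd = 2)
  }
  invisible(x)
}

#' Plot condition means of an experiment
#'
#' IL (top) and MD (bottom) per distractor configuration, one panel per
#' target position, small and large target overlaid -- the standard view
#' of the factorial reaching experiment.
#'
#' @param x a \code{crt_experiment} (or a summary data frame via
#'   \code{summary_df}).
#' @param measure "both", "il" or "md".
#' @param ... ignored.
#' @export
plot.crt_experiment <- function(x, measure = c("both", "il", "md"), ...) {
  measure <- match.arg(measure)
  s <- x$summary
  positions <- c("left", "middle", "right")
  rows <- if (measure == "both") 2L else 1L
  op <- graphics::par(mfrow = c(rows, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  panel <- function(col, ylab) {
    for (pos in positions) {
      sub <- s[s$target_position == pos, ]
      xs <- match(sub$distractor_config, c("dd", "Dd", "DD"))
      ylim <- range(s[[col]], na.rm = TRUE)
      graphics::plot(NA, xlim = c(0.8, 3.2), ylim = ylim, xaxt = "n",
                     xlab = "distractors", ylab = ylab,
                     main = paste("target", pos))
      graphics::axis(1, at = 1:3, labels = c("dd", "Dd", "DD"))
      for (sz in c("small", "large")) {
        sel <- sub$target_size == sz
        o <- order(xs[sel])
        graphics::lines(xs[sel][o], sub[[col]][sel][o],
                        lty = if (sz == "small") 1 else 2,
                        col = if (sz == "small") "blue" else "red")
        graphics::points(xs[sel][o], sub[[col]][sel][o],
                         pch = if (sz == "small") 15 else 8,
                         col = if (sz == "small") "blue" else "red")
      }
    }
  }
  if (measure %in% c("both", "il")) panel("mean_il", "IL (steps)")
  if (measure %in% c("both", "md")) panel("mean_md", "MD (px)")
  invisible(x)
}
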