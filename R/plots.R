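#' Plot a sliding-window affected-gene density scan
#'
#' Percentage of affected transcription units per window against the
#' window midpoint, with the cluster-calling threshold as a dashed line.
#'
#' @param scan a [window_scan()].
#' @param threshold_percent threshold line (study value 5).
#' @param ... passed to [graphics::plot()].
#' @export
plot_window_scan <- function(scan, threshold_percent = 5, ...) {
  stopifnot(inherits(scan, "window_scan"))
  ok <- !is.na(scan$percent)
  graphics::plot(scan$midpoint[ok] / 1e3, scan$percent[ok], type = "l",
                 xlab = "chromosome position (kbp)",
                 ylab = "affected transcription units (%)", ...)
  graphics::abline(h = threshold_percent, lty = 2, col = "grey40")
  invisible(scan)
}

#' Plot AT-content profiles of one or more sequence sets
#'
#' Mean windowed AT percentage against the window-start position of the
#' promoter window (1 = 750 bp upstream of the start codon; vertical line
#' at the start codon, position 751).
#'
#' @param profiles a single [at_profile()] or a list of them.
#' @param cols line colours.
#' @param ... passed to [graphics::plot()].
#' @export
plot_at_profile <- function(profiles, cols = c("blue", "red", "grey50"), ...) {
  if (inherits(profiles, "at_profile")) profiles <- list(profiles)
  rng <- range(unlist(lapply(profiles, `[[`, "mean")))
  graphics::plot(profiles[[1]]$positions, profiles[[1]]$mean, type = "n",
                 ylim = rng, xlab = "window start position (bp)",
                 ylab = "mean AT content (%)", ...)
  for (i in seq_along(profiles)) {
    graphics::lines(profiles[[i]]$positions, profiles[[i]]$mean,
                    col = cols[(i - 1) %% length(cols) + 1])
  }
  graphics::abline(v = 751, lty = 3, col = "grey40")
  graphics::legend("topright", bty = "n",
                   legend = vapply(profiles, `[[`, "", "set_label"),
                   col = cols[seq_along(profiles)], lty = 1)
  invisible(profiles)
}
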