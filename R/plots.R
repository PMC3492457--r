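#' @include AllClasses.R
NULL

#' Plot the canonical map of the time instants
#'
#' Scatter of every analyzed time instant on the first two canonical axes
#' (structure coefficients), with the selected regions highlighted when a
#' [RegionsOfInterest] is supplied.
#'
#' @param cr a [CanonicalResult].
#' @param regions optional [RegionsOfInterest].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted coordinates.
#' @export
plotCanonicalMap <- function(cr, regions = NULL, ...) {
  stopifnot(is(cr, "CanonicalResult"))
  xy <- cr@timeMap
  pct <- 100 * cr@varFraction[1:2]
  plot(xy[, 1], xy[, 2],
       xlab = sprintf("Canonical axis 1 (%.1f%%)", pct[1]),
       ylab = sprintf("Canonical axis 2 (%.1f%%)", pct[2]),
       pch = 16, col = "grey40", ...)
  lab <- unique(round(seq(1, nrow(xy), length.out = 8)))
  text(xy[lab, 1], xy[lab, 2], labels = sprintf("%g h", cr@times[lab]),
       pos = 3, cex = 0.7)
  if (!is.null(regions)) {
    i <- match(c(regions@t1, regions@t2), cr@times)
    points(xy[i, 1], xy[i, 2], pch = 1, cex = 2.2, col = c("red", "blue"),
           lwd = 2)
    legend("topleft", legend = sprintf(c("T1 = %g h", "T2 = %g h"),
                                       c(regions@t1, regions@t2)),
           col = c("red", "blue"), pch = 1, bty = "n")
  }
  invisible(xy)
}

#' Plot treatments in the (log T, r) synergy map
#'
#' One point per treatment at its replicate-mean coordinates, with the
#' classification thresholds as reference lines. The bottom-left quadrant
#' (fast transient, suppressed growth) is the ideal photodynamic response.
#'
#' @param report a [SynergyReport].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted treatment table.
#' @export
plotSynergyMap <- function(report, ...) {
  stopifnot(is(report, "SynergyReport"))
  tc <- report@treatmentCalls
  tc <- tc[tc$status == "determined", ]
  th <- report@thresholds
  plot(tc$logT, tc$r_per_h,
       xlab = sprintf("log%g(T [h])", th@logBase),
       ylab = "r (steady-state growth rate, /h)",
       pch = ifelse(tc$efficient, 16, 1),
       col = ifelse(tc$meetsCfCut, "red", "blue"), ...)
  abline(v = th@logTThreshold, h = th@rThreshold, lty = 2, col = "grey50")
  text(tc$logT, tc$r_per_h, labels = tc$label, pos = 3, cex = 0.6)
  legend("topleft",
         legend = c(sprintf("C.F >= %g %s", th@cfCut, report@units),
                    sprintf("C.F < %g %s", th@cfCut, report@units),
                    "efficient call"),
         col = c("red", "blue", "black"), pch = c(16, 1, 16), bty = "n")
  invisible(tc)
}
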