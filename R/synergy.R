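#' @include AllClasses.R
NULL

#' Concentration-fluence interaction
#'
#' The synergy axis of the factorial analysis: the product of photosensitizer
#' concentration and light fluence, in uM.J/cm^2.
#'
#' @param concentration photosensitizer concentration, uM (>= 0).
#' @param fluence light dose, J/cm^2 (>= 0).
#' @return numeric C*F product(s).
#' @examples
#' cfInteraction(0.5, 5)  # 2.5, on the default synergy boundary
#' @export
cfInteraction <- function(concentration, fluence) {
  stopifnot(all(concentration >= 0), all(fluence >= 0))
  concentration * fluence
}

## quadrant of the (log T, r) map relative to the thresholds
.quadrant <- function(fast, suppressed) {
  ifelse(fast & suppressed, "rapid+null-growth (ideal)",
  ifelse(!fast & !suppressed, "slow+regrowth (inefficient)",
  ifelse(fast, "rapid+regrowth", "slow+suppressed")))
}

#' Classify fitted wells against the synergy thresholds
#'
#' Applies the threshold rule to each row of a fit table (see [fitPlate()]):
#' a fast transient is `log(T) < logTThreshold` (strict, log base as
#' configured, T in hours), suppressed growth is `r < rThreshold` (strict),
#' and a well is called efficient when both hold. The interaction cuts are
#' inclusive (`cf >= cfCut`). Non-converged fits get an `"undetermined"`
#' status with the boolean calls withheld (NA). `k` carries no printed
#' threshold and is reported as a within-table percentile instead.
#'
#' @param fits fit table with columns `concentration_uM`, `fluence_J_cm2`,
#'   `k`, `T_h`, `r_per_h`, `converged`.
#' @param thresholds a [SynergyThresholds].
#' @return data.frame with cf, logT, the boolean calls, quadrant, k
#'   percentile and status; row order follows the input.
#' @export
classifyFits <- function(fits, thresholds = synergyThresholds()) {
  stopifnot(is(thresholds, "SynergyThresholds"))
  need <- c("concentration_uM", "fluence_J_cm2", "k", "T_h", "r_per_h",
            "converged")
  miss <- setdiff(need, names(fits))
  if (length(miss)) stop("fit table lacks column(s): ",
                         paste(miss, collapse = ", "))
  cf <- cfInteraction(fits$concentration_uM, fits$fluence_J_cm2)
  logT <- log(fits$T_h, base = thresholds@logBase)
  fast <- logT < thresholds@logTThreshold
  supp <- fits$r_per_h < thresholds@rThreshold
  ok <- fits$converged & is.finite(logT) & is.finite(fits$r_per_h)
  fast[!ok] <- NA
  supp[!ok] <- NA
  kok <- fits$k[ok]
  kPct <- rep(NA_real_, nrow(fits))
  if (length(kok))
    kPct[ok] <- vapply(fits$k[ok], function(v) mean(kok <= v) * 100,
                       numeric(1))
  out <- data.frame(fits[, intersect(c("well", "label", "concentration_uM",
                                       "fluence_J_cm2", "replicate"),
                                     names(fits)), drop = FALSE],
                    cf = cf, logT = logT, r_per_h = fits$r_per_h,
                    fastTransient = fast, suppressedGrowth = supp,
                    kPercentile = kPct,
                    quadrant = ifelse(ok, .quadrant(fast, supp),
                                      "undetermined"),
                    efficient = fast & supp,
                    meetsCfCut = cf >= thresholds@cfCut,
                    meetsCfCutStrict = cf >= thresholds@cfCutStrict,
                    status = ifelse(ok, "determined", "undetermined"))
  attr(out, "cf_units") <- "uM.J/cm2"
  attr(out, "log_base") <- thresholds@logBase
  out
}

#' Per-treatment synergy report
#'
#' Aggregates a per-well fit table to treatment level (mean of the converged
#' replicate estimates of T and r per treatment), classifies each treatment
#' against the thresholds, and cross-tabulates the efficient calls with the
#' `C.F >= cfCut` interaction rule. Interaction units (uM.J/cm^2) and the
#' log base are recorded in the report.
#'
#' @param fits a fit table from [fitPlate()] with at least one converged row.
#' @param thresholds a [SynergyThresholds].
#' @return a [SynergyReport].
#' @export
synergyReport <- function(fits, thresholds = synergyThresholds()) {
  wellCalls <- classifyFits(fits, thresholds)
  if (!any(wellCalls$status == "determined"))
    stop("all fits are undetermined; nothing to report")
  ok <- fits$converged & is.finite(fits$T_h) & is.finite(fits$r_per_h)
  key <- paste(fits$concentration_uM, fits$fluence_J_cm2, sep = "|")
  agg <- do.call(rbind, lapply(split(seq_len(nrow(fits)), key), function(i) {
    iOk <- i[ok[i]]
    data.frame(concentration_uM = fits$concentration_uM[i[1L]],
               fluence_J_cm2 = fits$fluence_J_cm2[i[1L]],
               nWells = length(i), nConverged = length(iOk),
               k = if (length(iOk)) mean(fits$k[iOk]) else NA_real_,
               T_h = if (length(iOk)) mean(fits$T_h[iOk]) else NA_real_,
               r_per_h = if (length(iOk)) mean(fits$r_per_h[iOk]) else NA_real_,
               converged = length(iOk) > 0L)
  }))
  agg <- agg[order(agg$fluence_J_cm2, agg$concentration_uM), ]
  rownames(agg) <- NULL
  tCalls <- classifyFits(agg, thresholds)
  tCalls$label <- sprintf("C%g_F%g", tCalls$concentration_uM,
                          tCalls$fluence_J_cm2)
  det <- tCalls$status == "determined"
  agreement <- table(efficient = factor(tCalls$efficient[det],
                                        levels = c(FALSE, TRUE)),
                     cfAboveCut = factor(tCalls$meetsCfCut[det],
                                         levels = c(FALSE, TRUE)))
  new("SynergyReport", wellCalls = wellCalls, treatmentCalls = tCalls,
      agreement = agreement, thresholds = thresholds, units = "uM.J/cm2")
}
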