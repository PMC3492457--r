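#' @include AllClasses.R
NULL

#' Convert impedance readings to cell index
#'
#' CI = (z - z0) / 15, the instrument's dimensionless cell-index scale.
#' Negative CI (impedance below background) is passed through but flagged
#' with a message.
#'
#' @param z impedance at the measurement time(s), Ohm.
#' @param z0 background impedance of the well, Ohm.
#' @return numeric CI value(s).
#' @examples
#' impedanceToCI(30, 15)  # 1
#' @export
impedanceToCI <- function(z, z0) {
  ci <- (z - z0) / 15
  if (any(ci < 0))
    message(sum(ci < 0), " CI value(s) below background (negative CI) retained")
  ci
}

## snap a requested time onto the trace grid: nearest point, ties toward
## the earlier instant (determinism)
.snapTime <- function(times, t) {
  if (t < min(times) || t > max(times))
    stop(sprintf("time %g h is outside the trace span [%g, %g] h",
                 t, min(times), max(times)))
  d <- abs(times - t)
  i <- which(d == min(d))[1L]
  if (abs(times[i] - t) > 1e-9)
    message(sprintf("time %g h snapped to grid point %g h", t, times[i]))
  i
}

#' @rdname normalizeCI
#' @export
setMethod("normalizeCI", "CITrace", function(trace, t0 = 25) {
  i0 <- .snapTime(trace@times, t0)
  ref <- trace@values[i0]
  if (ref <= 0)
    stop(sprintf("well %s: CI at t0 = %g h is %g (must be > 0)",
                 trace@well, trace@times[i0], ref))
  v <- trace@values / ref
  v[i0] <- 1  # exact by construction
  new("NCITrace", well = trace@well, times = trace@times, values = v,
      clock = trace@clock, t0Ref = trace@times[i0])
})

#' @rdname transformCI
#' @export
setMethod("transformCI", "CITrace", function(trace, originT, floorEps = 1e-3) {
  if (floorEps <= 0) stop("floorEps must be > 0")
  v <- trace@values
  nBad <- sum(v <= 0)
  if (nBad > 0) {
    warning(sprintf("well %s: %d non-positive CI value(s) floored at %g before log transform",
                    trace@well, nBad, floorEps))
    v[v <= 0] <- floorEps
  }
  i0 <- .snapTime(trace@times, originT)
  x <- log(v / v[i0])
  new("TCITrace", well = trace@well, times = trace@times, values = x,
      clock = trace@clock, originCI = v[i0], originT = trace@times[i0])
})

#' @rdname inverseTransform
#' @export
setMethod("inverseTransform", "TCITrace", function(tci) {
  CITrace(tci@well, tci@times, tci@originCI * exp(tci@values),
          clock = tci@clock)
})
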