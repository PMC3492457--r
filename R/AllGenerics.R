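#' @include rtcakinetics-package.R
NULL

#' Well identifiers of a plate object
#'
#' @param x a [PlateMap] or [TraceSet].
#' @return Character vector of well ids.
#' @export
setGeneric("wells", function(x) standardGeneric("wells"))

#' Treatment table of a design
#'
#' One row per distinct treatment (concentration x fluence combination).
#'
#' @param x a [PlateMap].
#' @return data.frame with columns `concentration_uM`, `fluence_J_cm2`,
#'   `label` and, when present, `gadolinium_uM`.
#' @export
setGeneric("treatments", function(x) standardGeneric("treatments"))

#' @rdname CITrace-class
#' @param x a trace object.
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))

#' @rdname CITrace-class
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' @rdname CITrace-class
#' @export
setGeneric("traceClock", function(x) standardGeneric("traceClock"))

#' Evaluate a dose-response map
#'
#' @param map a [DoseResponseMap].
#' @param concentration photosensitizer concentration, uM.
#' @param fluence light dose, J/cm^2.
#' @return data.frame with columns `cf`, `k`, `T_h`, `r_per_h`.
#' @export
setGeneric("doseResponse",
           function(map, concentration, fluence) standardGeneric("doseResponse"))

#' Normalize a CI trace at a reference time
#'
#' @param trace a [CITrace].
#' @param t0 reference time in hours (on the trace's clock).
#' @return an [NCITrace] whose value at the snapped `t0` is exactly 1.
#' @export
setGeneric("normalizeCI", function(trace, t0 = 25) standardGeneric("normalizeCI"))

#' Log-ratio transform of a CI trace
#'
#' Produces the transformed cell index x(t) = ln(y(t) / y(origin)) used as the
#' fitting scale of the exponential-linear kinetic model.
#'
#' @param trace a [CITrace].
#' @param originT transform origin in hours (typically the irradiation time).
#' @param floorEps values at or below zero are floored here before the log.
#' @return a [TCITrace].
#' @export
setGeneric("transformCI",
           function(trace, originT, floorEps = 1e-3) standardGeneric("transformCI"))

#' Invert the TCI transform
#'
#' @param tci a [TCITrace].
#' @return the [CITrace] whose transform reproduces `tci`.
#' @export
setGeneric("inverseTransform", function(tci) standardGeneric("inverseTransform"))

#' Predict the exponential-linear model
#'
#' @param t time since the transform origin, hours.
#' @param params a [KineticParams].
#' @return numeric TCI values.
#' @export
setGeneric("modelPredict", function(t, params) standardGeneric("modelPredict"))

#' Fit the exponential-linear model to one transformed trace
#'
#' @param tci a [TCITrace] covering the post-irradiation period.
#' @param ... further arguments (`maxStarts`, `minPoints`).
#' @return a [FitResult].
#' @export
setGeneric("fitWell", function(tci, ...) standardGeneric("fitWell"))
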