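#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------- PlateMap

#' Plate map of a factorial RTCA experiment
#'
#' Maps each well to its treatment (photosensitizer concentration in uM,
#' light fluence in J/cm^2) and replicate index. Constructed from a
#' data.frame (see [readPlateMap()]) or from factorial levels with
#' [factorialPlateMap()].
#'
#' @slot map data.frame with columns `well`, `concentration_uM`,
#'   `fluence_J_cm2`, `replicate` and optionally `gadolinium_uM`, `label`;
#'   extra columns are preserved as metadata.
#' @export
setClass("PlateMap", representation(map = "data.frame"))

.plateRequired <- c("well", "concentration_uM", "fluence_J_cm2", "replicate")

setValidity("PlateMap", function(object) {
  m <- object@map
  miss <- setdiff(.plateRequired, names(m))
  if (length(miss))
    return(sprintf("missing column '%s'", miss[1L]))
  if (nrow(m) == 0L)
    return(TRUE)
  if (anyDuplicated(m$well))
    return(sprintf("duplicate well id: %s",
                   paste(unique(m$well[duplicated(m$well)]), collapse = ", ")))
  if (any(m$concentration_uM < 0) || any(m$fluence_J_cm2 < 0))
    return("concentration and fluence must be non-negative")
  if ("label" %in% names(m)) {
    ## label identifies the treatment: one label per (C, F) and vice versa
    u <- unique(m[, c("concentration_uM", "fluence_J_cm2", "label")])
    if (anyDuplicated(u$label) ||
        anyDuplicated(u[, c("concentration_uM", "fluence_J_cm2")]))
      return("treatment labels must map 1:1 to (concentration, fluence)")
  }
  ## replicate indices must be 1..n without gaps within each treatment
  key <- paste(m$concentration_uM, m$fluence_J_cm2)
  for (k in unique(key)) {
    rep <- sort(m$replicate[key == k])
    if (!identical(as.integer(rep), seq_along(rep)))
      return(sprintf("replicate indices for treatment (%s) are not 1..n", k))
  }
  TRUE
})

#' @rdname PlateMap-class
#' @param map data.frame with the plate-map columns.
#' @export
PlateMap <- function(map) {
  map <- as.data.frame(map)
  if (!"label" %in% names(map) && all(.plateRequired[1:3] %in% names(map)))
    map$label <- sprintf("C%g_F%g", map$concentration_uM, map$fluence_J_cm2)
  new("PlateMap", map = map)
}

#' Full factorial plate map
#'
#' Builds the design grid of a plate experiment: every concentration crossed
#' with every fluence, each combination replicated. The default levels are the
#' six photosensitizer concentrations and four fluences of a 24-treatment,
#' 144-well screen.
#'
#' @param concentrations photosensitizer levels, uM.
#' @param fluences light-dose levels, J/cm^2.
#' @param replicates wells per treatment.
#' @param gadolinium optional matched gadolinium concentrations, uM (one per
#'   concentration level).
#' @return a [PlateMap].
#' @examples
#' pm <- factorialPlateMap()
#' nrow(treatments(pm))  # 24
#' length(wells(pm))     # 144
#' @export
factorialPlateMap <- function(concentrations = c(0, 0.05, 0.1, 0.5, 1, 10),
                              fluences = c(0, 1, 5, 10),
                              replicates = 6L,
                              gadolinium = NULL) {
  grid <- expand.grid(replicate = seq_len(replicates),
                      concentration_uM = concentrations,
                      fluence_J_cm2 = fluences,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("concentration_uM", "fluence_J_cm2", "replicate")]
  grid$well <- sprintf("W%03d", seq_len(nrow(grid)))
  if (!is.null(gadolinium)) {
    if (length(gadolinium) != length(concentrations))
      stop("gadolinium must have one value per concentration level")
    grid$gadolinium_uM <- gadolinium[match(grid$concentration_uM, concentrations)]
  }
  PlateMap(grid[, c("well", setdiff(names(grid), "well"))])
}

#' @rdname wells
#' @export
setMethod("wells", "PlateMap", function(x) x@map$well)

#' @rdname treatments
#' @export
setMethod("treatments", "PlateMap", function(x) {
  m <- x@map
  if (nrow(m) == 0L)
    return(data.frame(concentration_uM = numeric(), fluence_J_cm2 = numeric(),
                      label = character()))
  keep <- c("concentration_uM", "fluence_J_cm2",
            intersect("gadolinium_uM", names(m)))
  u <- unique(m[, keep, drop = FALSE])
  u <- u[order(u$fluence_J_cm2, u$concentration_uM), , drop = FALSE]
  u$label <- sprintf("C%g_F%g", u$concentration_uM, u$fluence_J_cm2)
  rownames(u) <- NULL
  u
})

#' @describeIn PlateMap-class plate map as a data.frame.
#' @param x a `PlateMap`.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "PlateMap", function(x, ...) x@map)

setMethod("show", "PlateMap", function(object) {
  cat("PlateMap with", nrow(object@map), "wells,",
      nrow(treatments(object)), "treatments\n")
  if (nrow(object@map)) {
    cat("  concentrations (uM):",
        paste(sort(unique(object@map$concentration_uM)), collapse = ", "), "\n")
    cat("  fluences (J/cm2):  ",
        paste(sort(unique(object@map$fluence_J_cm2)), collapse = ", "), "\n")
  }
})

## ----------------------------------------------------------------- traces

.clocks <- c("seeding", "exposure", "irradiation")

#' Cell-index time series of one well
#'
#' `CITrace` holds a well's dimensionless cell-index (CI) values on a strictly
#' increasing time grid in hours, together with the declared clock origin.
#' `NCITrace` adds the normalization time (value there is exactly 1) and
#' `TCITrace` holds the log-transformed values x(t) together with the CI value
#' and time used as transform origin.
#'
#' @slot well well id.
#' @slot times hours since the declared clock origin, strictly increasing.
#' @slot values CI (or NCI / TCI) values, same length as `times`.
#' @slot clock one of `"seeding"`, `"exposure"`, `"irradiation"`.
#' @aliases NCITrace-class TCITrace-class
#' @export
setClass("CITrace",
         representation(well = "character", times = "numeric",
                        values = "numeric", clock = "character"))

setValidity("CITrace", function(object) {
  if (length(object@well) != 1L) return("well must be a single id")
  if (length(object@times) != length(object@values))
    return("times and values must have equal length")
  if (length(object@times) < 2L) return("a trace needs at least 2 time points")
  if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
  if (!object@clock %in% .clocks)
    return(sprintf("clock must be one of %s", paste(.clocks, collapse = ", ")))
  if (any(!is.finite(object@values))) return("values must be finite")
  TRUE
})

#' @rdname CITrace-class
#' @param well,times,values,clock see slots.
#' @export
CITrace <- function(well, times, values, clock = "exposure") {
  new("CITrace", well = as.character(well), times = as.numeric(times),
      values = as.numeric(values), clock = clock)
}

#' @rdname CITrace-class
#' @slot t0Ref normalization time, hours.
#' @export
setClass("NCITrace", contains = "CITrace", representation(t0Ref = "numeric"))

setValidity("NCITrace", function(object) {
  i <- match(object@t0Ref, object@times)
  if (is.na(i)) return("t0Ref must be one of the trace's time points")
  if (abs(object@values[i] - 1) > 1e-12) return("value at t0Ref must be 1")
  TRUE
})

#' @rdname CITrace-class
#' @slot originCI CI value at the transform origin (> 0).
#' @slot originT transform origin, hours on the trace's clock.
#' @export
setClass("TCITrace", contains = "CITrace",
         representation(originCI = "numeric", originT = "numeric"))

setValidity("TCITrace", function(object) {
  if (length(object@originCI) != 1L || object@originCI <= 0)
    return("originCI must be a single positive value")
  if (length(object@originT) != 1L) return("originT must be a single time")
  TRUE
})

#' @rdname traceTimes
#' @export
setMethod("traceTimes", "CITrace", function(x) x@times)

#' @rdname traceTimes
#' @export
setMethod("traceValues", "CITrace", function(x) x@values)

#' @rdname traceTimes
#' @export
setMethod("traceClock", "CITrace", function(x) x@clock)

setMethod("show", "CITrace", function(object) {
  cat(class(object), sprintf("well %s: %d points, [%g, %g] h (%s clock)\n",
      object@well, length(object@times), min(object@times), max(object@times),
      object@clock))
})

#' Change the clock origin of a trace
#'
#' Clock conversions are explicit: shifting to a new origin subtracts
#' `offsetH` from the time axis and relabels the clock.
#'
#' @param trace a [CITrace].
#' @param to target clock label.
#' @param offsetH hours between the current and the target origin
#'   (new times = times - offsetH).
#' @return a trace of the same class on the new clock.
#' @export
convertClock <- function(trace, to, offsetH) {
  stopifnot(is(trace, "CITrace"), to %in% .clocks)
  trace@times <- trace@times - offsetH
  trace@clock <- to
  trace
}

#' Collection of per-well traces
#'
#' A [S4Vectors::SimpleList] of [CITrace] objects, named by well id. Wells may
#' sit on different time grids.
#'
#' @export
setClass("TraceSet", contains = "SimpleList",
         prototype = prototype(elementType = "CITrace"))

setValidity("TraceSet", function(object) {
  if (length(object) == 0L) return(TRUE)
  if (!all(vapply(object, is, logical(1), "CITrace")))
    return("all elements must be CITrace objects")
  ids <- vapply(object, function(tr) tr@well, character(1))
  if (anyDuplicated(ids)) return("well ids must be unique")
  TRUE
})

#' @rdname TraceSet-class
#' @param traces list of [CITrace] objects.
#' @export
TraceSet <- function(traces = list()) {
  names(traces) <- vapply(traces, function(tr) tr@well, character(1))
  new("TraceSet", SimpleList(traces))
}

#' @rdname wells
#' @export
setMethod("wells", "TraceSet", function(x) unname(names(x)))

setMethod("show", "TraceSet", function(object) {
  cat("TraceSet with", length(object), "wells")
  if (length(object)) {
    n <- vapply(object, function(tr) length(tr@times), integer(1))
    cat(sprintf("; %d-%d points per trace, clock(s): %s",
        min(n), max(n),
        paste(unique(vapply(object, traceClock, character(1))), collapse = ", ")))
  }
  cat("\n")
})

## ------------------------------------------------------------ model params

#' Exponential-linear kinetic parameters
#'
#' Parameters of x(t) = x0 - k (1 - exp(-t/T)) + r t on the transformed-CI
#' scale: `T` is the time constant of the transient decrease (hours), `k` its
#' magnitude (dimensionless, >= 0 by convention; k enters negatively so a
#' larger k means a deeper decrease), `r` the steady-state growth rate per
#' hour, `x0` the initial value and `sigma` the residual standard deviation on
#' the transformed scale.
#'
#' @slot x0,k,T,r,sigma numeric scalars.
#' @export
setClass("KineticParams",
         representation(x0 = "numeric", k = "numeric", T = "numeric",
                        r = "numeric", sigma = "numeric"))

setValidity("KineticParams", function(object) {
  for (s in c("x0", "k", "T", "r", "sigma"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      return(sprintf("%s must be a finite scalar", s))
  if (object@T <= 0) return("T must be > 0")
  if (object@k < 0) return("k must be >= 0 under the default sign convention")
  if (object@sigma < 0) return("sigma must be >= 0")
  TRUE
})

#' @rdname KineticParams-class
#' @param x0,k,T,r,sigma see slots.
#' @export
kineticParams <- function(x0 = 0, k = 0, T = 1, r = 0, sigma = 0) {
  new("KineticParams", x0 = x0, k = k, T = T, r = r, sigma = sigma)
}

#' @describeIn KineticParams-class parameters as a named numeric vector.
#' @param x a `KineticParams`.
#' @param ... unused.
#' @export
setMethod("as.numeric", "KineticParams", function(x, ...)
  c(x0 = x@x0, k = x@k, T = x@T, r = x@r, sigma = x@sigma))

setMethod("show", "KineticParams", function(object) {
  cat(sprintf("KineticParams: x0=%.4g k=%.4g T=%.4g h r=%.4g /h sigma=%.4g\n",
      object@x0, object@k, object@T, object@r, object@sigma))
})

## --------------------------------------------------------------- fit types

#' Result of fitting one well
#'
#' @slot params estimated [KineticParams] (sigma from residuals).
#' @slot covariance 4x4 covariance of (x0, k, T, r); NA when unavailable.
#' @slot rss residual sum of squares.
#' @slot converged logical.
#' @slot nPoints number of fitted time points.
#' @slot diagnostics list: Jacobian condition number, gradient norm at the
#'   optimum, weak-identifiability flag for T.
#' @export
setClass("FitResult",
         representation(params = "KineticParams", covariance = "matrix",
                        rss = "numeric", converged = "logical",
                        nPoints = "integer", diagnostics = "list"))

setValidity("FitResult", function(object) {
  if (object@rss < 0) return("rss must be >= 0")
  TRUE
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult (%s, n=%d, rss=%.4g)\n  ",
      if (object@converged) "converged" else "NOT converged",
      object@nPoints, object@rss))
  show(object@params)
})

#' Two-stage mixed-effects summary of one treatment
#'
#' @slot fixedEffects mean (x0, k, T, r) across converged replicate fits.
#' @slot randomEffectVariances method-of-moments between-well variances
#'   (between-well variance minus mean sampling variance, floored at 0).
#' @slot wellDeviations per-well deviations from the fixed effects.
#' @slot fits list of per-well [FitResult]s.
#' @export
setClass("MixedFit",
         representation(fixedEffects = "numeric",
                        randomEffectVariances = "numeric",
                        wellDeviations = "matrix", fits = "list"))

setMethod("show", "MixedFit", function(object) {
  cat("MixedFit over", nrow(object@wellDeviations), "replicates\n")
  cat("  fixed:", paste(sprintf("%s=%.4g", names(object@fixedEffects),
                                object@fixedEffects), collapse = " "), "\n")
  cat("  RE var:", paste(sprintf("%s=%.3g", names(object@randomEffectVariances),
                                 object@randomEffectVariances), collapse = " "), "\n")
})

## ------------------------------------------------------ region selection

#' Matrix of NCI profiles over a study window
#'
#' Rows are wells, columns are time instants (hours); `groups` labels each row
#' with its treatment factor level (by default the concentration).
#'
#' @slot values numeric matrix (wells x time instants).
#' @slot times column time instants, hours.
#' @slot groups factor of row group labels.
#' @slot window study window, hours.
#' @export
setClass("ProfileMatrix",
         representation(values = "matrix", times = "numeric",
                        groups = "factor", window = "numeric"))

setValidity("ProfileMatrix", function(object) {
  if (ncol(object@values) != length(object@times))
    return("times must match the number of columns")
  if (nrow(object@values) != length(object@groups))
    return("groups must match the number of rows")
  if (nlevels(droplevels(object@groups)) < 2L) return("need at least 2 groups")
  if (min(table(droplevels(object@groups))) < 2L)
    return("need at least 2 wells per group")
  TRUE
})

setMethod("show", "ProfileMatrix", function(object) {
  cat(sprintf("ProfileMatrix: %d wells x %d time instants, %d groups, window [%g, %g] h\n",
      nrow(object@values), ncol(object@values),
      nlevels(droplevels(object@groups)), object@window[1], object@window[2]))
})

#' Canonical structure of the MANOVA discriminant analysis
#'
#' Eigen-structure of W^-1 B (between- over within-group scatter) computed
#' from a [ProfileMatrix], plus the canonical map coordinates of every time
#' instant on the first two axes.
#'
#' @slot eigenvalues non-negative, descending.
#' @slot varFraction eigenvalue_i / sum(eigenvalues).
#' @slot axes canonical directions in time-variable space (columns).
#' @slot scores per-well canonical coordinates.
#' @slot timeMap per-time-instant structure coefficients on axes 1-2.
#' @slot times time instants (hours) of the analyzed columns.
#' @slot nAxes number of meaningful axes, min(#groups - 1, #columns).
#' @export
setClass("CanonicalResult",
         representation(eigenvalues = "numeric", varFraction = "numeric",
                        axes = "matrix", scores = "matrix",
                        timeMap = "matrix", times = "numeric",
                        nAxes = "integer"))

setValidity("CanonicalResult", function(object) {
  if (any(object@eigenvalues < 0)) return("eigenvalues must be non-negative")
  if (is.unsorted(rev(object@eigenvalues))) return("eigenvalues must descend")
  s <- sum(object@varFraction)
  if (s > 0 && abs(s - 1) > 1e-8) return("varFraction must sum to 1")
  TRUE
})

setMethod("show", "CanonicalResult", function(object) {
  cat(sprintf("CanonicalResult: %d axes (%d meaningful), first two capture %.1f%% of variance\n",
      length(object@eigenvalues), object@nAxes,
      100 * sum(object@varFraction[1:min(2, length(object@varFraction))])))
})

#' Selected time regions of interest
#'
#' @slot t1,t2 selected time instants, hours (axis-2 and axis-1 picks).
#' @slot provenance data.frame with axis, pick and map distance.
#' @export
setClass("RegionsOfInterest",
         representation(t1 = "numeric", t2 = "numeric",
                        provenance = "data.frame"))

setValidity("RegionsOfInterest", function(object) {
  if (isTRUE(all.equal(object@t1, object@t2))) return("t1 and t2 must differ")
  TRUE
})

setMethod("show", "RegionsOfInterest", function(object) {
  cat(sprintf("RegionsOfInterest: T1 = %g h (axis 2), T2 = %g h (axis 1)\n",
      object@t1, object@t2))
})

#' One-way ANOVA at a time instant
#'
#' @slot fStatistic fixed-effects one-way F statistic.
#' @slot dfBetween,dfWithin degrees of freedom.
#' @slot pValue p value in `[0, 1]`.
#' @slot groupSummary per-group median and quartiles (boxplot-style).
#' @slot time analyzed time instant, hours.
#' @export
setClass("AnovaResult",
         representation(fStatistic = "numeric", dfBetween = "integer",
                        dfWithin = "integer", pValue = "numeric",
                        groupSummary = "data.frame", time = "numeric"))

setValidity("AnovaResult", function(object) {
  if (object@fStatistic < 0) return("F must be >= 0")
  if (object@pValue < 0 || object@pValue > 1) return("p must be in [0, 1]")
  if (object@dfBetween < 1L || object@dfWithin < 1L)
    return("degrees of freedom must be positive")
  TRUE
})

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf("AnovaResult at t = %g h: F(%d, %d) = %.4g, p = %.3g\n",
      object@time, object@dfBetween, object@dfWithin,
      object@fStatistic, object@pValue))
})

## ----------------------------------------------------------------- synergy

#' Thresholds of the synergy classification
#'
#' @slot logTThreshold threshold on log(T in hours); default 0, i.e. T = 1 h.
#' @slot rThreshold threshold on the steady-state growth rate; default 0 /h.
#' @slot cfCut concentration-fluence interaction cut, uM.J/cm^2 (inclusive).
#' @slot cfCutStrict stricter interaction cut (inclusive).
#' @slot logBase base of the T logarithm (10 by default).
#' @export
setClass("SynergyThresholds",
         representation(logTThreshold = "numeric", rThreshold = "numeric",
                        cfCut = "numeric", cfCutStrict = "numeric",
                        logBase = "numeric"))

setValidity("SynergyThresholds", function(object) {
  if (object@cfCut > object@cfCutStrict)
    return("cfCut must be <= cfCutStrict")
  if (object@logBase <= 1) return("logBase must be > 1")
  TRUE
})

#' @rdname SynergyThresholds-class
#' @param logTThreshold,rThreshold,cfCut,cfCutStrict,logBase see slots.
#' @export
synergyThresholds <- function(logTThreshold = 0, rThreshold = 0,
                              cfCut = 2.5, cfCutStrict = 5, logBase = 10) {
  new("SynergyThresholds", logTThreshold = logTThreshold,
      rThreshold = rThreshold, cfCut = cfCut, cfCutStrict = cfCutStrict,
      logBase = logBase)
}

setMethod("show", "SynergyThresholds", function(object) {
  cat(sprintf("SynergyThresholds: log%g(T) < %g, r < %g /h; C.F cuts >= %g / >= %g uM.J/cm2\n",
      object@logBase, object@logTThreshold, object@rThreshold,
      object@cfCut, object@cfCutStrict))
})

#' Synergy report of a fitted plate
#'
#' @slot wellCalls per-well classification table.
#' @slot treatmentCalls per-treatment classification from replicate-mean
#'   parameters, with (log T, r) map coordinates.
#' @slot agreement 2x2 table of efficient calls vs the C.F cut.
#' @slot thresholds the [SynergyThresholds] applied.
#' @slot units unit string of the interaction axis.
#' @export
setClass("SynergyReport",
         representation(wellCalls = "data.frame", treatmentCalls = "data.frame",
                        agreement = "table", thresholds = "SynergyThresholds",
                        units = "character"))

setMethod("show", "SynergyReport", function(object) {
  cat("SynergyReport:", nrow(object@treatmentCalls), "treatments,",
      sum(object@treatmentCalls$efficient, na.rm = TRUE), "called efficient\n")
  print(object@agreement)
})
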