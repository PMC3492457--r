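#' @include AllClasses.R
NULL

#' Ground-truth dose-response map of the simulator
#'
#' Maps a treatment (concentration C, fluence F) to the true kinetic
#' parameters of its post-irradiation response through smooth, monotone
#' functions of the interaction CF = C*F:
#' \itemize{
#'   \item k(CF) = k0 + kMax * CF^hill / (ec50K^hill + CF^hill)
#'   \item T(CF) = tMin + (tMax - tMin) * ec50T / (ec50T + CF)
#'   \item r(CF) = r0 - rDrop * CF / (ec50R + CF)
#' }
#' so k is non-decreasing and T, r non-increasing in CF, with k(C, 0) =
#' k(0, F) = k0. The default scales are calibrated so the T and r thresholds
#' of the synergy read-out (T = 1 h, r = 0 /h) are crossed at CF ~ 1.58
#' uM.J/cm^2, the geometric midpoint between the design's interaction levels
#' 1 and 2.5: treatments with CF >= 2.5 have log10(T) < 0 and r < 0, those
#' with CF <= 1 do not.
#'
#' @slot k0,kMax,ec50K,hill transient-magnitude response coefficients.
#' @slot tMax,tMin,ec50T time-constant response coefficients (hours).
#' @slot r0,rDrop,ec50R growth-rate response coefficients (per hour).
#' @export
setClass("DoseResponseMap",
         representation(k0 = "numeric", kMax = "numeric", ec50K = "numeric",
                        hill = "numeric", tMax = "numeric", tMin = "numeric",
                        ec50T = "numeric", r0 = "numeric", rDrop = "numeric",
                        ec50R = "numeric"))

setValidity("DoseResponseMap", function(object) {
  if (object@k0 < 0) return("k0 must be >= 0")
  if (object@tMin <= 0 || object@tMax < object@tMin)
    return("need 0 < tMin <= tMax")
  if (object@ec50K <= 0 || object@ec50T <= 0 || object@ec50R <= 0)
    return("half-saturation scales must be > 0")
  if (object@hill <= 0) return("hill must be > 0")
  TRUE
})

#' @rdname DoseResponseMap-class
#' @param k0,kMax,ec50K,hill,tMax,tMin,ec50T,r0,rDrop,ec50R see slots.
#' @export
doseResponseMap <- function(k0 = 0.05, kMax = 3, ec50K = 2.5, hill = 2,
                            tMax = 10, tMin = 0.5, ec50T = 0.088,
                            r0 = 0.05, rDrop = 0.08, ec50R = 0.95) {
  new("DoseResponseMap", k0 = k0, kMax = kMax, ec50K = ec50K, hill = hill,
      tMax = tMax, tMin = tMin, ec50T = ec50T, r0 = r0, rDrop = rDrop,
      ec50R = ec50R)
}

#' @rdname doseResponse
#' @export
setMethod("doseResponse", "DoseResponseMap",
          function(map, concentration, fluence) {
  cf <- concentration * fluence
  data.frame(
    cf = cf,
    k = map@k0 + map@kMax * cf^map@hill / (map@ec50K^map@hill + cf^map@hill),
    T_h = map@tMin + (map@tMax - map@tMin) * map@ec50T / (map@ec50T + cf),
    r_per_h = map@r0 - map@rDrop * cf / (map@ec50R + cf))
})

setMethod("show", "DoseResponseMap", function(object) {
  cat(sprintf(paste0("DoseResponseMap: k0=%g kMax=%g ec50K=%g hill=%g | ",
                     "T in [%g, %g] h ec50T=%g | r0=%g rDrop=%g ec50R=%g\n"),
      object@k0, object@kMax, object@ec50K, object@hill, object@tMin,
      object@tMax, object@ec50T, object@r0, object@rDrop, object@ec50R))
})

#' Configuration of the plate simulator
#'
#' @slot design the [PlateMap] to simulate.
#' @slot seed integer RNG seed; the same seed yields bit-identical output.
#' @slot sigma standard deviation of the Gaussian error on the transformed
#'   (log-CI) scale, i.e. multiplicative on CI.
#' @slot samplingH grid step in hours (0.25 = one reading every 15 min).
#' @slot preIrradiationH duration of the growth phase between exposure and
#'   irradiation, hours.
#' @slot postH monitored duration after irradiation, hours.
#' @slot growthRate exponential CI growth rate of the pre-irradiation phase,
#'   per hour.
#' @slot ci0 CI at seeding/exposure.
#' @slot washingDip numeric(0) to disable, else `c(depth, duration_h)` of the
#'   transient dip caused by the washing interruption at irradiation time.
#' @slot doseResponse the ground-truth [DoseResponseMap].
#' @slot lateDeclinePerH optional linear late-decline slope on the TCI scale
#'   applied after `lateDeclineAfterH`; 0 disables it.
#' @slot lateDeclineAfterH onset of the late decline, hours post-irradiation.
#' @export
setClass("GeneratorConfig",
         representation(design = "PlateMap", seed = "integer",
                        sigma = "numeric", samplingH = "numeric",
                        preIrradiationH = "numeric", postH = "numeric",
                        growthRate = "numeric", ci0 = "numeric",
                        washingDip = "numeric",
                        doseResponse = "DoseResponseMap",
                        lateDeclinePerH = "numeric",
                        lateDeclineAfterH = "numeric"))

setValidity("GeneratorConfig", function(object) {
  if (object@sigma < 0) return("sigma must be >= 0")
  if (object@samplingH <= 0) return("samplingH must be > 0")
  if (object@preIrradiationH <= 0 || object@postH <= 0)
    return("phase durations must be > 0")
  if (object@ci0 <= 0) return("ci0 must be > 0")
  if (length(object@washingDip) && length(object@washingDip) != 2L)
    return("washingDip must be numeric(0) or c(depth, duration_h)")
  TRUE
})

#' @rdname GeneratorConfig-class
#' @param design,seed,sigma,samplingH,preIrradiationH,postH,growthRate,ci0
#'   see slots.
#' @param washingDip `NULL` (default, off) or `c(depth, duration_h)`.
#' @param doseResponse,lateDeclinePerH,lateDeclineAfterH see slots.
#' @export
generatorConfig <- function(design = factorialPlateMap(), seed = 1L,
                            sigma = 0.05, samplingH = 0.25,
                            preIrradiationH = 24, postH = 30,
                            growthRate = log(1.4 / 0.2) / 24, ci0 = 0.2,
                            washingDip = NULL,
                            doseResponse = doseResponseMap(),
                            lateDeclinePerH = 0, lateDeclineAfterH = 60) {
  new("GeneratorConfig", design = design, seed = as.integer(seed),
      sigma = sigma, samplingH = samplingH,
      preIrradiationH = preIrradiationH, postH = postH,
      growthRate = growthRate, ci0 = ci0,
      washingDip = if (is.null(washingDip)) numeric() else washingDip,
      doseResponse = doseResponse, lateDeclinePerH = lateDeclinePerH,
      lateDeclineAfterH = lateDeclineAfterH)
}

## evaluate the exponential-linear model on the transformed scale
.elModel <- function(t, x0, k, T, r) x0 - k * (1 - exp(-t / T)) + r * t

#' Noiseless post-irradiation CI trace from kinetic parameters
#'
#' Maps the exponential-linear curve back to the CI scale:
#' y(t) = baselineCI * exp(x(t)) with x(t) = x0 - k (1 - exp(-t/T)) + r t.
#' The TCI transform of the returned trace reproduces the model curve
#' exactly.
#'
#' @param tGrid times since irradiation, hours (t = 0 allowed).
#' @param params a [KineticParams].
#' @param baselineCI CI at irradiation time, > 0.
#' @param well well id for the returned trace.
#' @return a [CITrace] on the irradiation clock.
#' @export
forwardCI <- function(tGrid, params, baselineCI, well = "sim") {
  stopifnot(is(params, "KineticParams"))
  if (baselineCI <= 0) stop("baselineCI must be > 0")
  x <- .elModel(tGrid, params@x0, params@k, params@T, params@r)
  CITrace(well, tGrid, baselineCI * exp(x), clock = "irradiation")
}

## run code under a seed without clobbering the caller's RNG state
.withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

#' Simulate a full plate experiment
#'
#' Generates one CI trace per well of the design: an exponential growth phase
#' from exposure to irradiation, then post-irradiation kinetics following the
#' exponential-linear model with treatment-specific ground-truth parameters
#' from the config's dose-response map. Noise is additive Gaussian on the
#' transformed (log) scale, hence multiplicative on CI. The ground truth is
#' returned alongside the data and is not inferable from the trace files
#' alone.
#'
#' @param config a [GeneratorConfig].
#' @return list with elements `traces` (a [TraceSet] on the exposure clock)
#'   and `truth` (data.frame: well, treatment, replicate, cf and the true
#'   x0, k, T_h, r_per_h, sigma, baseline_ci).
#' @examples
#' sim <- simulatePlate(generatorConfig(seed = 7))
#' length(sim$traces)  # 144
#' @export
simulatePlate <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  design <- as.data.frame(config@design)
  if (nrow(design) == 0L) stop("design has no wells")
  dt <- config@samplingH
  tPre <- seq(0, config@preIrradiationH, by = dt)
  tPost <- seq(dt, config@postH, by = dt)
  truthP <- doseResponse(config@doseResponse,
                         design$concentration_uM, design$fluence_J_cm2)
  baseline <- config@ci0 * exp(config@growthRate * config@preIrradiationH)
  .withSeed(config@seed, {
    traces <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
      yPre <- config@ci0 * exp(config@growthRate * tPre)
      x <- .elModel(tPost, 0, truthP$k[i], truthP$T_h[i], truthP$r_per_h[i])
      if (config@lateDeclinePerH > 0)
        x <- x - config@lateDeclinePerH * pmax(0, tPost - config@lateDeclineAfterH)
      y <- c(yPre, baseline * exp(x))
      if (config@sigma > 0)
        y <- y * exp(rnorm(length(y), 0, config@sigma))
      tr <- CITrace(design$well[i], c(tPre, config@preIrradiationH + tPost),
                    y, clock = "exposure")
      if (length(config@washingDip))
        tr <- injectWashingArtifact(tr, atH = config@preIrradiationH,
                                    depth = config@washingDip[1L],
                                    durationH = config@washingDip[2L])
      traces[[i]] <- tr
    }
    truth <- data.frame(design[, c("well", "concentration_uM",
                                   "fluence_J_cm2", "replicate")],
                        cf = truthP$cf, x0 = 0, k = truthP$k,
                        T_h = truthP$T_h, r_per_h = truthP$r_per_h,
                        sigma = config@sigma, baseline_ci = baseline)
    list(traces = TraceSet(traces), truth = truth)
  })
}

#' Inject a washing-step artifact into a trace
#'
#' Emulates the transient CI dip caused by the interruption of impedance
#' measurement during the washing step: samples inside
#' `[atH, atH + durationH]` are scaled down by `depth`, all others are left
#' untouched. A window shorter than the sampling step still affects the grid
#' point nearest to `atH`.
#'
#' @param trace a [CITrace].
#' @param atH window start, hours (must lie within the trace span).
#' @param depth fractional dip depth in `[0, 1]`.
#' @param durationH window length, hours.
#' @return the modified [CITrace].
#' @export
injectWashingArtifact <- function(trace, atH, depth, durationH) {
  stopifnot(is(trace, "CITrace"), depth >= 0, depth <= 1, durationH >= 0)
  tt <- trace@times
  if (atH < min(tt) || atH > max(tt))
    stop(sprintf("atH = %g h is outside the trace span [%g, %g] h",
                 atH, min(tt), max(tt)))
  inWindow <- tt >= atH & tt <= atH + durationH
  if (!any(inWindow))
    inWindow[which.min(abs(tt - atH))] <- TRUE
  trace@values[inWindow] <- trace@values[inWindow] * (1 - depth)
  trace
}
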