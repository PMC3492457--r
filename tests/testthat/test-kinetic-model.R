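test_that("model prediction follows the exponential-linear form", {
  p <- kineticParams(x0 = 0.3, k = 2, T = 5, r = 0.1)
  expect_equal(modelPredict(0, p), 0.3)                       # e^0 = 1
  expect_equal(modelPredict(50, kineticParams(x0 = 0, k = 2, T = 5, r = 0.1)),
               -2 * (1 - exp(-10)) + 5, tolerance = 1e-12)
  # k = 0 is a pure line
  expect_equal(modelPredict(0:10, kineticParams(x0 = 1, k = 0, T = 3, r = -0.2)),
               1 - 0.2 * (0:10))
  # finite and continuous over a wide range
  tt <- seq(0, 1000, length.out = 5000)
  v <- modelPredict(tt, p)
  expect_true(all(is.finite(v)))
  expect_lt(max(abs(diff(v))), 0.3)
  # a larger time constant slows the transient at any fixed t > 0 (checked
  # over the range where the transient has not fully decayed numerically)
  ts <- seq(0.01, 60, length.out = 500)
  slow <- modelPredict(ts, kineticParams(0, 2, 8, 0))
  fast <- modelPredict(ts, kineticParams(0, 2, 2, 0))
  expect_true(all(slow > fast))
})

test_that("noiseless profiles are recovered to numerical precision", {
  t <- seq(0.25, 30, 0.25)      # 120 points over 30 h
  p <- c(x0 = 0.05, k = 1.8, T = 2.4, r = -0.015)
  f <- fitWell(makeTCI(t, elCurve(t, p[1], p[2], p[3], p[4])))
  expect_true(f@converged)
  est <- as.numeric(f@params)
  expect_lt(max(abs(est[c("x0", "k", "T", "r")] - p) / pmax(abs(p), 1e-6)),
            1e-6)
  expect_lt(f@params@sigma, 1e-8)
  expect_error(fitWell(makeTCI(t[1:5], elCurve(t[1:5], 0, 1, 2, 0))),
               "at least 8")
})

test_that("noisy recovery stays within the simulation-calibrated accuracy", {
  t <- seq(0.25, 30, 0.25)
  p <- c(x0 = 0, k = 2, T = 3, r = -0.02)
  set.seed(12)
  err <- replicate(60, {
    x <- elCurve(t, p[1], p[2], p[3], p[4]) + rnorm(length(t), 0, 0.05)
    est <- as.numeric(fitWell(makeTCI(t, x))@params)
    abs(est[c("k", "T", "r")] - p[c("k", "T", "r")]) / abs(p[c("k", "T", "r")])
  })
  expect_lt(max(apply(err, 1, median)), 0.10)
})

test_that("flat profiles are flagged instead of returning a ridge point", {
  t <- seq(0.25, 30, 0.25)
  set.seed(13)
  x <- 0.05 + 0.03 * t + rnorm(length(t), 0, 0.05)   # no transient at all
  f <- fitWell(makeTCI(t, x))
  expect_true(f@converged)
  expect_lte(f@params@k, 0.05)
  expect_true(isTRUE(f@diagnostics$weakT))
})

test_that("the two-stage mixed summary separates between-well variance", {
  t <- seq(0.25, 30, 0.25)
  # identical true parameters: random-effect variances collapse to ~0
  set.seed(14)
  tcis <- lapply(1:6, function(i)
    makeTCI(t, elCurve(t, 0, 2, 3, -0.02) + rnorm(length(t), 0, 0.01),
            well = sprintf("w%d", i)))
  mf <- fitTreatmentMixed(tcis)
  expect_lt(mf@randomEffectVariances[["k"]], (0.05 * 2)^2)
  expect_lt(mf@randomEffectVariances[["T"]], (0.05 * 3)^2)
  expect_equal(mf@fixedEffects[["k"]], 2, tolerance = 0.05)
  expect_equal(mf@fixedEffects[["T"]], 3, tolerance = 0.05)

  # true T varying across replicates: its variance is recovered to a factor 2
  set.seed(15)
  v <- 0.25
  recT <- replicate(40, {
    Ts <- rnorm(6, mean = 3, sd = sqrt(v))
    tc <- lapply(seq_along(Ts), function(i)
      makeTCI(t, elCurve(t, 0, 2, Ts[i], -0.02) + rnorm(length(t), 0, 0.01),
              well = sprintf("w%d", i)))
    fitTreatmentMixed(tc)@randomEffectVariances[["T"]]
  })
  expect_gt(mean(recT), v / 2)
  expect_lt(mean(recT), v * 2)

  expect_error(fitTreatmentMixed(tcis[1:2]), "3 replicates")
})

test_that("plate fitting isolates faults and recovers sigma-0 truth", {
  pm <- factorialPlateMap(replicates = 2)   # 48 wells keeps this fast
  sim <- simulatePlate(generatorConfig(design = pm, seed = 16, sigma = 0))
  fits <- suppressMessages(fitPlate(sim$traces, pm))
  expect_equal(nrow(fits), 48L)
  expect_true(all(fits$converged))
  m <- merge(fits, sim$truth, by = "well", suffixes = c("", ".true"))
  expect_lt(max(abs(m$k - m$k.true) / abs(m$k.true)), 1e-6)
  expect_lt(max(abs(m$T_h - m$T_h.true) / abs(m$T_h.true)), 1e-6)
  expect_lt(max(abs(m$r_per_h - m$r_per_h.true) / abs(m$r_per_h.true)), 1e-6)

  # one corrupt well (too short to fit) becomes a flagged row, not an abort
  short <- CITrace("W001", c(0, 24.25, 24.5), c(1, 1, 1))
  traces2 <- as.list(sim$traces)
  traces2[["W001"]] <- short
  fits2 <- suppressMessages(suppressWarnings(fitPlate(TraceSet(traces2), pm)))
  expect_equal(nrow(fits2), 48L)
  bad <- fits2[fits2$well == "W001", ]
  expect_false(bad$converged)
  expect_match(bad$note, "at least 8")
  expect_equal(sum(fits2$converged), 47L)
})

test_that("residuals of a correctly specified fit look Gaussian", {
  t <- seq(0.25, 30, 0.25)
  set.seed(18)
  res <- unlist(lapply(1:20, function(i) {
    x <- elCurve(t, 0, 2, 3, -0.02) + rnorm(length(t), 0, 0.05)
    f <- fitWell(makeTCI(t, x))
    p <- as.numeric(f@params)
    x - elCurve(t, p[["x0"]], p[["k"]], p[["T"]], p[["r"]])
  }))
  skew <- mean((res - mean(res))^3) / sd(res)^3
  expect_lt(abs(skew), 0.5)
})
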