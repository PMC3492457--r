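test_that("forwardCI maps kinetic parameters to the CI scale exactly", {
  t <- seq(0, 30, 0.25)
  # null dynamics: constant at the baseline
  tr <- forwardCI(t, kineticParams(x0 = 0, k = 0, T = 1, r = 0),
                  baselineCI = 1.7)
  expect_equal(traceValues(tr), rep(1.7, length(t)))

  # closed form at t = 30 for (x0=0, k=2, T=5, r=0.1)
  tr <- forwardCI(t, kineticParams(x0 = 0, k = 2, T = 5, r = 0.1),
                  baselineCI = 2)
  tci <- suppressMessages(transformCI(tr, originT = 0))
  expect_equal(traceValues(tci)[t == 30], -2 * (1 - exp(-6)) + 3,
               tolerance = 1e-12)
  # the transform of the forward trace reproduces the model curve everywhere
  expect_equal(traceValues(tci), elCurve(t, 0, 2, 5, 0.1), tolerance = 1e-12)

  # k = 0, r > 0: strictly increasing CI
  tr <- forwardCI(t, kineticParams(x0 = 0, k = 0, T = 1, r = 0.05), 1)
  expect_true(all(diff(traceValues(tr)) > 0))

  expect_error(forwardCI(t, kineticParams(), baselineCI = 0), "baselineCI")
})

test_that("the default dose-response map is monotone in C.F with the stated limits", {
  drm <- doseResponseMap()
  grid <- expand.grid(C = c(0, 0.05, 0.1, 0.5, 1, 10), F = c(0, 1, 5, 10))
  resp <- doseResponse(drm, grid$C, grid$F)
  o <- order(resp$cf)
  expect_true(all(diff(resp$k[o]) >= -1e-12))       # k non-decreasing
  expect_true(all(diff(resp$T_h[o]) <= 1e-12))      # T non-increasing
  expect_true(all(diff(resp$r_per_h[o]) <= 1e-12))  # r non-increasing
  # no light or no drug leaves only the residual transient k0
  expect_equal(resp$k[resp$cf == 0], rep(drm@k0, sum(resp$cf == 0)))
  # threshold crossings align with the C.F >= 2.5 synergy boundary
  hot <- resp$cf >= 2.5
  expect_true(all(log10(resp$T_h[hot]) < 0))
  expect_true(all(resp$r_per_h[hot] < 0))
  expect_true(all(log10(resp$T_h[!hot]) > 0))
  expect_true(all(resp$r_per_h[!hot] > 0))
})

test_that("simulatePlate is reproducible and honours the noiseless limit", {
  cfg <- generatorConfig(seed = 5)
  sim1 <- simulatePlate(cfg)
  expect_length(sim1$traces, 144L)
  # every treatment carries its ground-truth triple; the dose-response map
  # depends on the interaction only, so distinct triples = distinct C.F levels
  expect_equal(nrow(unique(sim1$truth[, c("concentration_uM", "fluence_J_cm2",
                                          "k", "T_h", "r_per_h")])), 24L)
  expect_equal(nrow(unique(sim1$truth[, c("k", "T_h", "r_per_h")])),
               length(unique(sim1$truth$cf)))

  sim2 <- simulatePlate(cfg)
  expect_identical(lapply(as.list(sim2$traces), traceValues),
                   lapply(as.list(sim1$traces), traceValues))
  expect_identical(sim1$truth, sim2$truth)

  sim3 <- simulatePlate(generatorConfig(seed = 6))
  expect_false(identical(traceValues(sim3$traces[[1]]),
                         traceValues(sim1$traces[[1]])))

  # sigma = 0: every post-irradiation segment equals the forward model
  cfg0 <- generatorConfig(seed = 5, sigma = 0)
  sim0 <- simulatePlate(cfg0)
  tr <- sim0$traces[["W144"]]
  truth <- sim0$truth[sim0$truth$well == "W144", ]
  post <- traceTimes(tr) > 24
  fw <- forwardCI(traceTimes(tr)[post] - 24,
                  kineticParams(x0 = 0, k = truth$k, T = truth$T_h,
                                r = truth$r_per_h),
                  baselineCI = truth$baseline_ci)
  expect_equal(traceValues(tr)[post], traceValues(fw), tolerance = 1e-12)
})

test_that("the generator RNG state does not leak", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulatePlate(generatorConfig(seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("washing artifact scales exactly the in-window samples", {
  tr <- CITrace("w", seq(0, 50, 0.25), rep(2, 201), clock = "exposure")
  # depth 0 is the identity
  expect_equal(traceValues(injectWashingArtifact(tr, 24, 0, 0.5)),
               traceValues(tr))
  # depth 0.3 at 24 h for 0.5 h: exactly the window samples reduced by 30%
  out <- injectWashingArtifact(tr, 24, 0.3, 0.5)
  inWin <- traceTimes(tr) >= 24 & traceTimes(tr) <= 24.5
  expect_equal(traceValues(out)[inWin], rep(1.4, sum(inWin)))
  expect_equal(traceValues(out)[!inWin], rep(2, sum(!inWin)))
  # degenerate window still hits the nearest grid point
  out <- injectWashingArtifact(tr, 24.07, 0.5, 0.01)
  expect_equal(sum(traceValues(out) != 2), 1L)
  expect_equal(traceValues(out)[traceTimes(tr) == 24], 1)
  expect_error(injectWashingArtifact(tr, 99, 0.3, 0.5), "span")
})
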