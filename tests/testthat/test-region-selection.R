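test_that("profile matrix assembly follows the window and grouping", {
  # 36 wells on an hourly grid over [25, 120] h -> 36 x 96 matrix, 6 groups
  pm <- factorialPlateMap(fluences = 10)
  t <- seq(0, 120, 1)
  set.seed(8)
  traces <- TraceSet(lapply(wells(pm), function(w)
    CITrace(w, t, rlnorm(length(t)))))
  mat <- buildProfileMatrix(traces, pm, window = c(25, 120), maxCols = 96)
  expect_equal(dim(mat@values), c(36L, 96L))
  expect_equal(nlevels(mat@groups), 6L)
  expect_equal(rownames(mat@values), sort(wells(pm)))

  # thinning to the default n - #groups bound
  thin <- buildProfileMatrix(traces, pm, window = c(25, 120))
  expect_lte(ncol(thin@values), 36L - 6L)

  # down-sample factor 4 on a 0.25 h grid gives hourly columns
  tq <- seq(25, 35, 0.25)
  tr4 <- TraceSet(lapply(wells(pm), function(w)
    CITrace(w, tq, rlnorm(length(tq)))))
  m4 <- buildProfileMatrix(tr4, pm, window = c(25, 35), maxCols = 11)
  expect_equal(m4@times, seq(25, 35, 1))

  # window outside the data span
  expect_error(buildProfileMatrix(traces, pm, window = c(200, 300)), "cover")

  # the constant normalization column is dropped with a message
  nci <- TraceSet(lapply(as.list(traces), function(x)
    suppressMessages(normalizeCI(x, 25))))
  expect_message(mc <- buildProfileMatrix(nci, pm, window = c(25, 120),
                                          maxCols = 96),
                 "constant")
  expect_false(25 %in% mc@times)
})

test_that("canonical eigenvalues match a brute-force generalized eigensolve", {
  set.seed(21)
  g <- rep(1:3, each = 4)                  # n = 12, p = 4
  means <- rbind(c(0, 0, 0, 0), c(2, 1, 0, 0), c(0, 2, 1, 0))
  X <- means[g, ] + matrix(rnorm(48, sd = 0.7), 12, 4)
  pm <- makeProfileMatrix(X, times = 1:4, groups = g)
  cr <- manovaCanonical(pm)
  lamBrute <- bruteCanonicalEigen(X, g)
  expect_equal(cr@eigenvalues[1:2], lamBrute[1:2], tolerance = 1e-10)
  expect_lt(max(abs(cr@eigenvalues[3:4])), 1e-10)
  expect_equal(cr@nAxes, 2L)
})

test_that("canonical structure honours rank and degeneracy limits", {
  set.seed(22)
  # two groups: between-scatter has rank 1, so one non-null axis
  g2 <- rep(1:2, each = 6)
  X2 <- rbind(matrix(rnorm(30), 6), matrix(rnorm(30, mean = 2), 6))
  cr2 <- manovaCanonical(makeProfileMatrix(X2, 1:5, g2))
  expect_equal(cr2@varFraction[1], 1, tolerance = 1e-9)
  expect_lt(cr2@eigenvalues[2] / cr2@eigenvalues[1], 1e-12)

  # identical group means (constructed exactly): all eigenvalues ~ 0
  g0 <- rep(1:3, each = 4)
  E <- matrix(rnorm(60), 12, 5)
  X0 <- E
  for (idx in split(seq_len(12), g0))    # remove each group's own mean
    X0[idx, ] <- sweep(E[idx, ], 2, colMeans(E[idx, ]))
  cr0 <- manovaCanonical(makeProfileMatrix(X0, 1:5, g0))
  expect_lt(max(cr0@eigenvalues), 1e-18)

  # p > n - g is refused with guidance, shrinkage makes it tractable
  set.seed(23)
  Xw <- matrix(rnorm(10 * 9), 10, 9)
  pmw <- makeProfileMatrix(Xw, 1:9, rep(1:2, each = 5))
  expect_error(manovaCanonical(pmw), "down-sample")
  expect_s4_class(manovaCanonical(pmw, shrinkage = 1e-6), "CanonicalResult")
})

test_that("canonical invariants: fractions and shift invariance", {
  set.seed(24)
  g <- rep(1:4, each = 5)
  X <- matrix(rnorm(20 * 6), 20, 6) + outer(as.numeric(g), seq(0.1, 0.6, 0.1))
  cr <- manovaCanonical(makeProfileMatrix(X, 1:6, g))
  expect_true(all(cr@varFraction >= 0))
  expect_true(all(diff(cr@varFraction) <= 1e-12))
  expect_equal(sum(cr@varFraction), 1, tolerance = 1e-12)
  # adding a constant to every profile leaves scores unchanged up to sign
  crs <- manovaCanonical(makeProfileMatrix(X + 5, 1:6, g))
  for (j in 1:3) {
    agree <- min(max(abs(crs@scores[, j] - cr@scores[, j])),
                 max(abs(crs@scores[, j] + cr@scores[, j])))
    expect_lt(agree, 1e-8)
  }
})

test_that("region picking takes the farthest instants per axis", {
  # synthetic map: axis 1 coordinate grows with time, so T2 = window end
  times <- seq(30, 120, 10)
  map <- cbind(axis1 = seq(-0.1, 0.9, length.out = 10),
               axis2 = c(-0.05, 0.8, 0.3, 0.2, 0.1, 0, -0.1, -0.2, 0, 0.1))
  cr <- new("CanonicalResult", eigenvalues = c(10, 4, rep(0, 8)),
            varFraction = c(10, 4, rep(0, 8)) / 14,
            axes = diag(10), scores = matrix(0, 2, 10),
            timeMap = map, times = times, nAxes = 2L)
  roi <- selectRegions(cr, t0 = 25)
  expect_equal(roi@t2, 120)   # axis-1 pick
  expect_equal(roi@t1, 40)    # axis-2 pick
  expect_true(roi@t1 != roi@t2)

  # tie on axis 2 resolved toward the earlier instant
  map2 <- map; map2[, "axis2"] <- c(0, 0.8, 0.1, 0.8, 0, 0, 0, 0, 0, 0)
  cr2 <- new("CanonicalResult", eigenvalues = c(10, 4, rep(0, 8)),
             varFraction = c(10, 4, rep(0, 8)) / 14, axes = diag(10),
             scores = matrix(0, 2, 10), timeMap = map2, times = times,
             nAxes = 2L)
  expect_message(roi2 <- selectRegions(cr2, t0 = 25), "tie")
  expect_equal(roi2@t1, 40)

  # degenerate map is an error
  cr0 <- new("CanonicalResult", eigenvalues = rep(0, 10),
             varFraction = rep(0, 10), axes = diag(10),
             scores = matrix(0, 2, 10), timeMap = map * 0, times = times,
             nAxes = 2L)
  expect_error(selectRegions(cr0), "degenerate")
})

test_that("regions on the synthetic concentration series are late and interior", {
  sim <- simulatePlate(regionDemoConfig(seed = 31))
  nci <- normalizeAll(sim$traces, t0 = 25)
  pm <- suppressMessages(buildProfileMatrix(nci, regionDemoConfig(seed = 31)@design,
                                            window = c(25, 120)))
  cr <- manovaCanonical(pm)
  roi <- suppressMessages(selectRegions(cr, t0 = 25))
  # separation between concentration groups keeps growing with time, so the
  # axis-1 pick sits at the late end of the study window
  expect_gte(roi@t2, 100)
  expect_true(roi@t1 != roi@t2)
  expect_true(roi@t1 >= 25 && roi@t1 <= 120)
})

test_that("one-way ANOVA matches its algebraic identities", {
  # hand-computable integer table, 3 groups x 3 values
  vals <- c(1, 2, 3, 2, 4, 6, 5, 6, 10)
  g <- rep(c("a", "b", "c"), each = 3)
  X <- cbind(vals, vals * 0 + rnorm(9))
  pm <- makeProfileMatrix(X, times = c(1, 2), groups = g)
  a <- anovaAtTime(pm, 1)
  expect_equal(a@fStatistic, handAnovaF(vals, g), tolerance = 1e-12)
  expect_equal(a@dfBetween, 2L)
  expect_equal(a@dfWithin, 6L)
  expect_equal(nrow(a@groupSummary), 3L)
  expect_true(all(c("median", "q1", "q3") %in% names(a@groupSummary)))

  # two groups: F equals the squared pooled-variance t statistic
  set.seed(9)
  v2 <- rnorm(12); g2 <- rep(1:2, each = 6)
  pm2 <- makeProfileMatrix(cbind(v2, v2), times = c(1, 2), groups = g2)
  a2 <- anovaAtTime(pm2, 2)
  tt <- t.test(v2[g2 == 1], v2[g2 == 2], var.equal = TRUE)
  expect_equal(a2@fStatistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a2@pValue, tt$p.value, tolerance = 1e-10)

  # t must hit a column; singleton groups are rejected at construction
  expect_error(anovaAtTime(pm, 7), "not a column")
  expect_error(makeProfileMatrix(cbind(v2, v2), times = c(1, 2),
                                 groups = c(rep(1, 11), 2)),
               "2 wells per group")
})
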