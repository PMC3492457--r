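# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# closed-form exponential-linear curve, written out independently of the
# package's model code so recovery tests have an external reference
elCurve <- function(t, x0, k, T, r) x0 - k * (1 - exp(-t / T)) + r * t

makeTCI <- function(t, x, well = "w1", originCI = 1, originT = 0,
                    clock = "irradiation") {
  new("TCITrace", well = well, times = t, values = x, clock = clock,
      originCI = originCI, originT = originT)
}

makeProfileMatrix <- function(X, times = seq_len(ncol(X)), groups,
                              window = range(times)) {
  dimnames(X) <- list(sprintf("W%03d", seq_len(nrow(X))), NULL)
  new("ProfileMatrix", values = X, times = as.numeric(times),
      groups = factor(groups), window = as.numeric(window))
}

# the 36-well concentration-series demo used for region selection: one
# fluence, six concentrations, six replicates, monitored long enough to
# cover the [25, 120] h study window
regionDemoConfig <- function(seed, sigma = 0.05) {
  generatorConfig(design = factorialPlateMap(fluences = 10), seed = seed,
                  sigma = sigma, postH = 96)
}

normalizeAll <- function(traces, t0 = 25) {
  TraceSet(lapply(as.list(traces), function(tr)
    suppressMessages(normalizeCI(tr, t0 = t0))))
}

# brute-force generalized eigenvalues of det(B - lambda W) = 0, computed
# from the raw scatter definitions with a plain non-symmetric eigensolve
bruteCanonicalEigen <- function(X, groups) {
  m <- colMeans(X)
  B <- matrix(0, ncol(X), ncol(X))
  W <- matrix(0, ncol(X), ncol(X))
  for (idx in split(seq_len(nrow(X)), groups)) {
    mi <- colMeans(X[idx, , drop = FALSE])
    B <- B + length(idx) * tcrossprod(mi - m)
    Xc <- sweep(X[idx, , drop = FALSE], 2, mi)
    W <- W + crossprod(Xc)
  }
  sort(Re(eigen(solve(W) %*% B)$values), decreasing = TRUE)
}

# one-way ANOVA F by explicit sums (spreadsheet-style arithmetic)
handAnovaF <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(unlist(tapply(values, groups, function(v) (v - mean(v))^2)))
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  (ssb / dfb) / (ssw / dfw)
}
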