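#' @include AllClasses.R
NULL

#' Build a well-by-time profile matrix over a study window
#'
#' Assembles one row per well from the times shared by all traces inside the
#' window, thinned uniformly to at most `maxCols` columns so the within-group
#' scatter of the canonical analysis stays invertible. Columns with (near)
#' zero variance — notably the normalization instant, where every NCI value
#' is exactly 1 — are dropped with a message.
#'
#' @param traces a [TraceSet] (typically of [NCITrace]s on a common grid).
#' @param plate a [PlateMap] supplying the grouping variable.
#' @param window study window in hours on the traces' clock.
#' @param groupBy plate-map column defining the groups (default
#'   `"concentration_uM"`).
#' @param maxCols maximum number of time columns kept; default
#'   `n wells - n groups`.
#' @return a [ProfileMatrix] with rows ordered by well id.
#' @export
buildProfileMatrix <- function(traces, plate, window = c(25, 120),
                               groupBy = "concentration_uM", maxCols = NULL) {
  stopifnot(is(traces, "TraceSet"), is(plate, "PlateMap"),
            length(window) == 2L, window[1] < window[2])
  pm <- as.data.frame(plate)
  if (!groupBy %in% names(pm))
    stop("grouping column '", groupBy, "' not in plate map")
  ids <- sort(intersect(wells(traces), pm$well))
  if (length(ids) == 0L) stop("no wells shared between traces and plate map")
  ## common grid: intersection of in-window times across wells
  grid <- NULL
  for (id in ids) {
    tr <- traces[[id]]
    tt <- tr@times[tr@times >= window[1] & tr@times <= window[2]]
    if (length(tt) < 2L)
      stop(sprintf("well %s does not cover the window [%g, %g] h",
                   id, window[1], window[2]))
    key <- round(tt, 9)
    grid <- if (is.null(grid)) key else intersect(grid, key)
  }
  if (length(grid) < 2L)
    stop("traces share fewer than 2 time points inside the window")
  grid <- sort(grid)
  X <- t(vapply(ids, function(id) {
    tr <- traces[[id]]
    tr@values[match(grid, round(tr@times, 9))]
  }, numeric(length(grid))))
  groups <- factor(pm[[groupBy]][match(ids, pm$well)])
  ## drop degenerate columns before thinning
  cv <- apply(X, 2L, var)
  if (any(cv < 1e-18)) {
    message(sum(cv < 1e-18), " constant time column(s) dropped (e.g. the normalization instant)")
    X <- X[, cv >= 1e-18, drop = FALSE]
    grid <- grid[cv >= 1e-18]
  }
  if (is.null(maxCols)) maxCols <- nrow(X) - nlevels(groups)
  if (maxCols < 2L) stop("maxCols must be at least 2")
  if (ncol(X) > maxCols) {
    keep <- unique(round(seq(1L, ncol(X), length.out = maxCols)))
    X <- X[, keep, drop = FALSE]
    grid <- grid[keep]
  }
  dimnames(X) <- list(ids, .numFmt(grid))
  new("ProfileMatrix", values = X, times = grid, groups = groups,
      window = as.numeric(window))
}

## between- and within-group scatter matrices of a profile matrix
.scatter <- function(X, groups) {
  m <- colMeans(X)
  p <- ncol(X)
  B <- matrix(0, p, p)
  W <- matrix(0, p, p)
  for (idx in split(seq_len(nrow(X)), groups)) {
    mi <- colMeans(X[idx, , drop = FALSE])
    B <- B + length(idx) * tcrossprod(mi - m)
    Xc <- sweep(X[idx, , drop = FALSE], 2L, mi)
    W <- W + crossprod(Xc)
  }
  list(B = B, W = W)
}

#' MANOVA with canonical analysis of a profile matrix
#'
#' Solves the generalized eigenproblem of the between- over within-group
#' scatter, W^-1 B, via a Cholesky whitening of W (numerically a symmetric
#' eigenproblem). Eigenvalues measure per-axis discriminative variance;
#' `varFraction` is each eigenvalue over their sum. The time map holds the
#' structure coefficients — the correlation of each time variable with each
#' canonical score — on the first two axes; each axis is oriented so the
#' earliest analyzed instant (the one closest to the normalization time) has
#' a non-positive coordinate.
#'
#' @param pm a [ProfileMatrix] with at most `n - #groups` columns.
#' @param shrinkage ridge factor; `shrinkage > 0` replaces W with
#'   `W + shrinkage * tr(W)/p * I` to stabilize a near-singular within
#'   scatter (default 0, no shrinkage).
#' @return a [CanonicalResult].
#' @export
manovaCanonical <- function(pm, shrinkage = 0) {
  stopifnot(is(pm, "ProfileMatrix"), shrinkage >= 0)
  X <- pm@values
  groups <- droplevels(pm@groups)
  n <- nrow(X); p <- ncol(X); g <- nlevels(groups)
  if (shrinkage == 0 && p > n - g)
    stop(sprintf(paste0("%d time columns exceed n - #groups = %d; down-sample ",
                        "the grid (maxCols) or set shrinkage > 0"), p, n - g))
  sc <- .scatter(X, groups)
  W <- sc$W
  if (shrinkage > 0)
    W <- W + diag(shrinkage * sum(diag(W)) / p, p)
  L <- tryCatch(chol(W), error = function(e)
    stop("within-group scatter is singular; down-sample the time grid ",
         "(maxCols) or set shrinkage > 0"))
  ## whitened between scatter: L^-T B L^-1, symmetric
  M <- backsolve(L, t(backsolve(L, t(sc$B), transpose = TRUE)),
                 transpose = TRUE)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  A <- backsolve(L, e$vectors)
  scores <- sweep(X, 2L, colMeans(X)) %*% A
  nAxes <- min(g - 1L, p)
  frac <- if (sum(lam) > 0) lam / sum(lam) else rep(0, length(lam))
  map <- suppressWarnings(cor(X, scores[, 1:2, drop = FALSE]))
  map[!is.finite(map)] <- 0
  ## orientation: earliest instant's coordinate <= 0 on each of the first
  ## two axes; if it is 0, make the largest-magnitude coordinate positive
  for (j in 1:2) {
    refc <- map[1L, j]
    flip <- if (refc != 0) refc > 0 else map[which.max(abs(map[, j])), j] < 0
    if (flip) {
      map[, j] <- -map[, j]
      A[, j] <- -A[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(map) <- c("axis1", "axis2")
  rownames(map) <- colnames(X)
  new("CanonicalResult", eigenvalues = lam, varFraction = frac,
      axes = A, scores = scores, timeMap = map, times = pm@times,
      nAxes = as.integer(nAxes))
}

#' Pick the regions of interest from a canonical map
#'
#' For each of the first two canonical axes, selects the time instant whose
#' map coordinate lies farthest from the reference coordinate of the
#' normalization time `t0` (0 when `t0`'s column was dropped as constant).
#' The axis-1 pick is the T2 candidate, the axis-2 pick the T1 candidate.
#' Ties go to the earlier instant; if both axes pick the same instant the
#' axis-2 pick moves to its next-farthest instant so T1 != T2. With fewer
#' than two positive eigenvalues both picks fall back to axis 1.
#'
#' @param cr a [CanonicalResult].
#' @param t0 normalization time, hours.
#' @return a [RegionsOfInterest].
#' @export
selectRegions <- function(cr, t0 = 25) {
  stopifnot(is(cr, "CanonicalResult"))
  map <- cr@timeMap
  if (all(abs(map) < 1e-12))
    stop("degenerate canonical map: all time coordinates are equal")
  refCoord <- function(j) {
    i <- which(abs(cr@times - t0) < 1e-9)
    if (length(i)) map[i[1L], j] else 0
  }
  pick <- function(j, exclude = numeric()) {
    d <- abs(map[, j] - refCoord(j))
    d[cr@times %in% exclude] <- -Inf
    i <- which(d == max(d))
    if (length(i) > 1L)
      message(sprintf("axis %d: tie between %s h, earlier instant chosen",
                      j, paste(cr@times[i], collapse = ", ")))
    i <- i[1L]
    list(time = cr@times[i], distance = d[i])
  }
  posLam <- sum(cr@eigenvalues > 1e-10 * max(cr@eigenvalues, 1e-300))
  if (posLam >= 2L) {
    p2 <- pick(1L)           # axis 1 -> T2
    p1 <- pick(2L, exclude = p2$time)  # axis 2 -> T1
    prov <- data.frame(axis = c(2L, 1L), region = c("T1", "T2"),
                       time_h = c(p1$time, p2$time),
                       map_distance = c(p1$distance, p2$distance))
  } else {
    message("fewer than 2 positive eigenvalues; both picks taken from axis 1")
    p2 <- pick(1L)
    p1 <- pick(1L, exclude = p2$time)
    prov <- data.frame(axis = c(1L, 1L), region = c("T1", "T2"),
                       time_h = c(p1$time, p2$time),
                       map_distance = c(p1$distance, p2$distance))
  }
  new("RegionsOfInterest", t1 = p1$time, t2 = p2$time, provenance = prov)
}

#' One-way ANOVA of the profile values at one time instant
#'
#' Classical fixed-effects one-way F test of the group effect on the profile
#' values at time `t` (a column of the matrix; `t` is snapped to the nearest
#' column within half a grid step). Per-group medians and quartiles are
#' returned for boxplot-style summaries. No multiple-testing correction is
#' applied across instants.
#'
#' @param pm a [ProfileMatrix].
#' @param t time instant, hours.
#' @return an [AnovaResult].
#' @export
anovaAtTime <- function(pm, t) {
  stopifnot(is(pm, "ProfileMatrix"))
  d <- abs(pm@times - t)
  i <- which.min(d)
  step <- median(diff(pm@times))
  if (d[i] > step / 2 + 1e-9)
    stop(sprintf("t = %g h is not a column of the profile matrix", t))
  groups <- droplevels(pm@groups)
  if (min(table(groups)) < 2L)
    stop("every group needs at least 2 observations")
  v <- pm@values[, i]
  a <- anova(lm(v ~ groups))
  gs <- do.call(rbind, lapply(split(v, groups), function(x)
    data.frame(n = length(x), median = median(x),
               q1 = unname(quantile(x, 0.25)), q3 = unname(quantile(x, 0.75)))))
  gs <- data.frame(group = rownames(gs), gs, row.names = NULL)
  new("AnovaResult", fStatistic = a[["F value"]][1L],
      dfBetween = as.integer(a[["Df"]][1L]),
      dfWithin = as.integer(a[["Df"]][2L]),
      pValue = a[["Pr(>F)"]][1L], groupSummary = gs, time = pm@times[i])
}
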