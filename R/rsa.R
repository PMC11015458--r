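#' Representational dissimilarity matrix over 16 color bins
#'
#' Trials are binned in the first color space (offset 0). Per repetition the
#' bin counts are equalized by random subsampling, bin-average patterns are
#' formed, and all pairwise Mahalanobis distances are computed with a
#' shrinkage covariance estimated from the condition-demeaned trials; the
#' final RDM is the average over repetitions.
#'
#' @param patterns trials x dims matrix from [windowPool()].
#' @param colors color per trial (degrees).
#' @param centers bin centers (default the first color space).
#' @param nReps subsampling repetitions.
#' @param seed integer seed.
#' @return a [ColorRDM-class].
#' @export
computeRDM <- function(patterns, colors, centers = colorSpace(0),
                       nReps = 100, seed = 1L) {
  X <- as.matrix(patterns)
  bins0 <- as.integer(assignBins(colors, centers))
  cnt <- tabulate(bins0 + 1L, nbins = 16L)
  if (any(cnt < 2L)) {
    b <- which.min(cnt) - 1L
    stop(sprintf(
      "bin %d (center %g deg) has only %d trial(s); at least 2 are required",
      b, centers[b + 1L], cnt[b + 1L]), call. = FALSE)
  }
  # covariance does not depend on the subsample: estimate once
  binMeans <- rowsum(X, bins0) / cnt
  resid <- X - binMeans[bins0 + 1L, , drop = FALSE]
  if (max(abs(resid)) == 0 && max(abs(sweep(binMeans, 2, binMeans[1, ]))) == 0) {
    # all trials share one pattern: every pairwise distance is zero
    return(new("ColorRDM", values = matrix(0, 16, 16), centers = centers,
               nReps = as.integer(nReps)))
  }
  Sigma <- shrinkageCovariance(resid)
  L <- t(chol(Sigma))
  byBin <- split(seq_len(nrow(X)), factor(bins0, levels = 0:15))
  m <- min(cnt)
  repSeeds <- .subSeeds(seed, nReps)
  acc <- matrix(0, 16, 16)
  for (r in seq_len(nReps)) {
    keep <- .withSeed(repSeeds[r],
      lapply(byBin, function(ix) ix[sample.int(length(ix), m)]))
    M <- t(vapply(keep, function(ix)
      colMeans(X[ix, , drop = FALSE]), numeric(ncol(X))))
    Mw <- t(forwardsolve(L, t(M)))                  # whitened bin means
    acc <- acc + as.matrix(stats::dist(Mw))
  }
  vals <- acc / nReps
  vals <- (vals + t(vals)) / 2
  diag(vals) <- 0
  new("ColorRDM", values = unname(vals), centers = centers,
      nReps = as.integer(nReps))
}

# z-score the off-diagonal entries, zero the diagonal
.zscoreOffdiag <- function(m) {
  off <- row(m) != col(m)
  v <- m[off]
  if (stats::sd(v) == 0) stop("model is constant off the diagonal", call. = FALSE)
  m[off] <- (v - mean(v)) / stats::sd(v)
  diag(m) <- 0
  m
}

#' Uniform circular color-space model RDM
#'
#' Dissimilarity between bins i and j is their absolute circular angular
#' distance in degrees (0..180), z-scored over the off-diagonal entries.
#'
#' @param centers 16 bin center angles.
#' @return 16 x 16 matrix with attribute `name = "uniform"`.
#' @export
modelUniform <- function(centers = colorSpace(0)) {
  stopifnot(length(centers) == 16L)
  m <- abs(outer(centers, centers, circDiffDeg))
  structure(.zscoreOffdiag(m), name = "uniform")
}

#' Primary-color (categorical) model RDM
#'
#' Each bin is assigned to the circularly nearest of the three primary hues;
#' dissimilarity is 0 for bins in the same category and 1 otherwise,
#' z-scored over the off-diagonal entries.
#'
#' @param centers 16 bin center angles.
#' @param primaries exactly 3 primary hue angles (degrees).
#' @return 16 x 16 matrix with attribute `name = "primary"`.
#' @export
modelPrimary <- function(centers = colorSpace(0),
                         primaries = c(30, 150, 270)) {
  if (length(primaries) != 3L)
    stop("primaries must contain exactly 3 angles", call. = FALSE)
  stopifnot(length(centers) == 16L)
  cat16 <- vapply(centers, function(th)
    which.min(abs(circDiffDeg(primaries, th))), integer(1))
  m <- 1 * outer(cat16, cat16, "!=")
  structure(.zscoreOffdiag(m), name = "primary")
}

#' Regress one participant's RDM on model RDMs
#'
#' The strictly-lower-triangle entries (120 pairs; the diagonal is excluded)
#' of the data and of each model are vectorized and the data are regressed
#' on each model separately with an intercept. Both sides are z-scored, so
#' the returned beta is the standardized slope.
#'
#' @param rdm a [ColorRDM-class] or a 16 x 16 matrix.
#' @param models list of model matrices (see [modelUniform()],
#'   [modelPrimary()]); names are taken from their `name` attributes.
#' @return named numeric vector of standardized slopes.
#' @export
fitModels <- function(rdm, models = list(modelUniform(), modelPrimary())) {
  v <- if (is(rdm, "ColorRDM")) rdmValues(rdm) else as.matrix(rdm)
  lt <- lower.tri(v)
  y <- v[lt]
  if (stats::sd(y) == 0)
    stop("degenerate fit: RDM is constant off the diagonal", call. = FALSE)
  y <- (y - mean(y)) / stats::sd(y)
  betas <- vapply(models, function(m) {
    x <- m[lt]
    x <- (x - mean(x)) / stats::sd(x)
    unname(stats::coef(stats::lm(y ~ x))[2])
  }, numeric(1))
  names(betas) <- vapply(seq_along(models), function(i) {
    nm <- attr(models[[i]], "name")
    if (is.null(nm)) paste0("model", i) else nm
  }, character(1))
  betas
}

#' Group-level RSA model fit
#'
#' Fits each participant's RDM to each model and tests the group-mean beta
#' against zero with a sign-flip permutation test.
#'
#' @param rdms list of per-participant [ColorRDM-class] objects.
#' @param models list of model matrices.
#' @param tail,nPerm,seed passed to [signflipTest()].
#' @return list with `betas` (participants x models matrix), `groupMean`,
#'   and `p` (named per model).
#' @export
fitModelsGroup <- function(rdms, models = list(modelUniform(), modelPrimary()),
                           tail = "one_greater", nPerm = 100000, seed = 1L) {
  res <- vapply(rdms, fitModels, numeric(length(models)), models = models)
  betas <- if (length(models) == 1L)
    matrix(res, ncol = 1, dimnames = list(NULL, names(fitModels(rdms[[1]], models))))
  else t(res)
  p <- apply(betas, 2, function(b)
    signflipTest(b, tail = tail, nPerm = nPerm, seed = seed)$p)
  list(betas = betas, groupMean = colMeans(betas), p = p)
}

#' Estimate primary hues from behavioral reports
#'
#' Circular k-means (k = 3) on reported colors: cluster means are resultant
#' directions, assignment is by smallest circular distance. Used to derive
#' the primary-color model from behavior rather than assuming hue angles.
#'
#' @param reports reported colors in degrees.
#' @param k number of modes.
#' @param nStart random restarts.
#' @param seed integer seed.
#' @return sorted cluster mean angles (degrees).
#' @export
estimatePrimaries <- function(reports, k = 3, nStart = 10, seed = 1L) {
  th <- .deg2rad(reports)
  best <- NULL; bestCost <- Inf
  startSeeds <- .subSeeds(seed, nStart)
  for (s in seq_len(nStart)) {
    centers <- .withSeed(startSeeds[s], sort(stats::runif(k, 0, 2 * pi)))
    for (it in 1:50) {
      d <- abs(outer(th, centers, function(a, b) atan2(sin(a - b), cos(a - b))))
      cl <- max.col(-d)
      newc <- vapply(seq_len(k), function(j) {
        if (!any(cl == j)) return(centers[j])
        atan2(mean(sin(th[cl == j])), mean(cos(th[cl == j])))
      }, numeric(1))
      if (max(abs(atan2(sin(newc - centers), cos(newc - centers)))) < 1e-8) {
        centers <- newc; break
      }
      centers <- newc
    }
    cost <- sum(d[cbind(seq_along(th), cl)]^2)
    if (cost < bestCost) { bestCost <- cost; best <- centers }
  }
  sort(wrapDeg(best * 180 / pi))
}
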