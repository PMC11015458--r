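#' @useDynLib impulseWM, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.CENTERS0 <- seq(0, 337.5, by = 22.5)

#' The 16 bin centers of a rotated color space
#'
#' Three rotations of a 16-bin partition of the color wheel are used so that
#' every wheel color ends up near a bin center in at least one space:
#' offsets 0, 7.5 and 15 degrees, centers 22.5 degrees apart.
#'
#' @param offsetDeg rotation offset, one of 0, 7.5, 15 (any offset accepted).
#' @return 16 sorted center angles in degrees.
#' @export
#' @examples
#' colorSpace(7.5)
colorSpace <- function(offsetDeg = 0) {
  seq(offsetDeg, by = 22.5, length.out = 16)
}

#' All three rotated color spaces
#' @return list of three 16-vectors of bin centers (offsets 0, 7.5, 15).
#' @export
colorSpaces <- function() {
  lapply(c(0, 7.5, 15), colorSpace)
}

#' Assign colors to the circularly nearest bin center
#'
#' Ties are broken toward the lower bin index.
#'
#' @param colors angles in degrees, in `[0, 360)`.
#' @param centers 16 bin centers from [colorSpace()].
#' @return integer bin indices in `0..15`, with attribute `centers`.
#' @export
#' @examples
#' assignBins(c(10, 350, 11.25), colorSpace(0))  # 0 0 0
assignBins <- function(colors, centers = colorSpace(0)) {
  idx <- vapply(colors, function(th)
    which.min(abs(circDiffDeg(th, centers))) - 1L, integer(1))
  structure(idx, centers = centers)
}

#' Half-cosine basis smoothing weights
#'
#' `weight(i, j) = cos(delta_ij / 2)^power`, with `delta_ij` the circular
#' difference between bin centers i and j; rows are normalized to sum to 1.
#' Multiplying this matrix by the 16 x dims matrix of condition means pools
#' information across neighboring color bins. As `power` grows the weights
#' approach the identity; `power = 0` gives uniform pooling.
#'
#' @param power non-negative exponent (the analysis default is 15).
#' @param normalize divide each row by its sum (the default); with
#'   `normalize = FALSE` the raw weights are returned, which are exactly 1
#'   at zero angular difference and 0 at 180 degrees.
#' @return 16 x 16 weight matrix (row-stochastic when normalized).
#' @export
halfCosineBasis <- function(power = 15, normalize = TRUE) {
  if (length(power) != 1L || is.na(power) || power < 0)
    stop("power must be a single non-negative number", call. = FALSE)
  deltaDeg <- outer(.CENTERS0, .CENTERS0, circDiffDeg)
  W <- cospi(deltaDeg / 360)^power      # cospi: exactly 0 at 180 degrees
  if (normalize) W / rowSums(W) else W
}

#' Ledoit-Wolf shrinkage covariance estimate
#'
#' Optimal-shrinkage convex combination of the sample covariance of the
#' (centered) residuals with a scaled-identity target, yielding a
#' well-conditioned symmetric positive-definite estimate even when the
#' number of observations is small relative to the dimensionality.
#'
#' @param residuals observations x dims matrix, typically training trials
#'   after subtracting their condition mean.
#' @return dims x dims covariance matrix.
#' @export
shrinkageCovariance <- function(residuals) {
  X <- as.matrix(residuals)
  n <- nrow(X); d <- ncol(X)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / d
  if (mu <= 0)
    stop("singular covariance: residuals have no variance", call. = FALSE)
  frob2 <- sum(S^2)
  d2 <- frob2 - 2 * mu * sum(diag(S)) + d * mu^2
  if (d2 <= 0) return(S)
  rs <- rowSums(Xc^2)
  b2bar <- sum(rs^2) / n^2 - frob2 / n
  shrink <- min(max(b2bar, 0), d2) / d2
  out <- (1 - shrink) * S
  diag(out) <- diag(out) + shrink * mu
  out
}

#' Mahalanobis distances of a pattern to a set of class means
#'
#' `d_k = sqrt((x - m_k)' Sigma^-1 (x - m_k))`, computed via a Cholesky
#' factorization (no explicit inverse). A non-positive-definite covariance
#' raises the factorization error rather than being silently regularized.
#'
#' @param x numeric pattern of length `d`.
#' @param means classes x d matrix of class means.
#' @param cov d x d symmetric positive-definite covariance.
#' @return numeric vector of one distance per class.
#' @export
#' @examples
#' mahalanobisDist(c(3, 4), rbind(c(0, 0)), diag(2))  # 5
mahalanobisDist <- function(x, means, cov) {
  means <- as.matrix(means)
  L <- t(chol(cov))                                   # lower triangular
  diff <- t(means) - x                                # d x k
  w <- forwardsolve(L, diff)
  sqrt(colSums(w^2))
}

#' Cosine-convolution decoding score of a 16-bin distance profile
#'
#' Distances are mean-centered and sign-reversed so that positive values
#' indicate similarity; the accuracy is the mean of these values weighted by
#' the cosine of the angular distance of each bin from the true bin. The
#' tuning curve is the same profile reordered by signed angular difference
#' from the true bin (-180 to +157.5 degrees).
#'
#' @param distances 16 finite Mahalanobis distances (bin order of `centers`).
#' @param trueBin 0-based index of the trial's true color bin.
#' @param centers the 16 bin centers (degrees).
#' @return list with `accuracy` (scalar, chance 0) and `tuning` (named
#'   16-vector summing to 0).
#' @export
cosineScore <- function(distances, trueBin, centers = colorSpace(0)) {
  stopifnot(length(distances) == 16L, all(is.finite(distances)))
  s <- -(distances - mean(distances))
  delta <- circDiffDeg(centers, centers[trueBin + 1L])
  accuracy <- mean(s * cos(.deg2rad(delta)))
  pos <- ((seq_len(16L) - 1L - trueBin) %% 16L + 8L) %% 16L + 1L
  tuning <- numeric(16)
  tuning[pos] <- s
  names(tuning) <- seq(-180, 157.5, by = 22.5)
  list(accuracy = accuracy, tuning = tuning)
}

# cosMat(b, k) = cos(angular difference between centers k and b); identical
# for all three rotated spaces since only index offsets matter
.cosMat <- function() {
  cos(.deg2rad(outer(.CENTERS0, .CENTERS0, function(a, b) circDiffDeg(b, a))))
}

# fold assignment: random partition, or stratified so each bin is spread
# approximately evenly over folds
.foldPlan <- function(bins0, nFolds, stratified = FALSE) {
  n <- length(bins0)
  foldOf <- integer(n)
  if (!stratified) {
    foldOf[sample.int(n)] <- rep_len(seq_len(nFolds), n)
  } else {
    for (b in 0:15) {
      idx <- which(bins0 == b)
      idx <- idx[sample.int(length(idx))]
      foldOf[idx] <- rep_len(sample.int(nFolds), length(idx))
    }
  }
  foldOf
}

# per-fold training subsample equalizing bin counts to the minimum
.subsamplePlan <- function(bins0, foldOf, nFolds, centers) {
  lapply(seq_len(nFolds), function(f) {
    train <- which(foldOf != f)
    byBin <- split(train, factor(bins0[train], levels = 0:15))
    m <- min(lengths(byBin))
    if (m < 1L) {
      b <- which(lengths(byBin) == 0)[1] - 1L
      stop(sprintf(
        "no training trials in bin %d (center %g deg) for fold %d; more trials per bin are needed",
        b, centers[b + 1L], f), call. = FALSE)
    }
    keep <- unlist(lapply(byBin, function(ix) ix[sample.int(length(ix), m)]),
                   use.names = FALSE)
    as.integer(keep - 1L)                           # 0-based for the C++ core
  })
}

.checkBinCounts <- function(bins0, nFolds, centers) {
  cnt <- tabulate(bins0 + 1L, nbins = 16L)
  if (any(cnt < nFolds)) {
    b <- which.min(cnt) - 1L
    stop(sprintf(
      "bin %d (center %g deg) has only %d trial(s); at least nFolds = %d are required",
      b, centers[b + 1L], cnt[b + 1L], nFolds), call. = FALSE)
  }
}

# shared engine: X is trials x dims x timepoints
.decodeEngine <- function(X, colors, nFolds, nReps, seed, stratified,
                          basisPower = 15) {
  n <- dim(X)[1]; nT <- dim(X)[3]
  basis <- halfCosineBasis(basisPower)
  cosMat <- .cosMat()
  accSum <- matrix(0, n, nT)
  tunSum <- matrix(0, 16, nT)
  spaces <- colorSpaces()
  spaceSeeds <- .subSeeds(seed, length(spaces))
  for (s in seq_along(spaces)) {
    centers <- spaces[[s]]
    bins0 <- as.integer(assignBins(colors, centers))
    .checkBinCounts(bins0, nFolds, centers)
    repSeeds <- .subSeeds(spaceSeeds[s], nReps)
    for (r in seq_len(nReps)) {
      plan <- .withSeed(repSeeds[r], {
        foldOf <- .foldPlan(bins0, nFolds, stratified)
        list(foldOf = foldOf,
             keep = .subsamplePlan(bins0, foldOf, nFolds, centers))
      })
      res <- cppScoreRep(X, bins0, plan$foldOf, plan$keep, basis, cosMat)
      accSum <- accSum + res$acc
      tunSum <- tunSum + res$tun
    }
  }
  nAvg <- length(spaces) * nReps
  list(trialAcc = accSum / nAvg, tuning = tunSum / (nAvg * n))
}

#' Cross-validated Mahalanobis color decoding of a time window of interest
#'
#' For each of the three rotated color spaces and each repetition, trials are
#' partitioned into `nFolds` random folds. Within each training set the
#' number of trials per color bin is equalized by random subsampling, bin
#' averages are smoothed with the half-cosine basis (power 15), and a
#' shrinkage covariance is estimated from the condition-demeaned training
#' trials. Each held-out trial is scored by the cosine-weighted,
#' mean-centered, sign-reversed Mahalanobis distance profile; results are
#' averaged over folds, repetitions, color spaces and trials.
#'
#' @param patterns trials x dims matrix from [windowPool()].
#' @param colors the decoded color per trial (degrees).
#' @param nFolds number of cross-validation folds.
#' @param nReps number of random fold/subsampling repetitions.
#' @param seed integer seed; repetitions use an internally derived stream so
#'   they are independent but reproducible.
#' @param stratified use bin-stratified fold assignment.
#' @param label free-text label of what is decoded (metadata only).
#' @return a [DecodingResult-class].
#' @export
decodeWindow <- function(patterns, colors, nFolds = 8, nReps = 100,
                         seed = 1L, stratified = FALSE, label = "color") {
  patterns <- as.matrix(patterns)
  stopifnot(nrow(patterns) == length(colors))
  X <- array(patterns, c(dim(patterns), 1L))
  eng <- .decodeEngine(X, colors, nFolds, nReps, seed, stratified)
  tuning <- eng$tuning[, 1]
  names(tuning) <- seq(-180, 157.5, by = 22.5)
  new("DecodingResult", accuracy = mean(eng$trialAcc[, 1]),
      trialAccuracy = eng$trialAcc[, 1], tuningCurve = tuning,
      label = label, nReps = as.integer(nReps), nFolds = as.integer(nFolds))
}

#' Time-resolved Mahalanobis color decoding with a sliding window
#'
#' Applies the [decodeWindow()] machinery independently at every time point
#' of the sliding spatio-temporal patterns (see [slidingPatterns()]), with
#' bin-stratified fold assignment. Fold and subsampling draws are shared
#' across time points within a repetition.
#'
#' @param epochs an [EpochSet-class] (voltage, or an alpha envelope from
#'   [alphaEnvelope()]).
#' @param colors the decoded color per trial (degrees).
#' @param widthMs sliding window width in ms.
#' @param fsOut output sampling rate in Hz (100 for voltage, 125 for alpha
#'   in the reference analysis).
#' @inheritParams decodeWindow
#' @return a [TimecourseResult-class].
#' @export
decodeTimecourse <- function(epochs, colors, widthMs = 100, fsOut = 100,
                             nFolds = 8, nReps = 100, seed = 1L,
                             stratified = TRUE, label = "color") {
  X <- slidingPatterns(epochs, widthMs, fsOut)
  tms <- attr(X, "timesMs")
  eng <- .decodeEngine(X, colors, nFolds, nReps, seed, stratified)
  new("TimecourseResult", accuracy = colMeans(eng$trialAcc),
      similarity = eng$tuning, timesMs = tms, label = label)
}

# plain-R reference scorer mirroring cppScoreRep on a matrix of patterns;
# used to cross-check the compiled core against the exported building blocks
.scoreRepR <- function(X, bins0, foldOf, keep, basisPower = 15) {
  n <- nrow(X)
  basis <- halfCosineBasis(basisPower)
  acc <- numeric(n)
  tun <- numeric(16)
  for (f in seq_along(keep)) {
    test <- which(foldOf == f)
    train <- which(foldOf != f)
    if (!length(test)) next
    binMeans <- rowsum(X[train, , drop = FALSE], bins0[train]) /
      as.vector(table(factor(bins0[train], levels = sort(unique(bins0[train])))))
    rowsOf <- match(bins0[train], sort(unique(bins0[train])))
    resid <- X[train, , drop = FALSE] - binMeans[rowsOf, , drop = FALSE]
    Sigma <- shrinkageCovariance(resid)
    kp <- keep[[f]] + 1L
    Msub <- rowsum(X[kp, , drop = FALSE], bins0[kp])
    Msub <- Msub / as.vector(table(factor(bins0[kp], levels = 0:15)))
    Msm <- basis %*% Msub
    for (j in test) {
      d <- mahalanobisDist(X[j, ], Msm, Sigma)
      sc <- cosineScore(d, bins0[j])
      acc[j] <- acc[j] + sc$accuracy
      tun <- tun + sc$tuning
    }
  }
  list(acc = acc, tun = tun)
}
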