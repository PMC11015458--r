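#' Group-level sign-flip permutation test
#'
#' Tests the group mean of per-participant statistics against zero by
#' randomly negating each participant's value with probability 0.5. When the
#' number of distinct flip patterns `2^n` does not exceed `nPerm` the test
#' enumerates all patterns exactly (the identity pattern included, so the
#' smallest attainable p is `1 / 2^n`); otherwise a Monte-Carlo null is drawn
#' and p carries the usual `+1` correction so it can never be zero.
#'
#' @param values per-participant statistics (length >= 2).
#' @param tail `"one_greater"` (mean > 0) or `"two"`.
#' @param nPerm number of permutations.
#' @param seed integer seed (Monte-Carlo mode).
#' @return list with `observed`, `p`, `tail`, `nPerm`, `exhaustive`, `seed`.
#' @export
#' @examples
#' signflipTest(c(1, 1, 1), tail = "one_greater")$p  # exactly 1/8
signflipTest <- function(values, tail = c("one_greater", "two"),
                         nPerm = 100000, seed = 1L) {
  tail <- match.arg(tail)
  n <- length(values)
  if (n < 2L) stop("need at least 2 participants", call. = FALSE)
  obs <- mean(values)
  eps <- 1e-12 * max(1, max(abs(values)))
  exhaustive <- (2^n <= nPerm)
  if (exhaustive) {
    nullMeans <- .allFlipMeans(values)
    pG <- sum(nullMeans >= obs - eps) / length(nullMeans)
    pL <- sum(nullMeans <= obs + eps) / length(nullMeans)
  } else {
    nullMeans <- .withSeed(seed, {
      signs <- matrix(sample(c(-1, 1), n * nPerm, replace = TRUE), n)
      as.vector(crossprod(values, signs)) / n
    })
    pG <- (1 + sum(nullMeans >= obs - eps)) / (nPerm + 1)
    pL <- (1 + sum(nullMeans <= obs + eps)) / (nPerm + 1)
  }
  p <- switch(tail, one_greater = pG, two = min(1, 2 * min(pG, pL)))
  list(observed = obs, p = p, tail = tail, nPerm = nPerm,
       exhaustive = exhaustive, seed = seed)
}

# means over all 2^n sign patterns
.allFlipMeans <- function(values) {
  n <- length(values)
  signs <- matrix(1, n, 2^n)
  for (i in seq_len(n))
    signs[i, ] <- rep(c(1, -1), each = 2^(i - 1), length.out = 2^n)
  as.vector(crossprod(values, signs)) / n
}

#' Paired condition-difference permutation test
#'
#' Computes each participant's difference `a - b` and applies
#' [signflipTest()] to it.
#'
#' @param a,b aligned per-participant statistics.
#' @inheritParams signflipTest
#' @return as [signflipTest()].
#' @export
pairedDifferenceTest <- function(a, b, tail = c("one_greater", "two"),
                                 nPerm = 100000, seed = 1L) {
  if (length(a) != length(b))
    stop("a and b must have the same length (aligned participants)",
         call. = FALSE)
  signflipTest(a - b, tail = tail, nPerm = nPerm, seed = seed)
}

#' Bootstrap percentile confidence interval for the mean
#'
#' @param values per-participant statistics (length >= 2).
#' @param level confidence level.
#' @param nBoot bootstrap resamples.
#' @param seed integer seed.
#' @return numeric length-2 interval.
#' @export
bootstrapCI <- function(values, level = 0.95, nBoot = 100000, seed = 1L) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  means <- .withSeed(seed,
    colMeans(matrix(sample(values, n * nBoot, replace = TRUE), n)))
  unname(stats::quantile(means, c((1 - level) / 2, (1 + level) / 2)))
}

# contiguous supra-threshold runs; for two-tailed inference runs must share
# the sign of the group-mean statistic; optionally wraps across the ends
.findClusters <- function(sig, statSign, circular = FALSE) {
  n <- length(sig)
  if (!any(sig)) return(list())
  lab <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!sig[i]) next
    if (i > 1L && sig[i - 1L] && statSign[i] == statSign[i - 1L])
      lab[i] <- cur
    else { cur <- cur + 1L; lab[i] <- cur }
  }
  if (circular && sig[1L] && sig[n] && lab[1L] != lab[n] &&
      statSign[1L] == statSign[n])
    lab[lab == lab[n]] <- lab[1L]
  out <- split(seq_len(n), lab[seq_len(n)])
  out[names(out) != "0"]
}

#' Cluster-corrected sign-flip permutation test over an ordered axis
#'
#' Pointwise sign-flip p values are computed at every point of the series
#' (time, or angular difference); contiguous runs with `p < alphaForm` form
#' clusters whose mass is the sum of the group-mean statistic over the run.
#' The same flip pattern is applied to all points within a permutation, and
#' the null distribution of the maximum cluster mass across the axis yields
#' the corrected p value of each observed cluster.
#'
#' @param series participants x points matrix of per-participant statistics.
#' @param alphaForm cluster-forming threshold on the pointwise p value.
#' @param nPerm number of sign-flip permutations.
#' @param tail `"one_greater"` or `"two"`; two-tailed clusters are formed
#'   from same-sign runs and tested on absolute mass.
#' @param seed integer seed.
#' @param circular treat the axis as circular (clusters may wrap).
#' @return list with `clusters` (data.frame: `start`, `end`, `mass`, `p`),
#'   `members` (list of index vectors), `pointwiseP`, `mean`, `alphaForm`,
#'   `tail`, `nPerm`.
#' @export
clusterCorrect <- function(series, alphaForm = 0.05, nPerm = 1000,
                           tail = c("one_greater", "two"), seed = 1L,
                           circular = FALSE) {
  tail <- match.arg(tail)
  stopifnot(is.matrix(series), nrow(series) >= 2L)
  n <- nrow(series)
  nT <- ncol(series)
  m <- colMeans(series)
  eps <- 1e-12 * max(1, max(abs(series)))

  M <- .withSeed(seed, {
    signs <- matrix(sample(c(-1, 1), n * nPerm, replace = TRUE), n)
    crossprod(signs, series) / n                  # nPerm x nT null means
  })

  cntG <- colSums(M >= rep(m - eps, each = nPerm))
  cntL <- colSums(M <= rep(m + eps, each = nPerm))
  pG <- (1 + cntG) / (nPerm + 1)
  pL <- (1 + cntL) / (nPerm + 1)
  pointP <- if (tail == "one_greater") pG else pmin(1, 2 * pmin(pG, pL))

  # pointwise null p values from within-column ranks (ties handled exactly)
  nullPG <- (nPerm - apply(M, 2, rank, ties.method = "min") + 1) / nPerm
  nullP <- if (tail == "one_greater") nullPG else {
    nullPL <- apply(M, 2, rank, ties.method = "max") / nPerm
    two <- 2 * pmin(nullPG, nullPL)    # pmin(1, .) would drop the dim
    two[two > 1] <- 1
    two
  }

  massOf <- function(vals, idx) sum(vals[idx])
  obsClusters <- .findClusters(pointP < alphaForm,
                               ifelse(m >= 0, 1L, -1L), circular)

  nullMax <- numeric(nPerm)
  for (i in seq_len(nPerm)) {
    ci <- .findClusters(nullP[i, ] < alphaForm,
                        ifelse(M[i, ] >= 0, 1L, -1L), circular)
    nullMax[i] <- if (length(ci))
      max(vapply(ci, function(ix) abs(massOf(M[i, ], ix)), numeric(1))) else 0
  }

  if (length(obsClusters)) {
    mass <- vapply(obsClusters, function(ix) massOf(m, ix), numeric(1))
    pCl <- vapply(mass, function(ms)
      (1 + sum(nullMax >= abs(ms) - eps)) / (nPerm + 1), numeric(1))
    clusters <- data.frame(
      start = vapply(obsClusters, min, integer(1)),
      end = vapply(obsClusters, max, integer(1)),
      mass = mass, p = pCl)
    ord <- order(clusters$start)
    clusters <- clusters[ord, , drop = FALSE]
    obsClusters <- obsClusters[ord]
    rownames(clusters) <- NULL
  } else {
    clusters <- data.frame(start = integer(), end = integer(),
                           mass = numeric(), p = numeric())
  }
  list(clusters = clusters, members = obsClusters, pointwiseP = pointP,
       mean = m, alphaForm = alphaForm, tail = tail, nPerm = nPerm)
}
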