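#' Adjusted report error
#'
#' Signed circular difference between the reported color and the center of
#' the color bin containing the cued item, wrapped to `(-180, 180]`.
#' Positive values are counterclockwise of the bin center.
#'
#' @param report reported colors in degrees.
#' @param cuedBinCenter center of the cued item's bin (degrees; recycled).
#' @return signed errors in degrees.
#' @export
#' @examples
#' adjustedError(30, 22.5)   # +7.5
#' adjustedError(350, 0)     # -10
adjustedError <- function(report, cuedBinCenter) {
  circDiffDeg(report, cuedBinCenter)
}

#' Median-normalize errors within each color bin
#'
#' Subtracts each cued-color bin's median signed error from the errors in
#' that bin, removing per-color idiosyncrasies in perception before the
#' bias analysis.
#'
#' @param errors signed adjusted errors (degrees).
#' @param cuedBins bin assignment per trial (any label vector).
#' @return normalized errors; the per-bin median of the output is 0.
#' @export
medianNormalize <- function(errors, cuedBins) {
  stopifnot(length(errors) == length(cuedBins), !anyNA(cuedBins))
  errors - stats::ave(errors, cuedBins, FUN = stats::median)
}

#' Moving-mean bias curve over the cued-uncued color difference
#'
#' For each center on the circular difference axis (default every 7.5
#' degrees from -180 to +172.5) the mean of the normalized errors whose
#' cued-minus-uncued difference lies within `width/2` (circularly) of the
#' center is computed. Adjacent bins overlap (width 22.5, step 7.5), so the
#' curve is smooth by construction.
#'
#' @param normErrors median-normalized signed errors (degrees).
#' @param cuedMinusUncued signed circular difference cued - uncued per trial.
#' @param width bin width in degrees.
#' @param step bin step in degrees.
#' @return data.frame with `center`, `mean` (NA where a bin is empty) and
#'   `n` (trials contributing).
#' @export
biasCurve <- function(normErrors, cuedMinusUncued, width = 22.5, step = 7.5) {
  stopifnot(length(normErrors) == length(cuedMinusUncued))
  centers <- seq(-180, 180 - step, by = step)
  stats_ <- vapply(centers, function(cc) {
    inBin <- abs(circDiffDeg(cuedMinusUncued, cc)) <= width / 2
    c(if (any(inBin)) mean(normErrors[inBin]) else NA_real_, sum(inBin))
  }, numeric(2))
  data.frame(center = centers, mean = stats_[1, ], n = as.integer(stats_[2, ]))
}

#' Behavioral summary statistics of a trial table
#'
#' Computes the adjusted error of every trial (relative to the center of the
#' cued item's bin in the first color space), its absolute-mean and signed
#' SD, and the screening statistic (proportion of trials with at most 30
#' degrees of absolute error).
#'
#' @param trials trial table with `cued_color` and `report_color`.
#' @param centers bin centers used for the adjustment.
#' @return list with `adjustedErrors`, `meanAbsError`, `meanSignedError`,
#'   `sdSignedError`, `propWithin30` (QC report, not a filter).
#' @export
behaviorSummary <- function(trials, centers = colorSpace(0)) {
  stopifnot(all(c("cued_color", "report_color") %in% names(trials)))
  bins0 <- as.integer(assignBins(trials$cued_color, centers))
  err <- adjustedError(trials$report_color, centers[bins0 + 1L])
  list(adjustedErrors = err,
       meanAbsError = mean(abs(err)),
       meanSignedError = mean(err),
       sdSignedError = stats::sd(err),
       propWithin30 = mean(abs(err) <= 30))
}

#' Group-level repulsion-bias analysis
#'
#' Runs the full behavioral pipeline on a cohort: per participant, adjusted
#' errors are median-normalized within cued-color bins and binned into the
#' moving-mean bias curve over the cued-uncued difference axis; the curves
#' are then tested against zero per bin with a cluster-corrected two-tailed
#' sign-flip permutation test that treats the difference axis as circular.
#'
#' @param trialsList list of per-participant trial tables (reports filled).
#' @param centers bin centers for the error adjustment.
#' @param width,step bias-curve bin width and step (degrees).
#' @param alphaForm cluster-forming threshold.
#' @param nPerm sign-flip permutations.
#' @param seed integer seed.
#' @return list with `centers` (difference-axis bin centers), `curves`
#'   (participants x bins matrix), `groupMean`, and `test` (the
#'   [clusterCorrect()] result).
#' @export
analyzeRepulsionBias <- function(trialsList, centers = colorSpace(0),
                                 width = 22.5, step = 7.5, alphaForm = 0.05,
                                 nPerm = 1000, seed = 1L) {
  curves <- t(vapply(trialsList, function(tr) {
    bins0 <- as.integer(assignBins(tr$cued_color, centers))
    err <- adjustedError(tr$report_color, centers[bins0 + 1L])
    norm <- medianNormalize(err, bins0)
    delta <- circDiffDeg(tr$cued_color, tr$uncued_color)
    biasCurve(norm, delta, width, step)$mean
  }, numeric(length(seq(-180, 180 - step, by = step)))))
  if (anyNA(curves))
    stop("some difference-axis bins are empty for at least one participant; ",
         "more trials (or wider bins) are needed for the group test",
         call. = FALSE)
  test <- clusterCorrect(curves, alphaForm = alphaForm, nPerm = nPerm,
                         tail = "two", seed = seed, circular = TRUE)
  list(centers = seq(-180, 180 - step, by = step), curves = curves,
       groupMean = colMeans(curves), test = test)
}
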