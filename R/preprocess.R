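#' Select and reorder channels of an EpochSet
#'
#' @param epochs an [EpochSet-class].
#' @param names channels to keep; output follows this order.
#' @return an [EpochSet-class] restricted to `names`.
#' @export
selectChannels <- function(epochs, names) {
  missing <- setdiff(names, channelNames(epochs))
  if (length(missing))
    stop("channel(s) not present: ", paste(missing, collapse = ", "),
         call. = FALSE)
  idx <- match(names, channelNames(epochs))
  EpochSet(epochs@data[, idx, , drop = FALSE], names, epochs@fs,
           epochs@timesMs, epochs@event, epochs@trialIds)
}

#' Subtract a per-trial, per-channel baseline
#'
#' @param epochs an [EpochSet-class].
#' @param startMs,endMs baseline interval (inclusive), relative to onset.
#' @return baselined [EpochSet-class].
#' @export
baselineEpochs <- function(epochs, startMs, endMs) {
  tm <- timesMs(epochs)
  if (startMs < min(tm) || endMs > max(tm) || startMs >= endMs)
    stop(sprintf("baseline interval [%g, %g] outside epoch [%g, %g]",
                 startMs, endMs, min(tm), max(tm)), call. = FALSE)
  idx <- which(tm >= startMs & tm <= endMs)
  m <- rowMeans(epochs@data[, , idx, drop = FALSE], dims = 2)
  EpochSet(epochs@data - as.vector(m), channelNames(epochs), epochs@fs,
           tm, epochs@event, epochs@trialIds)
}

#' Pool a time window of interest into one spatio-temporal pattern per trial
#'
#' Within `[startMs, endMs)` each trial/channel is baselined by subtracting
#' its mean over that window, then downsampled by averaging consecutive
#' `binMs` bins; the channel x bin values are concatenated into one vector
#' per trial. With the default 100-400 ms window, 10 ms bins and 17 channels
#' this yields 17 x 30 = 510 dimensions.
#'
#' @param epochs an [EpochSet-class].
#' @param startMs,endMs window relative to event onset; `[startMs, endMs)`.
#' @param binMs pooling bin width in ms; must span a whole number of samples.
#' @return numeric matrix, trials x (channels * bins), with attributes
#'   `event`, `window`, `binMs`, `channels`.
#' @export
windowPool <- function(epochs, startMs = 100, endMs = 400, binMs = 10) {
  tm <- timesMs(epochs)
  step <- 1000 / epochs@fs
  if (startMs < min(tm) || endMs > max(tm) + step)   # [startMs, endMs) is half-open
    stop(sprintf("window [%g, %g) outside epoch [%g, %g]",
                 startMs, endMs, min(tm), max(tm)), call. = FALSE)
  idx <- which(tm >= startMs & tm < endMs)
  spb <- binMs / step
  if (abs(spb - round(spb)) > 1e-6)
    stop("binMs must span a whole number of samples", call. = FALSE)
  spb <- as.integer(round(spb))
  nBins <- length(idx) %/% spb
  if (nBins < 1L) stop("window shorter than one bin", call. = FALSE)
  idx <- idx[seq_len(nBins * spb)]
  X <- epochs@data[, , idx, drop = FALSE]
  X <- X - as.vector(rowMeans(X, dims = 2))       # window-mean baseline
  n <- dim(X)[1]; nCh <- dim(X)[2]
  # block means over the time dimension
  X4 <- array(aperm(X, c(3, 1, 2)), c(spb, nBins, n, nCh))
  pooled <- aperm(colMeans(X4), c(2, 3, 1))       # n x ch x nBins
  out <- matrix(pooled, n, nCh * nBins)
  structure(out, event = epochs@event, window = c(startMs, endMs),
            binMs = binMs, channels = channelNames(epochs),
            trialIds = epochs@trialIds)
}

#' Sliding spatio-temporal patterns for time-resolved decoding
#'
#' At each output time point `t` (step `1000/fsOut` ms), the preceding
#' `widthMs` of data is taken, its own mean removed per trial and channel,
#' and decimated to `fsOut` by non-overlapping block means; channel x sample
#' values are concatenated. When `widthMs * fsOut / 1000` is not a whole
#' number the window is truncated to the largest whole number of blocks
#' (dropping its earliest samples), e.g. a 100 ms window at 125 Hz yields 12
#' samples per channel.
#'
#' @param epochs an [EpochSet-class].
#' @param widthMs sliding window width in ms.
#' @param fsOut output sampling rate in Hz; must divide the epoch's rate.
#' @return array trials x (channels * blocks) x timepoints with attribute
#'   `timesMs` (window end times).
#' @export
slidingPatterns <- function(epochs, widthMs = 100, fsOut = 100) {
  fs <- epochs@fs
  if (fsOut > fs) stop("fsOut must not exceed the sampling rate", call. = FALSE)
  ratio <- fs / fsOut
  if (abs(ratio - round(ratio)) > 1e-6)
    stop("fsOut must divide the sampling rate", call. = FALSE)
  blockSize <- as.integer(round(ratio))
  widthSamp <- as.integer(round(widthMs * fs / 1000))
  tm <- timesMs(epochs)
  nT <- length(tm)
  if (widthSamp > nT) stop("widthMs exceeds epoch length", call. = FALSE)
  nBlocks <- widthSamp %/% blockSize
  used <- nBlocks * blockSize
  n <- dim(epochs@data)[1]; nCh <- dim(epochs@data)[2]
  outIdx <- seq(widthSamp, nT, by = blockSize)
  out <- array(0, c(n, nCh * nBlocks, length(outIdx)))
  for (k in seq_along(outIdx)) {
    j <- outIdx[k]
    sl <- epochs@data[, , (j - used + 1L):j, drop = FALSE]
    sl <- sl - as.vector(rowMeans(sl, dims = 2))
    X4 <- array(aperm(sl, c(3, 1, 2)), c(blockSize, nBlocks, n, nCh))
    pooled <- aperm(colMeans(X4), c(2, 3, 1))     # n x ch x nBlocks
    out[, , k] <- matrix(pooled, n, nCh * nBlocks)
  }
  structure(out, timesMs = tm[outIdx], widthMs = widthMs, fsOut = fsOut,
            channels = channelNames(epochs), trialIds = epochs@trialIds)
}

#' 8-12 Hz amplitude envelope via bandpass filtering and the Hilbert transform
#'
#' Each trial/channel is bandpass filtered with a zero-phase (two-pass)
#' Hamming-window FIR filter of order `3 * floor(fs / lowHz)`, the analytic
#' signal is formed by the Hilbert transform, and its magnitude is returned.
#' Epochs are reflection-padded (at least three cycles of `lowHz` and the
#' filter length) before filtering; roughly the outer 100 ms of the envelope
#' still carries residual edge bias and should not be interpreted on its own.
#'
#' @param epochs an [EpochSet-class].
#' @param lowHz,highHz band edges in Hz; `0 < lowHz < highHz < fs/2`.
#' @return an [EpochSet-class] of the same shape holding the non-negative
#'   amplitude envelope.
#' @export
alphaEnvelope <- function(epochs, lowHz = 8, highHz = 12) {
  fs <- epochs@fs
  if (!(0 < lowHz && lowHz < highHz))
    stop("need 0 < lowHz < highHz", call. = FALSE)
  if (highHz >= fs / 2)
    stop("band must lie below the Nyquist frequency", call. = FALSE)
  ord <- 2L * ((3L * floor(fs / lowHz)) %/% 2L)    # even order
  h <- signal::fir1(ord, c(lowHz, highHz) / (fs / 2), type = "pass")
  d <- dim(epochs@data)
  n <- d[1]; nCh <- d[2]; nT <- d[3]
  X <- matrix(aperm(epochs@data, c(3, 1, 2)), nT)  # time x (trials*channels)
  pad <- max(ceiling(3 * fs / lowHz), length(h))
  pad <- min(pad, nT - 1L)
  # odd (point-symmetric) reflection keeps value and slope continuous at the
  # ends, minimizing the filter transient that leaks into the epoch
  Xp <- rbind(matrix(2 * X[1L, ], pad, ncol(X), byrow = TRUE) -
                X[(pad + 1L):2L, , drop = FALSE],
              X,
              matrix(2 * X[nT, ], pad, ncol(X), byrow = TRUE) -
                X[(nT - 1L):(nT - pad), , drop = FALSE])
  N <- nrow(Xp)
  H <- stats::fft(c(h, numeric(N - length(h))))
  gain <- Mod(H)^2                                  # two-pass, zero phase
  u <- numeric(N)                                   # analytic-signal weights
  u[1] <- 1
  if (N %% 2 == 0) { u[N / 2 + 1] <- 1; u[2:(N / 2)] <- 2 } else
    u[2:((N + 1) / 2)] <- 2
  Fx <- stats::mvfft(Xp)
  env <- abs(stats::mvfft(Fx * (gain * u), inverse = TRUE) / N)
  env <- env[(pad + 1L):(pad + nT), , drop = FALSE]
  out <- aperm(array(env, c(nT, n, nCh)), c(2, 3, 1))
  EpochSet(out, channelNames(epochs), fs, timesMs(epochs), epochs@event,
           epochs@trialIds)
}
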