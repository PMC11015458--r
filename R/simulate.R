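#' Equidistant color wheel angles
#'
#' @param n number of colors; must be at least 2.
#' @return `n` angles in degrees, starting at 0 with step `360/n`.
#' @export
#' @examples
#' makeColorWheel(4)  # 0 90 180 270
makeColorWheel <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 2)
    stop("n must be a single integer >= 2", call. = FALSE)
  seq(0, 360 - 360 / n, by = 360 / n)
}

#' Generate a trial table for the retro-cue task
#'
#' Item colors are drawn independently and uniformly from the configured
#' wheel; the cue (1 or 2) is drawn with probability 0.5 and determines which
#' item is cued. `report_color` is left `NA`; fill it with
#' [generateReports()].
#'
#' @param config a [SimConfig-class].
#' @param seed integer seed.
#' @return data.frame with columns `trial_id`, `item1_color`, `item2_color`,
#'   `cue`, `cued_color`, `uncued_color`, `report_color`.
#' @export
#' @examples
#' head(generateTrials(simConfig(nTrials = 8), seed = 1))
generateTrials <- function(config, seed) {
  validObject(config)
  wheel <- makeColorWheel(config@nWheelColors)
  n <- config@nTrials
  .withSeed(seed, {
    item1 <- sample(wheel, n, replace = TRUE)
    item2 <- sample(wheel, n, replace = TRUE)
    cue <- sample(1:2, n, replace = TRUE)
  })
  data.frame(
    trial_id = seq_len(n),
    item1_color = item1,
    item2_color = item2,
    cue = cue,
    cued_color = ifelse(cue == 1L, item1, item2),
    uncued_color = ifelse(cue == 1L, item2, item1),
    report_color = NA_real_
  )
}

# von Mises sampler (Best & Fisher 1979); returns radians in (-pi, pi]
.rvonmises <- function(n, kappa) {
  if (!is.finite(kappa)) return(rep(0, n))
  if (kappa <= 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(keep)) {
      th <- sign(u3[keep] - 0.5) * acos(pmin(1, pmax(-1, f[keep])))
      out[got + seq_along(th)] <- th
      got <- got + length(th)
    }
  }
  out
}

# odd repulsion kernel: zero at 0 and +/-180 deg, pushes away from the uncued
# color; delta is the signed circular difference cued - uncued in degrees
.repulsionKernel <- function(deltaDeg) {
  sin(.deg2rad(deltaDeg)) * exp(-abs(deltaDeg) / 90)
}

# sin-shaped pull toward the nearest primary hue, zero at the primary itself
.primaryPull <- function(colorsDeg, primariesDeg) {
  d <- vapply(colorsDeg, function(th) {
    diffs <- circDiffDeg(primariesDeg, th)
    diffs[which.min(abs(diffs))]
  }, numeric(1))
  sin(3 * .deg2rad(d))
}

#' Fill behavioral reports into a trial table
#'
#' The report is the cued color plus von Mises circular noise, a repulsion
#' away from the uncued color, and an attraction toward the nearest of three
#' primary hues. The repulsion follows the odd kernel
#' `K(delta) = sin(delta) * exp(-|delta| / 90)` with `delta` the signed
#' circular difference cued - uncued (degrees): reports deviate away from the
#' task-irrelevant color, maximally for intermediate color differences.
#'
#' @param trials trial table from [generateTrials()].
#' @param config a [SimConfig-class].
#' @param seed integer seed.
#' @return `trials` with `report_color` filled (degrees in `[0, 360)`).
#' @export
generateReports <- function(trials, config, seed) {
  stopifnot(all(c("cued_color", "uncued_color") %in% names(trials)))
  delta <- circDiffDeg(trials$cued_color, trials$uncued_color)
  noise <- .withSeed(seed, .rvonmises(nrow(trials), config@reportKappa))
  report <- trials$cued_color +
    noise * 180 / pi +
    config@repulsionAmpDeg * .repulsionKernel(delta) +
    config@primaryAttractionDeg *
      .primaryPull(trials$cued_color, config@primariesDeg)
  trials$report_color <- wrapDeg(report)
  trials
}

# half-cosine channel tuning profile of a color against the 16 canonical
# centers; power chosen so the full width at half maximum is ~widthDeg
.tuningBasis <- function(colorsDeg, widthDeg) {
  centers <- seq(0, 337.5, by = 22.5)
  pow <- log(0.5) / log(cos(.deg2rad(widthDeg / 4)))
  b <- vapply(colorsDeg, function(th) {
    v <- cos(.deg2rad(circDiffDeg(th, centers)) / 2)^pow
    v / sqrt(sum(v^2))
  }, numeric(16))
  b  # 16 x n
}

# fixed unit-energy evoked transient confined to 100-400 ms post-onset
.evokedTransient <- function(timesMs) {
  s <- numeric(length(timesMs))
  in_win <- timesMs >= 100 & timesMs <= 400
  s[in_win] <- sin(pi * (timesMs[in_win] - 100) / 300)^2
  if (any(in_win)) s <- s / sqrt(sum(s^2))
  s
}

# time-varying positive amplitude profile of the alpha carrier, per trial
# (rows). Two components: a deterministic event-locked modulation (partial
# desynchronization over 100-400 ms post-onset, identical across trials, so
# condition averages retain it) and a slow stochastic waxing-waning (Gaussian
# noise lowpassed below ~2 Hz, depth 0.3) for realism.
.slowAmplitude <- function(n, nT, fs, timesMs) {
  erd <- numeric(nT)
  in_win <- timesMs >= 100 & timesMs <= 400
  erd[in_win] <- sin(pi * (timesMs[in_win] - 100) / 300)^2
  z <- matrix(stats::rnorm(n * nT), nT, n)
  f <- c(seq(0, floor(nT / 2)), -seq(ceiling(nT / 2) - 1, 1)) * fs / nT
  H <- exp(-(f / 2)^2)
  zs <- Re(stats::mvfft(stats::mvfft(z) * H, inverse = TRUE) / nT)
  zs <- zs / max(stats::sd(as.vector(zs)), 1e-12)
  pmax(1 - 0.4 * matrix(erd, n, nT, byrow = TRUE) + 0.3 * t(zs), 0.05)
}

# per-participant tuning maps: channels x 16, drawn once from the seed stream
.tuningMaps <- function(config, seed) {
  nCh <- length(config@channelNames)
  .withSeed(.subSeeds(seed, 1L), {
    list(W = matrix(stats::rnorm(nCh * 16), nCh, 16),
         Walpha = matrix(stats::rnorm(nCh * 16), nCh, 16))
  })
}

#' Generate epoched multichannel signals for one event
#'
#' Simulates trials x channels x time data from a linear forward model:
#' color-tuned evoked transients (100-400 ms post-onset), a color-tuned
#' 10 Hz sinusoidal carrier with random phase per trial (information in its
#' amplitude, not phase), and spatially correlated Gaussian noise. The
#' per-participant tuning maps are a deterministic function of `seed`, so all
#' four events of one participant share the same maps while noise differs.
#'
#' Amplitude rules per event: the `item1` epoch carries item 1 at `snrItem`;
#' the `item2` epoch carries item 2 at `snrItem` and a residual item-1 trace
#' at `0.5 * snrItem`; the `cue` epoch carries no evoked color signal; the
#' `impulse` epoch carries the cued color at `snrCuedImpulse` and the uncued
#' color at `snrUncuedImpulse`. The alpha carrier is present from the cue
#' epoch onward at `alphaAmpCued` / `alphaAmpUncued`.
#'
#' @param trials trial table from [generateTrials()].
#' @param config a [SimConfig-class].
#' @param event one of `"item1"`, `"item2"`, `"cue"`, `"impulse"`.
#' @param seed integer participant seed.
#' @return an [EpochSet-class].
#' @export
generateEpochs <- function(trials, config, event, seed) {
  validObject(config)
  if (!(length(event) == 1L && event %in% .EVENTS))
    stop(sprintf("unknown event '%s'; expected one of %s",
                 paste(event, collapse = ","),
                 paste(.EVENTS, collapse = ", ")), call. = FALSE)
  n <- nrow(trials)
  nCh <- length(config@channelNames)
  w <- config@epochWindows[[event]]
  timesMs <- seq(w[1], w[2], by = 1000 / config@fs)
  nT <- length(timesMs)

  maps <- .tuningMaps(config, seed)

  # evoked amplitudes per source color for this event
  evoked <- switch(event,
    item1 = list(list(colors = trials$item1_color, amp = config@snrItem)),
    item2 = list(list(colors = trials$item2_color, amp = config@snrItem),
                 list(colors = trials$item1_color, amp = 0.5 * config@snrItem)),
    cue = list(),
    impulse = list(
      list(colors = trials$cued_color, amp = config@snrCuedImpulse),
      list(colors = trials$uncued_color, amp = config@snrUncuedImpulse))
  )
  # alpha carrier amplitudes (cue epoch onward)
  alpha <- if (event %in% c("cue", "impulse")) {
    list(list(colors = trials$cued_color, amp = config@alphaAmpCued),
         list(colors = trials$uncued_color, amp = config@alphaAmpUncued))
  } else list()

  data <- array(0, dim = c(n, nCh, nT))
  s <- .evokedTransient(timesMs)
  for (src in evoked) {
    if (src$amp == 0) next
    P <- t(maps$W %*% .tuningBasis(src$colors, config@tuningWidthDeg))  # n x ch
    for (ch in seq_len(nCh)) data[, ch, ] <- data[, ch, ] +
        src$amp * outer(P[, ch], s)
  }

  # event-specific noise/phase seed so events differ but remain reproducible
  evSeed <- .subSeeds(seed, 2L + match(event, .EVENTS))[2L + match(event, .EVENTS)]
  .withSeed(evSeed, {
    tSec <- timesMs / 1000
    for (src in alpha) {
      if (src$amp == 0) next
      A <- t(maps$Walpha %*% .tuningBasis(src$colors, config@tuningWidthDeg))
      phi <- stats::runif(n, 0, 2 * pi)
      carrier <- sin(2 * pi * 10 * matrix(tSec, n, nT, byrow = TRUE) + phi)
      # event-locked desynchronization plus slow bursting: a purely constant
      # carrier amplitude would be invisible to analyses that remove each
      # window's own mean, and purely stochastic fluctuations cancel in the
      # condition averages
      carrier <- carrier * .slowAmplitude(n, nT, config@fs, timesMs)
      for (ch in seq_len(nCh)) data[, ch, ] <- data[, ch, ] +
          src$amp * A[, ch] * carrier
    }
    if (config@noiseSd > 0) {
      corr <- config@spatialCorr^abs(outer(seq_len(nCh), seq_len(nCh), "-"))
      L <- t(chol(corr))
      Z <- matrix(stats::rnorm(nCh * n * nT), nCh)
      noise <- config@noiseSd * (L %*% Z)          # ch x (n*nT)
      data <- data + aperm(array(noise, c(nCh, n, nT)), c(2, 1, 3))
    }
  })

  EpochSet(data, config@channelNames, config@fs, timesMs, event,
           trialIds = as.integer(trials$trial_id))
}

#' Simulate one participant of the retro-cue experiment
#'
#' @param config a [SimConfig-class].
#' @param participant participant index (1-based); selects that participant's
#'   seed from the stream derived from `config@seed`.
#' @param events which epochs to generate (default all four).
#' @return list with elements `trials` (reports filled), `epochs` (named list
#'   of [EpochSet-class]), and `seed` (the participant seed used).
#' @export
simulateParticipant <- function(config, participant = 1L,
                                events = .EVENTS) {
  pSeeds <- .subSeeds(config@seed, config@nParticipants + 1L)
  seed <- pSeeds[participant]
  trials <- generateTrials(config, seed)
  trials <- generateReports(trials, config, seed + 1L)
  epochs <- lapply(events, function(ev) generateEpochs(trials, config, ev, seed))
  names(epochs) <- events
  list(trials = trials, epochs = epochs, seed = seed)
}
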