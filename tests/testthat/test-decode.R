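test_that("colors map to the circularly nearest bin center with low-index ties", {
  sp0 <- colorSpace(0)
  expect_equal(as.integer(assignBins(c(10, 350, 11.25), sp0)), c(0L, 0L, 0L))
  expect_equal(as.integer(assignBins(33, sp0)), 1L)

  # brute-force nearest-center oracle on a dense grid of colors
  circDist <- function(a, b) pmin(abs(a - b), 360 - abs(a - b))
  for (centers in colorSpaces()) {
    colors <- seq(0, 359.5, by = 3.7)
    got <- as.integer(assignBins(colors, centers))
    want <- vapply(colors, function(th)
      which.min(circDist(th, centers)) - 1L, integer(1))
    expect_identical(got, want)
  }
})

test_that("half-cosine basis has the analytic endpoints and limit behavior", {
  raw <- halfCosineBasis(15, normalize = FALSE)
  expect_equal(raw[1, 1], 1)                      # delta = 0
  expect_equal(raw[1, 9], 0)                      # delta = 180 deg
  W <- halfCosineBasis(15)
  expect_equal(rowSums(W), rep(1, 16))
  expect_equal(halfCosineBasis(0), matrix(1 / 16, 16, 16))  # uniform pooling
  expect_equal(halfCosineBasis(5000), diag(16), tolerance = 1e-6)
  expect_error(halfCosineBasis(-1), "non-negative")
})

test_that("shrinkage covariance is consistent and rejects degenerate input", {
  withr::with_seed(99, {
    X <- matrix(rnorm(1e5 * 10), ncol = 10)
    S <- shrinkageCovariance(X)
    expect_lt(max(abs(S - diag(10))), 0.05)

    X2 <- cbind(rnorm(2e4, sd = 2), rnorm(2e4, sd = 1))
    S2 <- shrinkageCovariance(X2)
    expect_equal(diag(S2), c(4, 1), tolerance = 0.05 * 4)
  })
  expect_error(shrinkageCovariance(matrix(3, 10, 4)), "singular")
})

test_that("Mahalanobis distances match closed forms and the explicit-inverse oracle", {
  expect_equal(mahalanobisDist(c(3, 4), rbind(c(0, 0)), diag(2)), 5)
  expect_equal(mahalanobisDist(c(2, 0), rbind(c(0, 0)), diag(c(4, 1))), 1)
  withr::with_seed(4, {
    for (i in 1:20) {
      d <- 5
      Sigma <- randomSPD(d)
      x <- rnorm(d)
      M <- matrix(rnorm(16 * d), 16)
      oracle <- sqrt(vapply(seq_len(16), function(k)
        drop(t(x - M[k, ]) %*% solve(Sigma) %*% (x - M[k, ])), numeric(1)))
      expect_equal(mahalanobisDist(x, M, Sigma), oracle, tolerance = 1e-10)
    }
  })
  expect_error(mahalanobisDist(c(1, 1), rbind(c(0, 0)),
                               matrix(c(1, 2, 2, 1), 2)), "not positive")
})

test_that("cosine scoring has the analytic fixed points and matches brute force", {
  flat <- cosineScore(rep(3.7, 16), 5L)
  expect_identical(flat$accuracy, 0)
  expect_true(all(flat$tuning == 0))

  centers <- colorSpace(0)
  delta <- circDiffDeg(centers, centers[3])
  sc <- cosineScore(10 - cos(impulseWM:::.deg2rad(delta)), 2L)
  expect_equal(sc$accuracy, 0.5)                 # sum cos^2 over a cycle = n/2

  # arbitrary distances against a hand-rolled loop
  d <- 0:15
  got <- cosineScore(d, 7L)
  s <- -(d - mean(d))
  acc <- 0
  for (k in 1:16)
    acc <- acc + s[k] * cos(impulseWM:::.deg2rad(circDiffDeg(centers[k], centers[8]))) / 16
  expect_equal(got$accuracy, acc)
  expect_equal(sum(got$tuning), 0)
  # tuning entry at delta 0 is the score of the true bin
  expect_equal(unname(got$tuning["0"]), s[8])
  # accuracy equals the cosine-weighted mean of the tuning curve
  deltas <- as.numeric(names(got$tuning))
  expect_equal(mean(got$tuning * cos(impulseWM:::.deg2rad(deltas))), acc)
  # invariance to adding a constant to all distances
  expect_equal(cosineScore(d + 100, 7L)$accuracy, acc)
})

test_that("the compiled scorer agrees with the plain-R reference path", {
  withr::with_seed(12, {
    n <- 160; d <- 12
    colors <- sample(makeColorWheel(48), n, replace = TRUE)
    bins0 <- as.integer(assignBins(colors, colorSpace(0)))
    X <- matrix(rnorm(n * d), n)
    X <- X + outer(cos(impulseWM:::.deg2rad(colors)), rnorm(d))
    foldOf <- impulseWM:::.foldPlan(bins0, 4L, stratified = TRUE)
    keep <- impulseWM:::.subsamplePlan(bins0, foldOf, 4L, colorSpace(0))
  })
  basis <- halfCosineBasis(15)
  cosMat <- impulseWM:::.cosMat()
  cpp <- impulseWM:::cppScoreRep(array(X, c(dim(X), 1L)), bins0, foldOf,
                                 keep, basis, cosMat)
  ref <- impulseWM:::.scoreRepR(X, bins0, foldOf, keep)
  expect_equal(as.vector(cpp$acc), ref$acc, tolerance = 1e-10)
  expect_equal(as.vector(cpp$tun), unname(ref$tun), tolerance = 1e-10)
})

test_that("window decoding is reproducible, scale-invariant and label-sensitive", {
  p <- testParticipant()
  pat <- testPatterns()
  r1 <- decodeWindow(pat, p$trials$cued_color, nReps = 3, seed = 31L)
  r2 <- decodeWindow(pat, p$trials$cued_color, nReps = 3, seed = 31L)
  expect_identical(r1@trialAccuracy, r2@trialAccuracy)
  expect_gt(accuracy(r1), 0)
  expect_equal(sum(tuningCurve(r1)), 0, tolerance = 1e-10)

  # global pattern scaling leaves Mahalanobis-based accuracy unchanged
  r3 <- decodeWindow(pat * 2.5, p$trials$cued_color, nReps = 3, seed = 31L)
  expect_equal(accuracy(r3), accuracy(r1), tolerance = 1e-8)

  # label permutation should sit at chance (within 3 SE over trials)
  perm <- withr::with_seed(8, sample(p$trials$cued_color))
  r0 <- decodeWindow(pat, perm, nReps = 3, seed = 31L)
  se <- sd(trialAccuracy(r0)) / sqrt(length(trialAccuracy(r0)))
  expect_lt(abs(accuracy(r0)), 3 * se)
})

test_that("noiseless separable patterns decode positively for every trial", {
  withr::with_seed(14, {
    n <- 256
    colors <- sample(makeColorWheel(48), n, replace = TRUE)
    B <- impulseWM:::.tuningBasis(colors, 60)      # 16 x n, noise-free
    W <- matrix(rnorm(20 * 16), 20)
    X <- t(W %*% B)
  })
  res <- decodeWindow(X, colors, nFolds = 4, nReps = 2, seed = 3L)
  expect_true(all(trialAccuracy(res) > 0))
})

test_that("decoded accuracy rises monotonically with the impulse signal strength", {
  accAt <- function(snr) {
    cfg <- testConfig(nTrials = 512, snrCuedImpulse = snr,
                      snrUncuedImpulse = 0)
    tr <- generateTrials(cfg, 55L)
    ep <- generateEpochs(tr, cfg, "impulse", 55L)  # shared maps and noise
    accuracy(decodeWindow(windowPool(ep, 100, 400, 50), tr$cued_color,
                          nReps = 3, seed = 56L))
  }
  accs <- vapply(c(0.2, 0.6, 1.2), accAt, numeric(1))
  expect_identical(cor(accs, 1:3, method = "spearman"), 1)
})

test_that("insufficient trials per bin raise an actionable error", {
  pat <- matrix(rnorm(40 * 6), 40)
  colors <- rep(c(0, 90, 180, 270), 10)    # only 4 of 16 bins occupied
  expect_error(decodeWindow(pat, colors, nFolds = 8, nReps = 1, seed = 1L),
               "bin .* has only")
})

test_that("channels without color coupling show no time-resolved decoding", {
  # gaze-channel control: 4 EOG-like channels carrying no color signal
  cfg <- simConfig(nParticipants = 6, nTrials = 512, fs = 100, seed = 77L,
                   channelNames = c("HEOG_L", "HEOG_R", "VEOG_U", "VEOG_D"),
                   snrItem = 0, snrCuedImpulse = 0, snrUncuedImpulse = 0,
                   alphaAmpCued = 0, alphaAmpUncued = 0)
  accs <- t(vapply(1:6, function(p) {
    part <- simulateParticipant(cfg, p, events = "impulse")
    tc <- decodeTimecourse(part$epochs$impulse, part$trials$cued_color,
                           widthMs = 100, fsOut = 20, nReps = 2,
                           seed = part$seed)
    accuracy(tc)
  }, numeric(14)))
  cl <- clusterCorrect(accs, nPerm = 500, tail = "one_greater", seed = 78L)
  expect_false(any(cl$clusters$p < 0.05))
})

test_that("time-resolved decoding localizes the evoked window and is deterministic", {
  p <- testParticipant()
  tc1 <- decodeTimecourse(p$impulse, p$trials$cued_color, widthMs = 100,
                          fsOut = 20, nReps = 2, seed = 91L)
  tc2 <- decodeTimecourse(p$impulse, p$trials$cued_color, widthMs = 100,
                          fsOut = 20, nReps = 2, seed = 91L)
  expect_identical(accuracy(tc1), accuracy(tc2))
  expect_equal(max(abs(colSums(similarityMatrix(tc1)))), 0, tolerance = 1e-10)
  # the transient lives at 100-400 ms: windows ending inside it see it best,
  # and windows that end before onset or start after offset see nothing
  tms <- timesMs(tc1)
  core <- tms >= 190 & tms <= 390
  far <- tms < 100 | tms > 490
  expect_true(tms[which.max(accuracy(tc1))] >= 150 &&
                tms[which.max(accuracy(tc1))] <= 450)
  expect_gt(mean(accuracy(tc1)[core]),
            3 * abs(mean(accuracy(tc1)[far])) + 0.005)
})
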