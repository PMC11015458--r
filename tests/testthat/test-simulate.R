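test_that("color wheel divides the circle equally", {
  expect_equal(makeColorWheel(4), c(0, 90, 180, 270))
  w48 <- makeColorWheel(48)
  expect_length(w48, 48)
  expect_equal(unique(diff(w48)), 7.5)
  expect_true(all(w48 >= 0 & w48 < 360))
  expect_error(makeColorWheel(1), "n must be")
})

test_that("trial tables are deterministic, uniform and internally consistent", {
  cfg <- simConfig(nParticipants = 1, nTrials = 10000)
  t1 <- generateTrials(cfg, 42L)
  t2 <- generateTrials(cfg, 42L)
  expect_identical(t1, t2)

  # per-color frequency within 4 SD of the uniform binomial expectation
  p <- 1 / 48
  bound <- 4 * sqrt(10000 * p * (1 - p))
  cnt <- table(factor(t1$item1_color, levels = makeColorWheel(48)))
  expect_true(all(abs(cnt - 10000 * p) <= bound))

  # cue counts within 4 SD of n/2
  expect_lt(abs(sum(t1$cue == 1) - 5000), 4 * sqrt(10000 * 0.25))

  # cued/uncued bookkeeping
  expect_identical(t1$cued_color,
                   ifelse(t1$cue == 1, t1$item1_color, t1$item2_color))
  expect_identical(t1$uncued_color,
                   ifelse(t1$cue == 1, t1$item2_color, t1$item1_color))
  expect_true(all(t1$item1_color %in% makeColorWheel(48)))
})

test_that("noiseless reports reproduce the cued color exactly", {
  cfg <- simConfig(nParticipants = 1, nTrials = 200, reportKappa = Inf,
                   repulsionAmpDeg = 0, primaryAttractionDeg = 0)
  tr <- generateReports(generateTrials(cfg, 5L), cfg, 6L)
  expect_equal(tr$report_color, tr$cued_color)
})

test_that("repulsion kernel is odd with zero endpoints and pushes away from the uncued item", {
  K <- impulseWM:::.repulsionKernel
  expect_equal(K(0), 0)
  expect_equal(K(180), 0)
  expect_equal(K(-180), 0)
  expect_equal(K(60), -K(-60))

  # Monte-Carlo mean signed error at delta = +45 degrees is positive
  cfg <- simConfig(nParticipants = 1, nTrials = 10000, reportKappa = 8,
                   repulsionAmpDeg = 5, primaryAttractionDeg = 0)
  tr <- generateTrials(cfg, 9L)
  tr$cued_color <- 90; tr$uncued_color <- 45   # cued - uncued = +45
  tr <- generateReports(tr, cfg, 10L)
  err <- circDiffDeg(tr$report_color, tr$cued_color)
  expect_gt(mean(err), 1)      # expected bias ~ 5 * K(45) ~ 2.1 deg
})

test_that("pure-noise epochs have unit per-channel variance and no structure", {
  cfg <- testConfig(snrItem = 0, snrCuedImpulse = 0, snrUncuedImpulse = 0,
                    alphaAmpCued = 0, alphaAmpUncued = 0, noiseSd = 1,
                    nTrials = 256)
  tr <- generateTrials(cfg, 3L)
  ep <- generateEpochs(tr, cfg, "impulse", 3L)
  v <- apply(epochData(ep), 2, function(x) var(as.vector(x)))
  expect_true(all(abs(v - 1) < 0.05))
})

test_that("the evoked forward model is deterministic given the tuning maps", {
  cfg <- testConfig(noiseSd = 0, alphaAmpCued = 0, alphaAmpUncued = 0,
                    snrUncuedImpulse = 0, nTrials = 4)
  tr <- generateTrials(cfg, 11L)
  tr$cued_color <- c(90, 90, 180, 180)
  tr$uncued_color <- c(0, 45, 0, 45)
  ep <- generateEpochs(tr, cfg, "impulse", 11L)
  X <- epochData(ep)
  expect_equal(X[1, , ], X[2, , ])         # same cued color, no noise
  expect_false(isTRUE(all.equal(X[1, , ], X[3, , ])))

  # identical (config, seed) twice -> bit-identical epochs
  ep2 <- generateEpochs(tr, cfg, "impulse", 11L)
  expect_identical(epochData(ep), epochData(ep2))
})

test_that("events share tuning maps but differ in noise for one participant seed", {
  cfg <- testConfig(nTrials = 16)
  maps1 <- impulseWM:::.tuningMaps(cfg, 21L)
  maps2 <- impulseWM:::.tuningMaps(cfg, 21L)
  expect_identical(maps1, maps2)
  tr <- generateTrials(cfg, 21L)
  e1 <- generateEpochs(tr, cfg, "item1", 21L)
  e2 <- generateEpochs(tr, cfg, "item2", 21L)
  expect_false(identical(epochData(e1)[, , 1], epochData(e2)[, , 1]))
  expect_error(generateEpochs(tr, cfg, "probe", 21L), "unknown event")
})

test_that("impulse-epoch alpha bandpower grows monotonically with the cued alpha amplitude", {
  bandpower <- function(amp) {
    cfg <- testConfig(nTrials = 16, snrCuedImpulse = 0, snrUncuedImpulse = 0,
                      alphaAmpCued = amp, noiseSd = 0.2)
    tr <- generateTrials(cfg, 13L)
    ep <- generateEpochs(tr, cfg, "impulse", 13L)
    X <- epochData(ep)
    fs <- samplingRate(ep)
    nT <- dim(X)[3]
    f <- seq(0, fs, length.out = nT + 1)[seq_len(nT)]
    inBand <- f >= 8 & f <= 12
    mean(apply(X, 1:2, function(x) sum(Mod(fft(x))[inBand]^2)))
  }
  bp <- vapply(c(0.3, 0.6, 1.2), bandpower, numeric(1))
  expect_true(all(diff(bp) > 0))
})

test_that("simulated reports land near the cued color with primary-hue clustering", {
  p <- testParticipant()
  err <- abs(circDiffDeg(p$trials$report_color, p$trials$cued_color))
  expect_lt(mean(err), 45)
  # reports cluster toward the configured primaries
  prim <- estimatePrimaries(p$trials$report_color, seed = 2L)
  expect_true(all(vapply(prim, function(x)
    min(abs(circDiffDeg(x, p$cfg@primariesDeg))), numeric(1)) < 30))
})
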