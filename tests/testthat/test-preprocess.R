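test_that("channel selection subsets, reorders and validates names", {
  arr <- array(seq_len(2 * 4 * 3), c(2, 4, 3))
  ep <- toyEpochs(arr)
  sel <- selectChannels(ep, c("ch3", "ch1"))
  expect_equal(channelNames(sel), c("ch3", "ch1"))
  expect_equal(epochData(sel)[, 1, ], arr[, 3, ])
  expect_identical(epochData(selectChannels(ep, channelNames(ep))),
                   epochData(ep))
  expect_error(selectChannels(ep, c("ch1", "XX9")), "XX9")
})

test_that("window pooling yields the documented dimensionality and removes constants", {
  p <- testParticipant()
  pat10 <- windowPool(toyEpochs(array(rnorm(4 * 17 * 300), c(4, 17, 300))),
                      100, 400, 10)
  expect_equal(dim(pat10), c(4, 17 * 30))      # 17 channels x 30 bins = 510

  constant <- toyEpochs(array(5, c(3, 2, 200)))
  expect_true(all(windowPool(constant, 100, 300, 10) == 0))
  expect_error(windowPool(constant, 100, 5000, 10), "outside")
})

test_that("pooling a linear ramp gives bin means equidistant around zero", {
  # 4 samples at 500 Hz, values 0,2,4,6; one channel; window [0, 8), 2 bins
  arr <- array(c(0, 2, 4, 6), c(1, 1, 4))
  pat <- windowPool(toyEpochs(arr), 0, 8, 4)
  expect_equal(as.vector(pat), c(-2, 2))
})

test_that("window pooling and sliding patterns are linear operators", {
  a <- 2.5; b <- -1.25
  X <- array(rnorm(6 * 3 * 100), c(6, 3, 100))
  Y <- array(rnorm(6 * 3 * 100), c(6, 3, 100))
  pool <- function(Z) windowPool(toyEpochs(Z), 20, 180, 20)
  expect_equal(pool(a * X + b * Y), a * pool(X) + b * pool(Y),
               ignore_attr = TRUE)
  slide <- function(Z) {
    s <- slidingPatterns(toyEpochs(Z), 60, 100)
    attributes(s)[c("timesMs", "widthMs", "fsOut", "channels", "trialIds")] <- NULL
    s
  }
  expect_equal(slide(a * X + b * Y), a * slide(X) + b * slide(Y))
})

test_that("sliding patterns have the stated per-window sample counts", {
  ep <- toyEpochs(array(rnorm(2 * 17 * 400), c(2, 17, 400)))
  s100 <- slidingPatterns(ep, 100, 100)
  expect_equal(dim(s100)[2], 17 * 10)          # 10 samples/channel -> 170
  s125 <- slidingPatterns(ep, 100, 125)
  expect_equal(dim(s125)[2], 17 * 12)          # 12.5 truncated to 12 -> 204
  expect_true(all(slidingPatterns(toyEpochs(array(3, c(2, 2, 100))),
                                  40, 100) == 0))
  expect_error(slidingPatterns(ep, 100, 600), "must not exceed")
  expect_error(slidingPatterns(ep, 100, 333), "divide")
})

test_that("alpha envelope recovers amplitude in-band and rejects out-of-band", {
  tm <- seq(-150, 1100, by = 2)
  mk <- function(freq, A) {
    arr <- array(0, c(2, 2, length(tm)))
    for (i in 1:2) for (ch in 1:2)
      arr[i, ch, ] <- A * sin(2 * pi * freq * tm / 1000 + i + ch)
    EpochSet(arr, c("a", "b"), 500, tm, "cue")
  }
  interior <- tm > -150 + 200 & tm < 1100 - 200
  env10 <- epochData(alphaEnvelope(mk(10, 3)))
  expect_true(all(abs(env10[, , interior] - 3) < 0.06))   # within 2%
  env25 <- epochData(alphaEnvelope(mk(25, 3)))
  expect_lt(max(env25[, , interior]), 0.3)                # < 0.1 * A
  zero <- alphaEnvelope(toyEpochs(array(0, c(2, 2, 500))))
  expect_true(all(epochData(zero) == 0))
  # non-negativity on arbitrary input
  rnd <- alphaEnvelope(toyEpochs(array(rnorm(2 * 2 * 400), c(2, 2, 400))))
  expect_true(all(epochData(rnd) >= 0))
  expect_error(alphaEnvelope(toyEpochs(array(0, c(1, 1, 100)), fs = 20)),
               "Nyquist")
  expect_error(alphaEnvelope(toyEpochs(array(0, c(1, 1, 100))), 12, 8),
               "lowHz")
})

test_that("baselining subtracts the per-trial/channel interval mean", {
  expect_true(all(epochData(baselineEpochs(
    toyEpochs(array(7, c(2, 2, 100)), startMs = -100), -100, 0)) == 0))

  # step of height h at 0 ms
  tm <- 100
  arr <- array(0, c(1, 1, tm))
  arr[1, 1, 51:100] <- 4.5
  stepped <- baselineEpochs(toyEpochs(arr, startMs = -100), -100, -2)
  expect_equal(epochData(stepped)[1, 1, 100], 4.5)

  rndArr <- array(rnorm(3 * 2 * 150), c(3, 2, 150))
  ep <- toyEpochs(rndArr, startMs = -100)
  bl <- baselineEpochs(ep, -100, 0)
  idx <- which(timesMs(ep) >= -100 & timesMs(ep) <= 0)
  expect_equal(max(abs(rowMeans(epochData(bl)[, , idx, drop = FALSE],
                                dims = 2))), 0, tolerance = 1e-12)
  expect_error(baselineEpochs(ep, -500, 0), "outside")
})

test_that("preprocessing preserves trial alignment", {
  p <- testParticipant()
  ep <- p$impulse
  expect_identical(trialIds(selectChannels(ep, channelNames(ep)[1:5])),
                   trialIds(ep))
  expect_identical(attr(windowPool(ep, 100, 400, 50), "trialIds"),
                   trialIds(ep))
  expect_identical(trialIds(alphaEnvelope(ep)), trialIds(ep))
})
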