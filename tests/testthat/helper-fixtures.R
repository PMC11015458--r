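# Shared fixtures, built lazily and cached for the test run. Reduced-scale
# simulations use fs = 100 Hz and coarse 50 ms pooling bins (d = 102) so the
# suite stays fast; the decoding machinery is rate- and bin-agnostic.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, build(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# reduced-scale study config used across tests; any field can be overridden
testConfig <- function(...) {
  args <- utils::modifyList(
    list(nParticipants = 8, nTrials = 512, fs = 100, seed = 7L), list(...))
  do.call(simConfig, args)
}

# one simulated participant with impulse epochs and filled reports
testParticipant <- function() {
  fixture("participant", function() {
    cfg <- testConfig()
    tr <- generateTrials(cfg, 101L)
    tr <- generateReports(tr, cfg, 102L)
    list(cfg = cfg, trials = tr,
         impulse = generateEpochs(tr, cfg, "impulse", 101L))
  })
}

# window-of-interest patterns for the test participant
testPatterns <- function() {
  fixture("patterns", function() {
    p <- testParticipant()
    windowPool(p$impulse, 100, 400, 50)
  })
}

# tiny EpochSet built from an explicit array
toyEpochs <- function(data, fs = 500, startMs = 0, event = "impulse") {
  nT <- dim(data)[3]
  EpochSet(data, paste0("ch", seq_len(dim(data)[2])), fs,
           seq(startMs, by = 1000 / fs, length.out = nT), event)
}

# random symmetric positive-definite matrix
randomSPD <- function(d) {
  A <- matrix(rnorm(d * d), d)
  crossprod(A) + diag(d) * 0.1
}
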