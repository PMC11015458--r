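.defaultRunConfig <- function() {
  list(
    simulation = list(nParticipants = 4, nTrials = 256, seed = 1),
    analysis = list(
      window = c(100, 400), binMs = 10, folds = 8, reps = 10, seed = 1,
      timecourse = list(enabled = TRUE, widthMs = 100, fsOutVoltage = 100,
                        fsOutAlpha = 125, reps = 2),
      alphaBand = c(8, 12), nPerm = 1000, channels = "posterior"
    )
  )
}

# shallow-merge user config over defaults, per block
.mergeConfig <- function(user) {
  base <- .defaultRunConfig()
  for (blk in names(user)) {
    if (is.list(user[[blk]]) && is.list(base[[blk]]))
      base[[blk]] <- utils::modifyList(base[[blk]], user[[blk]])
    else base[[blk]] <- user[[blk]]
  }
  base
}

# load one participant from a directory with trials.csv and per-event stems
.loadParticipant <- function(dir, events = c("item1", "item2", "impulse")) {
  trials <- readTrials(file.path(dir, "trials.csv"))
  epochs <- lapply(events, function(ev) readEpochs(file.path(dir, ev)))
  names(epochs) <- events
  list(trials = trials, epochs = epochs)
}

#' Run the full analysis pipeline
#'
#' Executes simulation (or loads user data), preprocessing, window-of-interest
#' decoding (item 1 and item 2 at their presentations; cued and uncued at
#' impulse), optional voltage and alpha time-course decoding at impulse, RSA
#' at item and impulse epochs, the behavioral repulsion analysis, and the
#' group-level statistics, writing CSV/JSON outputs and a manifest with
#' content hashes and all seeds used.
#'
#' @param config a configuration list, or the path of a YAML file holding
#'   one. Recognized blocks: `simulation` (arguments of [simConfig()]) or
#'   `input` (`dir` containing one subdirectory per participant with
#'   `trials.csv` and per-event epoch files), and `analysis` (window, binMs,
#'   folds, reps, seed, timecourse settings, alphaBand, nPerm).
#' @param outDir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config = list(), outDir) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- .mergeConfig(config)
  an <- cfg$analysis
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  synthetic <- is.null(cfg$input)
  if (synthetic) {
    simCfg <- do.call(simConfig, cfg$simulation)
    nP <- simCfg@nParticipants
  } else {
    dirs <- sort(list.dirs(cfg$input$dir, recursive = FALSE))
    if (!length(dirs))
      stop("no participant directories under ", cfg$input$dir, call. = FALSE)
    nP <- length(dirs)
  }

  pSeeds <- .subSeeds(an$seed, nP)
  jobs <- list(item1 = c("item1", "item1_color"),
               item2 = c("item2", "item2_color"),
               cued = c("impulse", "cued_color"),
               uncued = c("impulse", "uncued_color"))
  acc <- matrix(NA_real_, nP, length(jobs),
                dimnames = list(NULL, names(jobs)))
  tcA <- list(cued = NULL, uncued = NULL)
  tcV <- list(cued = NULL, uncued = NULL)
  tcTimes <- NULL
  rdmsItem <- vector("list", nP)
  rdmsImpulse <- vector("list", nP)
  trialsList <- vector("list", nP)

  for (p in seq_len(nP)) {
    part <- if (synthetic)
      simulateParticipant(simCfg, p, events = c("item1", "item2", "impulse"))
    else .loadParticipant(dirs[p])
    trialsList[[p]] <- part$trials
    for (j in seq_along(jobs)) {
      ev <- jobs[[j]][1]; colcol <- jobs[[j]][2]
      pat <- windowPool(part$epochs[[ev]], an$window[1], an$window[2], an$binMs)
      acc[p, j] <- accuracy(decodeWindow(pat, part$trials[[colcol]],
                                         nFolds = an$folds, nReps = an$reps,
                                         seed = pSeeds[p],
                                         label = names(jobs)[j]))
    }
    patItem <- windowPool(part$epochs$item1, an$window[1], an$window[2], an$binMs)
    rdmsItem[[p]] <- computeRDM(patItem, part$trials$item1_color,
                                nReps = an$reps, seed = pSeeds[p])
    patImp <- windowPool(part$epochs$impulse, an$window[1], an$window[2], an$binMs)
    rdmsImpulse[[p]] <- computeRDM(patImp, part$trials$cued_color,
                                   nReps = an$reps, seed = pSeeds[p])
    if (isTRUE(an$timecourse$enabled)) {
      imp <- part$epochs$impulse
      impBl <- baselineEpochs(imp, max(-200, min(timesMs(imp))), 0)
      env <- alphaEnvelope(imp, an$alphaBand[1], an$alphaBand[2])
      envBl <- baselineEpochs(env, max(-200, min(timesMs(env))), 0)
      for (lab in c("cued", "uncued")) {
        colv <- part$trials[[paste0(lab, "_color")]]
        rv <- decodeTimecourse(impBl, colv, an$timecourse$widthMs,
                               an$timecourse$fsOutVoltage, an$folds,
                               an$timecourse$reps, pSeeds[p], label = lab)
        ra <- decodeTimecourse(envBl, colv, an$timecourse$widthMs,
                               an$timecourse$fsOutAlpha, an$folds,
                               an$timecourse$reps, pSeeds[p], label = lab)
        tcV[[lab]] <- rbind(tcV[[lab]], accuracy(rv))
        tcA[[lab]] <- rbind(tcA[[lab]], accuracy(ra))
        tcTimes <- list(voltage = timesMs(rv), alpha = timesMs(ra))
      }
    }
  }

  statSeed <- .subSeeds(an$seed + 1L, 1L)
  group <- list(
    decoding = lapply(seq_along(jobs), function(j)
      c(mean = mean(acc[, j]),
        p = signflipTest(acc[, j], "one_greater", an$nPerm, statSeed)$p)),
    cued_minus_uncued_p = pairedDifferenceTest(
      acc[, "cued"], acc[, "uncued"], "one_greater", an$nPerm, statSeed)$p
  )
  names(group$decoding) <- names(jobs)

  rsaItem <- fitModelsGroup(rdmsItem, nPerm = an$nPerm, seed = statSeed)
  rsaImpulse <- fitModelsGroup(rdmsImpulse, nPerm = an$nPerm, seed = statSeed)
  bias <- analyzeRepulsionBias(trialsList, nPerm = an$nPerm, seed = statSeed)

  # outputs
  files <- character()
  wr <- function(obj, name) {
    path <- file.path(outDir, name)
    utils::write.csv(obj, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }
  wr(data.frame(participant = seq_len(nP), acc), "accuracy.csv")
  wr(data.frame(participant = rep(seq_len(nP), 2),
                model = rep(colnames(rsaItem$betas), each = nP),
                beta_item = as.vector(rsaItem$betas),
                beta_impulse = as.vector(rsaImpulse$betas)), "rsa_betas.csv")
  wr(data.frame(center = bias$centers, mean = bias$groupMean), "bias_curve.csv")
  if (isTRUE(an$timecourse$enabled)) {
    for (lab in c("cued", "uncued")) {
      wr(data.frame(time_ms = tcTimes$voltage, t(tcV[[lab]])),
         sprintf("timecourse_voltage_%s.csv", lab))
      wr(data.frame(time_ms = tcTimes$alpha, t(tcA[[lab]])),
         sprintf("timecourse_alpha_%s.csv", lab))
    }
  }
  statsPath <- file.path(outDir, "group_stats.json")
  jsonlite::write_json(list(
    decoding = group, rsa_item = rsaItem[c("groupMean", "p")],
    rsa_impulse = rsaImpulse[c("groupMean", "p")],
    bias_clusters = bias$test$clusters), statsPath,
    auto_unbox = TRUE, digits = NA)
  files <- c(files, statsPath)

  manifest <- list(
    package = as.character(utils::packageVersion("impulseWM")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = list(analysis = an$seed, participants = pSeeds, stats = statSeed),
    synthetic = synthetic,
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files)))
  )
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
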