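#' Write a trial table to CSV
#'
#' Comma-separated, UTF-8, header row, degrees as decimal numbers.
#'
#' @param trials trial table data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTrials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

.TRIAL_COLS <- c("trial_id", "item1_color", "item2_color", "cue",
                 "cued_color", "uncued_color", "report_color")

#' Read a trial table from CSV
#'
#' @param path CSV file written by [writeTrials()] (or matching its schema).
#' @return trial table data.frame.
#' @export
readTrials <- function(path) {
  if (!file.exists(path))
    stop("trials CSV not found: ", path, call. = FALSE)
  tr <- utils::read.csv(path)
  missing <- setdiff(.TRIAL_COLS, names(tr))
  if (length(missing))
    stop("trials CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  tr
}

#' Write an EpochSet as a flat binary array plus JSON sidecar
#'
#' The data array is written little-endian in trial-major order (trials x
#' channels x time, R column order) to `<stem>.dat`; shape, channel names,
#' sampling rate, time axis, event and trial ids go to `<stem>.json`.
#'
#' @param epochs an [EpochSet-class].
#' @param stem output path stem (without extension).
#' @param dtype `"float32"` (portable default) or `"float64"` (lossless).
#' @return the sidecar path, invisibly.
#' @export
writeEpochs <- function(epochs, stem, dtype = c("float32", "float64")) {
  dtype <- match.arg(dtype)
  size <- if (dtype == "float32") 4L else 8L
  datPath <- paste0(stem, ".dat")
  con <- file(datPath, "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs@data), con, size = size, endian = "little")
  sidecar <- list(shape = dim(epochs@data), dtype = dtype,
                  order = "trials,channels,time",
                  channel_names = channelNames(epochs),
                  fs = samplingRate(epochs), times_ms = timesMs(epochs),
                  event = eventLabel(epochs), trial_ids = trialIds(epochs))
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(stem, ".json"))
}

#' Read an EpochSet written by [writeEpochs()]
#'
#' @param stem path stem (without extension).
#' @return an [EpochSet-class].
#' @export
readEpochs <- function(stem) {
  datPath <- paste0(stem, ".dat")
  sidePath <- paste0(stem, ".json")
  if (!file.exists(datPath) || !file.exists(sidePath))
    stop("epoch files not found at stem: ", stem, call. = FALSE)
  side <- jsonlite::read_json(sidePath, simplifyVector = TRUE)
  size <- if (identical(side$dtype, "float32")) 4L else 8L
  nVals <- prod(side$shape)
  con <- file(datPath, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = nVals, size = size, endian = "little")
  if (length(vals) != nVals)
    stop(sprintf("array file %s is truncated: expected %d values, got %d",
                 datPath, nVals, length(vals)), call. = FALSE)
  EpochSet(array(vals, side$shape), side$channel_names, side$fs,
           side$times_ms, side$event, as.integer(side$trial_ids))
}
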