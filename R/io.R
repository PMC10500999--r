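# Plain-text readers and writers for the exchange formats: trial tables
# as CSV, spike ensembles as CSV plus a JSON sidecar, LFP ensembles as
# wide CSV plus a JSON sidecar.

trialTableColumns <- c("trial_id", "task", "coherence", "cue_location",
                       "relation", "t_dur_s", "rt_s", "choice", "correct",
                       "rewarded")

#' Write / read a behavioural trial table
#'
#' CSV with the canonical header columns; missing values are empty fields.
#'
#' @param trials trial table (see [simulateChoices()]).
#' @param path file path.
#' @return `readTrialTable` returns the trial table data.frame.
#' @export
writeTrialTable <- function(trials, path) {
  for (cc in setdiff(trialTableColumns, names(trials))) trials[[cc]] <- NA
  write.csv(trials[, trialTableColumns], path, row.names = FALSE,
            na = "")
  invisible(path)
}

#' @rdname writeTrialTable
#' @export
readTrialTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("trial_id", "coherence", "choice"), names(df))
  if (length(missing))
    stop("trial table lacks required columns: ",
         paste(missing, collapse = ", "))
  df
}

#' Write / read a spike ensemble
#'
#' Long CSV of (trial_id, spike_time_s) plus a JSON sidecar
#' (`<path>.json`) carrying the alignment event, the window, and the full
#' trial id list so empty trials survive the round trip.
#'
#' @param spikes a [SpikeEnsemble-class] object.
#' @param path CSV file path.
#' @return `readSpikeEnsemble` returns the [SpikeEnsemble-class].
#' @export
writeSpikeEnsemble <- function(spikes, path) {
  stopifnot(is(spikes, "SpikeEnsemble"))
  df <- data.frame(
    trial_id = rep(spikes@trialId, lengths(spikes@spikes)),
    spike_time_s = unlist(spikes@spikes, use.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(alignEvent = spikes@alignEvent, window = spikes@window,
         trialId = spikes@trialId),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSpikeEnsemble
#' @export
readSpikeEnsemble <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  ids <- as.integer(meta$trialId)
  spk <- lapply(ids, function(i)
    sort(df$spike_time_s[df$trial_id == i]))
  spikeEnsemble(spk, trialId = ids, window = as.numeric(meta$window),
                alignEvent = meta$alignEvent)
}

#' Write / read an LFP ensemble
#'
#' Wide CSV (one row per sample, `time_s` column plus one column per
#' trial) with a JSON sidecar carrying the sampling rate and alignment
#' event; the event is at t = 0.
#'
#' @param lfp an [LfpEnsemble-class] object.
#' @param path CSV file path.
#' @return `readLfpEnsemble` returns the [LfpEnsemble-class].
#' @export
writeLfpEnsemble <- function(lfp, path) {
  stopifnot(is(lfp, "LfpEnsemble"))
  df <- data.frame(time_s = lfp@times)
  for (j in seq_len(ncol(lfp@data)))
    df[[paste0("trial_", j)]] <- lfp@data[, j]
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(samplingRate = lfp@samplingRate, alignEvent = lfp@alignEvent),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeLfpEnsemble
#' @export
readLfpEnsemble <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.csv(path)
  new("LfpEnsemble",
      data = as.matrix(df[, -1, drop = FALSE]), times = df$time_s,
      samplingRate = as.numeric(meta$samplingRate),
      alignEvent = meta$alignEvent)
}
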