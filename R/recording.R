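#' Multichannel electrophysiology recording
#'
#' A `recording` bundles fixed-rate time series from a chronically implanted
#' mouse — bilateral cortical EEG, a hippocampal CA1 depth LFP (in mV), and a
#' neck EMG — together with the sampling rate and animal metadata.
#'
#' @param channels named list of equal-length numeric vectors. The canonical
#'   channel names are `eeg_l`, `eeg_r`, `hlfp` (mV) and `emg` (a.u.); `hlfp`
#'   must be present for spike detection and spectral stages, `emg` for state
#'   segmentation.
#' @param fs sampling rate in Hz (positive scalar).
#' @param meta named list of animal metadata: `animal_id`, `genotype` (one of
#'   `"+/+"`, `"+/ls"`, `"+/-"`), `cre` (`"-"`/`"+"`), `tmx` (`"-"`/`"+"`),
#'   `phase` (`"I"`/`"II"`). Missing entries default to `NA`.
#' @return an object of class `recording`.
#' @export
recording <- function(channels, fs, meta = list()) {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stop("`channels` must be a named list of numeric vectors")
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("all channels must have equal length")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  defaults <- list(animal_id = NA_character_, genotype = NA_character_,
                   cre = NA_character_, tmx = NA_character_, phase = NA_character_)
  meta <- utils::modifyList(defaults, meta)
  structure(list(channels = lapply(channels, as.numeric), fs = fs, meta = meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              length(x$channels), n_samples(x), x$fs, duration(x)))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  m <- x$meta
  cat(sprintf("  animal %s  genotype %s  cre %s  tmx %s  phase %s\n",
              m$animal_id, m$genotype, m$cre, m$tmx, m$phase))
  invisible(x)
}

#' @rdname recording
#' @param x a `recording`.
#' @export
n_samples <- function(x) length(x$channels[[1]])

#' @rdname recording
#' @export
duration <- function(x) n_samples(x) / x$fs

#' Time axis of a recording (seconds, starting at 0)
#' @param rec a `recording`.
#' @keywords internal
rec_time <- function(rec) (seq_len(n_samples(rec)) - 1L) / rec$fs

has_channel <- function(rec, name) name %in% names(rec$channels)

#' Write / read a recording as columnar text plus a JSON sidecar
#'
#' The data file is a plain CSV with columns `t`, `eeg_l`, `eeg_r`, `hlfp_mV`,
#' `emg` (whichever channels exist); the sidecar `<path>.json` carries `fs` and
#' the animal metadata so a round trip preserves the object.
#'
#' @param rec a `recording`.
#' @param path CSV file path; the sidecar is written to `paste0(path, ".json")`.
#' @return `write_recording` returns `path` invisibly; `read_recording` a
#'   `recording`.
#' @export
write_recording <- function(rec, path) {
  cols <- list(t = rec_time(rec))
  nm_map <- c(eeg_l = "eeg_l", eeg_r = "eeg_r", hlfp = "hlfp_mV", emg = "emg")
  for (ch in names(rec$channels)) {
    out_nm <- if (ch %in% names(nm_map)) nm_map[[ch]] else ch
    cols[[out_nm]] <- rec$channels[[ch]]
  }
  utils::write.csv(as.data.frame(cols), path, row.names = FALSE)
  sidecar <- c(list(fs = rec$fs), rec$meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"))
  nm_map <- c(eeg_l = "eeg_l", eeg_r = "eeg_r", hlfp_mV = "hlfp", emg = "emg")
  chans <- list()
  for (nm in setdiff(names(df), "t")) {
    key <- if (nm %in% names(nm_map)) nm_map[[nm]] else nm
    chans[[key]] <- df[[nm]]
  }
  meta <- side[setdiff(names(side), "fs")]
  recording(chans, fs = as.numeric(side$fs), meta = meta)
}

#' Truncate a recording to its leading analysis window
#'
#' Spectral analyses focus on the first minutes of each session, when mice
#' explore most actively and theta is prominent. Returns the leading segment;
#' recordings shorter than the requested window are returned whole with a
#' warning.
#'
#' @param rec a `recording`.
#' @param minutes window length in minutes (default 10).
#' @return a `recording` covering `[0, minutes * 60]` seconds (or less).
#' @export
analysis_window <- function(rec, minutes = 10) {
  stopifnot(inherits(rec, "recording"))
  if (!is.numeric(minutes) || length(minutes) != 1L || minutes <= 0)
    stop("`minutes` must be a positive scalar")
  if (n_samples(rec) == 0L) stop("empty recording")
  n_keep <- min(n_samples(rec), round(minutes * 60 * rec$fs))
  if (n_keep == n_samples(rec) && duration(rec) < minutes * 60)
    warning(sprintf("recording is %.1f min, shorter than the %g-min window; using all of it",
                    duration(rec) / 60, minutes))
  recording(lapply(rec$channels, function(ch) ch[seq_len(n_keep)]),
            fs = rec$fs, meta = rec$meta)
}
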