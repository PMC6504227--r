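#' Segment a recording into wake and sleep from EMG quieting
#'
#' Sleep in chronic rodent recordings shows an abrupt quieting of the neck
#' EMG, optionally confirmed by immobility from video tracking. This routine
#' computes a sliding-window EMG RMS, takes an upper quantile (default 90th
#' percentile) of the windowed RMS over the whole recording as the wake
#' reference — unlike the median this survives recordings that are mostly
#' asleep, which rodents routinely are — and labels as sleep every
#' maximal run of samples whose RMS falls below `quiet_ratio` times that
#' reference, provided the run lasts at least `min_bout_s` (and, if an
#' immobility series is supplied, the animal is immobile throughout).
#' Everything else is wake. The output intervals tile the recording.
#'
#' @param rec a [recording()] with an `emg` channel.
#' @param emg_window_s RMS window length, seconds (default 1).
#' @param quiet_ratio sleep threshold as a fraction of the wake-reference
#'   RMS, in (0, 1) (default 0.5).
#' @param min_bout_s minimum sleep bout duration, seconds (default 10);
#'   shorter quiet bouts stay wake.
#' @param movement optional logical/numeric per-sample immobility series
#'   (`TRUE`/nonzero = moving); when given, sleep additionally requires no
#'   movement.
#' @param ref_quantile quantile of the windowed RMS used as the wake
#'   reference (default 0.9).
#' @return a [state_intervals()] tiling the recording.
#' @export
segment_states <- function(rec, emg_window_s = 1, quiet_ratio = 0.5,
                           min_bout_s = 10, movement = NULL,
                           ref_quantile = 0.9) {
  stopifnot(inherits(rec, "recording"))
  if (!has_channel(rec, "emg")) stop("recording has no EMG channel")
  if (!is.numeric(emg_window_s) || emg_window_s <= 0)
    stop("emg_window_s must be positive")
  if (!is.numeric(quiet_ratio) || quiet_ratio <= 0 || quiet_ratio >= 1)
    stop("quiet_ratio must lie in (0, 1)")
  emg <- rec$channels$emg
  n <- length(emg)
  if (stats::sd(emg) == 0)
    stop("degenerate input: EMG is constant; cannot infer states")
  w <- max(1L, round(emg_window_s * rec$fs))
  rms <- sqrt(running_mean(emg^2, w))
  ref <- stats::quantile(rms, ref_quantile, names = FALSE)
  quiet <- rms < quiet_ratio * ref
  if (!is.null(movement)) {
    if (length(movement) != n)
      stop("movement series must match the recording length")
    quiet <- quiet & !(as.logical(movement) %in% TRUE)
  }
  # duration gate: quiet runs shorter than min_bout_s revert to wake
  r <- rle(quiet)
  min_len <- round(min_bout_s * rec$fs)
  r$values[r$values & r$lengths < min_len] <- FALSE
  lab <- inverse.rle(r)
  r2 <- rle(lab)
  ends_i <- cumsum(r2$lengths)
  starts_i <- c(1L, utils::head(ends_i, -1) + 1L)
  state_intervals((starts_i - 1L) / rec$fs, ends_i / rec$fs,
                  ifelse(r2$values, "sleep", "wake"))
}

# centered running mean with edge shrinkage (partial windows at the borders)
running_mean <- function(x, w) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
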