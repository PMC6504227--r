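#' Detect high-amplitude interictal spikes by threshold crossing
#'
#' One event is logged per contiguous supra-threshold excursion of the
#' hippocampal depth channel, at the sample where the excursion peaks.
#' Excursions whose gap is shorter than `refractory_s` are merged into a
#' single event at the larger peak, so multiphasic waves are not
#' double-counted. Detection runs on the hLFP only; cortical EEG channels
#' are consulted later for artifact rejection.
#'
#' @param rec a [recording()] with an `hlfp` channel scaled in mV.
#' @param threshold_mV detection threshold, mV (default +1.0).
#' @param refractory_s minimum separation between events, seconds
#'   (default 0.2).
#' @return a `spike_events` data frame: `peak_time_s`, `peak_amp_mV`,
#'   `accepted` (all `TRUE` here), `reject_reason`.
#' @export
detect_spikes <- function(rec, threshold_mV = 1.0, refractory_s = 0.2) {
  stopifnot(inherits(rec, "recording"))
  if (!has_channel(rec, "hlfp")) stop("recording has no hLFP channel")
  if (!is.numeric(threshold_mV) || threshold_mV <= 0)
    stop("threshold_mV must be positive")
  x <- rec$channels$hlfp
  if (length(x) && max(abs(x)) < 0.01)
    warning("hLFP never exceeds 0.01 in magnitude; is it scaled in mV?")
  above <- x > threshold_mV
  ev <- spike_events(numeric(0), numeric(0))
  if (!any(above)) return(ev)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  run_start <- starts[r$values]; run_end <- ends[r$values]
  peak_i <- mapply(function(s, e) s - 1L + which.max(x[s:e]), run_start, run_end)
  peak_a <- x[peak_i]
  # merge runs separated by less than the refractory period, keep larger peak
  gap_s <- (run_start[-1] - run_end[-length(run_end)] - 1L) / rec$fs
  grp <- cumsum(c(TRUE, gap_s >= refractory_s))
  keep_i <- tapply(seq_along(peak_i), grp, function(ii) ii[which.max(peak_a[ii])])
  keep_i <- sort(unlist(keep_i, use.names = FALSE))
  spike_events((peak_i[keep_i] - 1L) / rec$fs, peak_a[keep_i])
}

#' @rdname detect_spikes
#' @param peak_time_s,peak_amp_mV event peak times (s) and amplitudes (mV).
#' @param accepted logical acceptance flags (default all `TRUE`).
#' @param reject_reason optional character reasons for rejected events.
#' @export
spike_events <- function(peak_time_s, peak_amp_mV,
                         accepted = rep(TRUE, length(peak_time_s)),
                         reject_reason = rep(NA_character_, length(peak_time_s))) {
  o <- order(peak_time_s)
  df <- data.frame(peak_time_s = peak_time_s[o], peak_amp_mV = peak_amp_mV[o],
                   accepted = accepted[o], reject_reason = reject_reason[o],
                   stringsAsFactors = FALSE)
  class(df) <- c("spike_events", "data.frame")
  df
}

#' Flag non-physiological artifacts among detected events
#'
#' Movement and electrical artifacts show unusually high amplitude with
#' time-locked peaks on several channels at once. An event is flagged
#' rejected when both hold: within `sync_window_s` of its peak at least
#' `sync_min_channels` other channels exceed the detection-scale threshold,
#' AND its own hLFP peak exceeds `amp_cap_mV`. Genuine interictal spikes that
#' generalize across channels but stay below the amplitude cap survive.
#' Nothing is deleted — events are only flagged, preserving the audit trail.
#'
#' @param events a `spike_events` from [detect_spikes()].
#' @param rec the source [recording()] (needs >= 2 EEG/LFP channels).
#' @param sync_window_s synchrony window, seconds (default 0.01).
#' @param sync_min_channels how many other channels must co-peak (default 2).
#' @param amp_cap_mV amplitude above which a synchronous event is deemed
#'   non-physiological (default 10).
#' @param channel_threshold_mV supra-threshold criterion applied to the other
#'   channels (default the detection threshold, 1.0).
#' @return the events with `accepted`/`reject_reason` updated.
#' @export
reject_artifacts <- function(events, rec, sync_window_s = 0.01,
                             sync_min_channels = 2, amp_cap_mV = 10,
                             channel_threshold_mV = 1.0) {
  stopifnot(inherits(events, "spike_events"), inherits(rec, "recording"))
  others <- setdiff(names(rec$channels), c("hlfp", "emg"))
  if (length(others) + 1L < 2L) stop("need >= 2 EEG/LFP channels")
  if (sync_min_channels > length(others))
    stop("sync_min_channels (", sync_min_channels, ") exceeds available other channels (",
         length(others), ")")
  n <- n_samples(rec)
  w <- max(1L, round(sync_window_s * rec$fs))
  for (k in seq_len(nrow(events))) {
    i <- round(events$peak_time_s[k] * rec$fs) + 1L
    lo <- max(1L, i - w); hi <- min(n, i + w)
    n_sync <- sum(vapply(others, function(ch) {
      any(abs(rec$channels[[ch]][lo:hi]) > channel_threshold_mV)
    }, logical(1)))
    if (n_sync >= sync_min_channels && events$peak_amp_mV[k] > amp_cap_mV) {
      events$accepted[k] <- FALSE
      events$reject_reason[k] <- sprintf(
        "synchronous on %d other channel(s) and peak %.1f mV > cap %.1f mV",
        n_sync, events$peak_amp_mV[k], amp_cap_mV)
    }
  }
  events
}

#' Interictal spike rates by vigilance state
#'
#' Assigns each accepted event to the state interval containing its peak and
#' reports events/min separately for wake and sleep. A state with zero total
#' time gets an `NA` rate flagged `undefined`, not a spurious zero.
#'
#' @param events a `spike_events`.
#' @param states a [state_intervals()] tiling the recording.
#' @return a `rate_by_state` list: `wake_rate`, `sleep_rate` (events/min),
#'   `wake_time_s`, `sleep_time_s`, `n_wake`, `n_sleep`, `undefined`
#'   (character vector of states with no time).
#' @export
spike_rate_by_state <- function(events, states) {
  stopifnot(inherits(events, "spike_events"), inherits(states, "state_intervals"))
  acc <- events[events$accepted, , drop = FALSE]
  lab <- state_at(states, acc$peak_time_s)
  if (anyNA(lab))
    stop("an accepted event lies outside the state intervals; states must tile the recording")
  out <- list(wake_time_s = state_time(states, "wake"),
              sleep_time_s = state_time(states, "sleep"),
              n_wake = sum(lab == "wake"), n_sleep = sum(lab == "sleep"),
              undefined = character(0))
  for (st in c("wake", "sleep")) {
    time_s <- out[[paste0(st, "_time_s")]]
    if (time_s > 0) {
      out[[paste0(st, "_rate")]] <- out[[paste0("n_", st)]] / (time_s / 60)
    } else {
      out[[paste0(st, "_rate")]] <- NA_real_
      out$undefined <- c(out$undefined, st)
    }
  }
  structure(out, class = "rate_by_state")
}

#' Fold change between two groups of rates
#'
#' Ratio of group mean rates (e.g. mutant wake rate over wild-type wake rate,
#' or sleep over wake within mutants). A zero denominator mean is replaced by
#' `pseudo_rate` and the result annotated, so an infinite fold never
#' propagates silently.
#'
#' @param group_a_rates,group_b_rates numeric rate vectors (events/min);
#'   the fold is `mean(a) / mean(b)`.
#' @param pseudo_rate substitute denominator when `mean(b)` is 0
#'   (default 0.01/min).
#' @return a list: `fold`, `mean_a`, `mean_b`, `pseudo_used` (logical).
#' @export
fold_change <- function(group_a_rates, group_b_rates, pseudo_rate = 0.01) {
  if (length(group_a_rates) == 0 || length(group_b_rates) == 0)
    stop("empty group")
  ma <- mean(group_a_rates, na.rm = TRUE)
  mb <- mean(group_b_rates, na.rm = TRUE)
  pseudo <- mb == 0
  denom <- if (pseudo) pseudo_rate else mb
  list(fold = ma / denom, mean_a = ma, mean_b = mb, pseudo_used = pseudo)
}

#' Export spike events with state labels as CSV
#' @param events a `spike_events`.
#' @param states optional [state_intervals()] used to label each event.
#' @param path output CSV.
#' @export
write_spike_events <- function(events, path, states = NULL) {
  df <- as.data.frame(events)
  df$state <- if (is.null(states)) NA_character_ else state_at(states, df$peak_time_s)
  utils::write.csv(df[, c("peak_time_s", "peak_amp_mV", "state", "accepted",
                          "reject_reason")], path, row.names = FALSE)
  invisible(path)
}
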