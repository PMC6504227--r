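#' Labeled wake/sleep intervals
#'
#' `state_intervals` holds disjoint, sorted intervals labeled `wake` or
#' `sleep` that tile a recording. Adjacent intervals with the same state are
#' merged on construction.
#'
#' @param start_s,end_s numeric vectors of interval bounds (seconds).
#' @param state character vector, each `"wake"` or `"sleep"`.
#' @return a `state_intervals` data frame with columns `start_s`, `end_s`,
#'   `state`.
#' @export
state_intervals <- function(start_s, end_s, state) {
  if (length(start_s) != length(end_s) || length(start_s) != length(state))
    stop("start_s, end_s and state must have equal length")
  if (length(start_s) == 0L) stop("state_intervals cannot be empty")
  if (!all(state %in% c("wake", "sleep")))
    stop("state must be 'wake' or 'sleep'")
  o <- order(start_s)
  start_s <- start_s[o]; end_s <- end_s[o]; state <- as.character(state)[o]
  if (any(end_s <= start_s)) stop("zero- or negative-length interval")
  if (any(abs(start_s[-1] - end_s[-length(end_s)]) > 1e-9))
    stop("intervals must be contiguous (tile the recording)")
  # merge same-state neighbours
  keep <- c(TRUE, state[-1] != state[-length(state)])
  grp <- cumsum(keep)
  df <- data.frame(
    start_s = tapply(start_s, grp, min),
    end_s   = tapply(end_s, grp, max),
    state   = state[keep],
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(df) <- c("state_intervals", "data.frame")
  df
}

#' Total time spent in a state
#' @param states a `state_intervals`.
#' @param state `"wake"` or `"sleep"`.
#' @return seconds (0 if the state never occurs).
#' @export
state_time <- function(states, state) {
  sel <- states$state == state
  sum(states$end_s[sel] - states$start_s[sel])
}

#' State label at given times
#' @param states a `state_intervals`.
#' @param times_s numeric vector of times (seconds).
#' @return character vector of labels; `NA` outside the tiled range.
#' @export
state_at <- function(states, times_s) {
  idx <- findInterval(times_s, states$start_s)
  lab <- rep(NA_character_, length(times_s))
  ok <- idx >= 1L & times_s <= states$end_s[pmax(idx, 1L)] + 1e-12
  lab[ok] <- states$state[idx[ok]]
  lab
}

#' Serialize state intervals as BED-like text
#'
#' Three tab-separated columns (`start_s`, `end_s`, `state`), no header —
#' an audit-friendly plain-text record of the segmentation.
#'
#' @param states a `state_intervals`.
#' @param path output file.
#' @return `write_state_intervals` returns `path` invisibly;
#'   `read_state_intervals` a `state_intervals`.
#' @export
write_state_intervals <- function(states, path) {
  utils::write.table(as.data.frame(states)[, c("start_s", "end_s", "state")],
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_state_intervals
#' @export
read_state_intervals <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("start_s", "end_s", "state"),
                          stringsAsFactors = FALSE)
  state_intervals(df$start_s, df$end_s, df$state)
}
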