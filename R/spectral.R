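#' Logarithmically spaced analysis frequencies
#'
#' The standard grid for broad-band hippocampal rhythm analysis: `n`
#' frequencies log-spaced over `[lo, hi]` Hz (default 50 over 1-100 Hz).
#'
#' @param n number of frequencies.
#' @param lo,hi band edges in Hz.
#' @return numeric vector of length `n`, strictly increasing.
#' @export
log_freqs <- function(n = 50, lo = 1, hi = 100) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Frequency-band definitions
#'
#' @param theta,delta `(low, high)` band edges in Hz. Defaults: theta 6-12,
#'   delta 1-4. Bands must not overlap and must lie inside the 1-100 Hz
#'   analysis range.
#' @return a `band_defs` list.
#' @export
band_defs <- function(theta = c(6, 12), delta = c(1, 4)) {
  stopifnot(length(theta) == 2, length(delta) == 2)
  if (max(delta) > min(theta) && max(theta) > min(delta))
    stop("theta and delta bands must not overlap")
  if (min(theta, delta) < 1 || max(theta, delta) > 100)
    stop("bands must lie within [1, 100] Hz")
  structure(list(theta = as.numeric(theta), delta = as.numeric(delta)),
            class = "band_defs")
}

# complex Morlet wavelet at frequency f: Gaussian envelope of n_cycles periods
# (sigma_t = n_cycles / (2 pi f)), truncated at +/- 4 sigma_t
morlet_wavelet <- function(f, fs, n_cycles, normalization) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(4 * sigma_t * fs)
  t <- (-half:half) / fs
  env <- exp(-t^2 / (2 * sigma_t^2))
  w <- env * exp(2i * pi * f * t)
  dt <- 1 / fs
  scale <- switch(normalization,
                  unit_area   = 1 / (sum(env) * dt),
                  unit_energy = 1 / sqrt(sum(env^2) * dt))
  list(w = w * scale * dt, half = half)  # dt folded in: conv approximates the integral
}

#' Time-resolved Morlet amplitude spectrum
#'
#' Convolves a trace with complex Morlet wavelets (Gaussian-windowed complex
#' sinusoids of `n_cycles` periods, `sigma_t = n_cycles / (2 pi f)`) at each
#' analysis frequency and returns the modulus. With the default `unit_area`
#' normalization the wavelet's magnitude envelope integrates to one, so a
#' unit-amplitude sinusoid yields amplitude 0.5 at its own frequency
#' independent of that frequency; `unit_energy` (L2) normalization is
#' available as an alternative convention. Convolution uses reflect padding;
#' samples within one wavelet half-support (4 sigma_t) of either boundary are
#' recorded per frequency in `edge` and treated as unreliable by downstream
#' averaging.
#'
#' @param trace numeric vector (typically the CA1 LFP, mV); must be finite.
#' @param fs sampling rate, Hz; must be at least `2 * max(freqs)`.
#' @param freqs analysis frequencies, Hz (default [log_freqs()]).
#' @param n_cycles wavelet width in periods (default 6).
#' @param normalization `"unit_area"` (default) or `"unit_energy"`.
#' @return an `amplitude_spectrum`: list with `freqs_hz`, `amp`
#'   (frequency x time matrix, >= 0), `fs`, `edge` (per-frequency unreliable
#'   samples per side), `n_cycles`, `normalization`.
#' @export
morlet_amplitude <- function(trace, fs, freqs = log_freqs(), n_cycles = 6,
                             normalization = c("unit_area", "unit_energy")) {
  normalization <- match.arg(normalization)
  if (!all(is.finite(trace))) stop("trace must be finite")
  if (any(diff(freqs) <= 0)) stop("freqs must be strictly increasing")
  if (fs < 2 * max(freqs))
    stop("fs = ", fs, " Hz is below Nyquist for max frequency ", max(freqs), " Hz")
  n <- length(trace)
  if (n == 0) stop("empty trace")
  amp <- matrix(0, length(freqs), n)
  edge <- integer(length(freqs))
  for (k in seq_along(freqs)) {
    mw <- morlet_wavelet(freqs[k], fs, n_cycles, normalization)
    half <- mw$half
    pad <- min(half, n - 1L)
    # reflect padding (no sample duplication at the joint)
    xp <- c(trace[pad:1 + 1L], trace, trace[n - seq_len(pad)])
    L <- length(xp) + length(mw$w) - 1L
    nfft <- stats::nextn(L, 2)
    X <- stats::fft(c(xp, rep(0, nfft - length(xp))))
    W <- stats::fft(c(mw$w, rep(0 + 0i, nfft - length(mw$w))))
    conv <- stats::fft(X * W, inverse = TRUE) / nfft
    centre <- pad + half + seq_len(n)   # aligned: wavelet centre over sample i
    amp[k, ] <- Mod(conv[centre])
    edge[k] <- min(half, n)
  }
  structure(list(freqs_hz = freqs, amp = amp, fs = fs, edge = edge,
                 n_cycles = n_cycles, normalization = normalization),
            class = "amplitude_spectrum")
}

band_rows <- function(spec, band) {
  rows <- which(spec$freqs_hz >= band[1] & spec$freqs_hz <= band[2])
  if (!length(rows))
    stop("band [", band[1], ", ", band[2], "] Hz contains no analysis frequency")
  rows
}

#' Theta/delta power ratio over time
#'
#' Per-sample band power is the mean squared wavelet amplitude over the
#' band's frequency rows; the ratio theta/delta is smoothed with a centered
#' moving average of `smooth_s`. Samples where delta power is zero are
#' flagged (`Inf` ratio) and excluded from representative-window selection;
#' so are samples inside the widest band-member wavelet's edge region.
#'
#' @param spec an [morlet_amplitude()] spectrum covering both bands.
#' @param bands a [band_defs()].
#' @param smooth_s moving-average window, seconds (default 1).
#' @return a `ratio_series`: list with `t` (s), `ratio` (smoothed), `fs`,
#'   `flagged` (logical; `TRUE` = unusable sample).
#' @export
theta_delta_ratio <- function(spec, bands = band_defs(), smooth_s = 1.0) {
  stopifnot(inherits(spec, "amplitude_spectrum"))
  th <- band_rows(spec, bands$theta)
  de <- band_rows(spec, bands$delta)
  p_th <- colMeans(spec$amp[th, , drop = FALSE]^2)
  p_de <- colMeans(spec$amp[de, , drop = FALSE]^2)
  n <- ncol(spec$amp)
  zero_de <- p_de == 0
  ratio <- ifelse(zero_de, Inf, p_th / p_de)
  w <- max(1L, round(smooth_s * spec$fs))
  sm <- running_mean(ifelse(is.finite(ratio), ratio, 0), w)
  sm[!is.finite(ratio)] <- Inf
  e <- max(spec$edge[c(th, de)])
  flagged <- zero_de
  if (e > 0 && e < n) {
    flagged[seq_len(e)] <- TRUE
    flagged[(n - e + 1L):n] <- TRUE
  } else if (e >= n) flagged[] <- TRUE
  structure(list(t = (seq_len(n) - 1L) / spec$fs, ratio = sm, fs = spec$fs,
                 flagged = flagged),
            class = "ratio_series")
}

#' Select the window with the highest theta/delta ratio
#'
#' Scans all windows of `window_s` and returns the one maximizing the mean
#' smoothed ratio, ignoring windows that contain any flagged sample; ties are
#' broken toward the earliest start.
#'
#' @param ratio a `ratio_series` from [theta_delta_ratio()].
#' @param window_s window length, seconds (default 1).
#' @return `c(start_s, end_s)` of the winning window.
#' @export
select_representative_window <- function(ratio, window_s = 1.0) {
  stopifnot(inherits(ratio, "ratio_series"))
  n <- length(ratio$ratio)
  w <- round(window_s * ratio$fs)
  if (w < 1 || w > n) stop("window longer than the series")
  ok <- !ratio$flagged & is.finite(ratio$ratio)
  x <- ifelse(ok, ratio$ratio, 0)
  cs <- cumsum(c(0, x))
  means <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  bad <- cumsum(c(0, !ok))
  usable <- (bad[(w + 1):(n + 1)] - bad[1:(n - w + 1)]) == 0
  if (!any(usable)) stop("no usable window: all samples flagged")
  means[!usable] <- -Inf
  i <- which.max(means)  # which.max returns the first maximum: earliest start
  c(start_s = (i - 1L) / ratio$fs, end_s = (i - 1L + w) / ratio$fs)
}

# time-averaged amplitude per frequency over reliable (non-edge) samples
time_avg_amp <- function(spec) {
  n <- ncol(spec$amp)
  vapply(seq_along(spec$freqs_hz), function(k) {
    e <- spec$edge[k]
    cols <- if (2 * e >= n) seq_len(n) else (e + 1L):(n - e)
    mean(spec$amp[k, cols])
  }, numeric(1))
}

#' Within-subject normalized amplitude change between phases
#'
#' For each animal, each phase's amplitude is the per-frequency time average
#' over reliable samples, averaged across that phase's sessions; the change
#' is `(phase2 - phase1) / phase1` — a +0.4 means a 40% amplitude increase
#' after the intervention. The grand mean averages animals per frequency.
#' Animals missing either phase are excluded with a warning.
#'
#' @param phase1,phase2 named lists, one entry per animal: either a single
#'   [morlet_amplitude()] spectrum or a list of session spectra.
#' @return an `amplitude_change`: list with `freqs_hz`, `per_animal`
#'   (animal x frequency matrix), `grand_mean`, `ci_low`/`ci_high` (`NULL`
#'   until [bootstrap_ci()]), `animals`.
#' @export
normalized_amplitude_change <- function(phase1, phase2) {
  as_sessions <- function(x) if (inherits(x, "amplitude_spectrum")) list(x) else x
  common <- intersect(names(phase1), names(phase2))
  missing <- setdiff(union(names(phase1), names(phase2)), common)
  if (length(missing))
    warning("excluding animal(s) missing a phase: ", paste(missing, collapse = ", "))
  if (!length(common)) stop("no animal has both phases")
  freqs <- as_sessions(phase1[[common[1]]])[[1]]$freqs_hz
  per_animal <- t(vapply(common, function(id) {
    m1 <- rowMeans(vapply(as_sessions(phase1[[id]]), time_avg_amp,
                          numeric(length(freqs))))
    m2 <- rowMeans(vapply(as_sessions(phase2[[id]]), time_avg_amp,
                          numeric(length(freqs))))
    (m2 - m1) / m1
  }, numeric(length(freqs))))
  structure(list(freqs_hz = freqs, per_animal = per_animal,
                 grand_mean = colMeans(per_animal),
                 ci_low = NULL, ci_high = NULL, animals = common),
            class = "amplitude_change")
}

#' Bootstrap confidence band for the grand-mean amplitude change
#'
#' Resamples animals with replacement `n_boot` times and fills per-frequency
#' percentile intervals. With a single animal the interval degenerates to the
#' point value and is flagged in `ci_note`.
#'
#' @param change an [normalized_amplitude_change()] result.
#' @param n_boot bootstrap replicates (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; the interval is deterministic given it.
#' @return the `amplitude_change` with `ci_low`/`ci_high` filled.
#' @export
bootstrap_ci <- function(change, n_boot = 2000, level = 0.95, seed = 1L) {
  stopifnot(inherits(change, "amplitude_change"))
  m <- change$per_animal
  n <- nrow(m)
  if (n < 1) stop("no animals")
  if (n == 1) {
    change$ci_low <- change$ci_high <- change$grand_mean
    change$ci_note <- "single animal: degenerate CI equal to the point value"
    return(change)
  }
  set.seed(seed)
  boots <- matrix(0, n_boot, ncol(m))
  for (b in seq_len(n_boot))
    boots[b, ] <- colMeans(m[sample.int(n, n, replace = TRUE), , drop = FALSE])
  a <- (1 - level) / 2
  change$ci_low <- apply(boots, 2, stats::quantile, probs = a, names = FALSE)
  change$ci_high <- apply(boots, 2, stats::quantile, probs = 1 - a, names = FALSE)
  change
}

#' Sign-flip permutation test on a frequency band
#'
#' Tests whether the band-averaged within-subject amplitude change differs
#' from zero. The statistic is the mean over animals of each animal's
#' band-averaged normalized change; the null exchanges each animal's phase
#' labels independently, which for a within-subject change is a sign flip.
#' When all `2^n` sign patterns fit inside `n_shuffles` the test enumerates
#' them exactly; otherwise it samples `n_shuffles` patterns and applies the
#' add-one correction `p = (1 + #{|null| >= |obs|}) / (n_shuffles + 1)`.
#' Two-sided throughout.
#'
#' @param change an [normalized_amplitude_change()] result.
#' @param band `(low, high)` Hz (default the 6-12 Hz theta band).
#' @param n_shuffles permutation count (default 5000).
#' @param seed integer seed (sampling mode only).
#' @return a list: `p`, `observed` (band-mean change), `mode`
#'   (`"exhaustive"`/`"sampled"`), `n_shuffles` actually used.
#' @export
band_permutation_test <- function(change, band = c(6, 12), n_shuffles = 5000,
                                  seed = 1L) {
  stopifnot(inherits(change, "amplitude_change"))
  rows <- which(change$freqs_hz >= band[1] & change$freqs_hz <= band[2])
  if (!length(rows))
    stop("band [", band[1], ", ", band[2], "] Hz is outside the spectrum")
  x <- rowMeans(change$per_animal[, rows, drop = FALSE])
  n <- length(x)
  if (n < 2) stop("need >= 2 animals")
  obs <- mean(x)
  tol <- 1e-12 * max(1, abs(obs))
  if (2^n <= n_shuffles) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null <- as.vector(signs %*% x) / n
    p <- mean(abs(null) >= abs(obs) - tol)
    list(p = p, observed = obs, mode = "exhaustive", n_shuffles = 2^n)
  } else {
    set.seed(seed)
    null <- replicate(n_shuffles, mean(sample(c(-1, 1), n, replace = TRUE) * x))
    p <- (1 + sum(abs(null) >= abs(obs) - tol)) / (n_shuffles + 1)
    list(p = p, observed = obs, mode = "sampled", n_shuffles = n_shuffles)
  }
}

#' Export an amplitude spectrum as a CSV matrix
#' @param spec an `amplitude_spectrum`.
#' @param path output CSV (rows = frequencies, first column `freq_hz`).
#' @export
write_amplitude_spectrum <- function(spec, path) {
  df <- data.frame(freq_hz = spec$freqs_hz, spec$amp, check.names = FALSE)
  names(df)[-1] <- sprintf("s%d", seq_len(ncol(spec$amp)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
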