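#' Parameters for a synthetic EEG/LFP recording
#'
#' The generator emulates the statistical structure the downstream analyses
#' assume: interictal spikes as state-dependent Poisson trains of biphasic
#' transients, a CA1 LFP carrying theta (8 Hz) and delta (2.5 Hz) sinusoids on
#' a 1/f background, and an EMG whose RMS switches abruptly between wake and
#' sleep levels. All randomness flows from a single seed with per-component
#' sub-streams.
#'
#' Default spike rates encode the fold relations of the modeled disease state
#' (mutant wake rate 50x the wild-type wake rate of 0.01/min; mutant sleep
#' rate 18x its wake rate); absolute rates are free parameters of the stated
#' world, not measured quantities.
#'
#' @param duration_s recording length in seconds.
#' @param fs sampling rate, Hz; must exceed 200 Hz so the 1-100 Hz analysis
#'   range is below Nyquist.
#' @param spike_rate_wake,spike_rate_sleep interictal spike rates, events/min.
#' @param spike_amp_mV peak amplitude of inserted spikes on the hLFP channel.
#' @param spike_width_ms width of the positive transient (approximately the
#'   full width of its Gaussian envelope).
#' @param theta_amp,delta_amp amplitudes (mV) of the 8 Hz theta and 2.5 Hz
#'   delta components of the hLFP.
#' @param noise_exponent slope of the 1/f^a background power spectrum.
#' @param sleep_fraction target fraction of time asleep, in \[0, 1\].
#' @param sleep_bout_s mean sleep bout duration (exponential), seconds.
#' @param emg_wake_rms,emg_sleep_rms EMG RMS in each state (a.u.).
#' @param seed integer seed.
#' @return a validated `sim_recording_params` list.
#' @export
sim_recording_params <- function(duration_s = 600, fs = 2000,
                                 spike_rate_wake = 0.5, spike_rate_sleep = 9,
                                 spike_amp_mV = 2, spike_width_ms = 25,
                                 theta_amp = 0.2, delta_amp = 0.2,
                                 noise_exponent = 1,
                                 sleep_fraction = 0.3, sleep_bout_s = 60,
                                 emg_wake_rms = 1, emg_sleep_rms = 0.1,
                                 seed = 1L) {
  p <- list(duration_s = duration_s, fs = fs,
            spike_rate_wake = spike_rate_wake,
            spike_rate_sleep = spike_rate_sleep,
            spike_amp_mV = spike_amp_mV, spike_width_ms = spike_width_ms,
            theta_amp = theta_amp, delta_amp = delta_amp,
            noise_exponent = noise_exponent,
            sleep_fraction = sleep_fraction, sleep_bout_s = sleep_bout_s,
            emg_wake_rms = emg_wake_rms, emg_sleep_rms = emg_sleep_rms,
            seed = as.integer(seed))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(p$duration_s) || p$duration_s <= 0)
    stop("invalid parameters: duration_s must be a positive scalar")
  if (!num1(p$fs) || p$fs <= 200)
    stop("invalid parameters: fs must exceed 200 Hz (Nyquist for 1-100 Hz analysis)")
  if (!num1(p$spike_rate_wake) || p$spike_rate_wake < 0 ||
      !num1(p$spike_rate_sleep) || p$spike_rate_sleep < 0)
    stop("invalid parameters: spike rates must be >= 0")
  if (!num1(p$sleep_fraction) || p$sleep_fraction < 0 || p$sleep_fraction > 1)
    stop("invalid parameters: sleep_fraction must lie in [0, 1]")
  if (!num1(p$sleep_bout_s) || p$sleep_bout_s <= 0)
    stop("invalid parameters: sleep_bout_s must be positive")
  if (!num1(p$spike_width_ms) || p$spike_width_ms <= 0)
    stop("invalid parameters: spike_width_ms must be positive")
  if (!num1(p$emg_wake_rms) || p$emg_wake_rms <= 0 ||
      !num1(p$emg_sleep_rms) || p$emg_sleep_rms <= 0)
    stop("invalid parameters: EMG RMS levels must be positive")
  class(p) <- "sim_recording_params"
  p
}

# 1/f^a noise of unit RMS via spectral shaping of white Gaussian noise
shaped_noise <- function(n, exponent) {
  w <- stats::rnorm(n)
  if (exponent == 0) return(w / stats::sd(w))
  X <- stats::fft(w)
  # two-sided frequency index; DC zeroed, shaping |H(f)| = f^(-a/2)
  k <- c(0, seq_len(n - 1))
  k <- pmin(k, n - k)
  h <- c(0, k[-1]^(-exponent / 2))
  x <- Re(stats::fft(X * h, inverse = TRUE)) / n
  x / stats::sd(x)
}

# alternating exponential wake/sleep bouts hitting the target sleep fraction
draw_states <- function(duration_s, sleep_fraction, sleep_bout_s) {
  if (sleep_fraction == 0)
    return(state_intervals(0, duration_s, "wake"))
  if (sleep_fraction == 1)
    return(state_intervals(0, duration_s, "sleep"))
  wake_bout_s <- sleep_bout_s * (1 - sleep_fraction) / sleep_fraction
  starts <- c(); ends <- c(); labels <- c()
  t <- 0; st <- "wake"
  while (t < duration_s) {
    mean_len <- if (st == "wake") wake_bout_s else sleep_bout_s
    len <- stats::rexp(1, rate = 1 / mean_len)
    len <- max(len, 1 / 1000)  # avoid zero-length intervals
    e <- min(t + len, duration_s)
    starts <- c(starts, t); ends <- c(ends, e); labels <- c(labels, st)
    t <- e
    st <- if (st == "wake") "sleep" else "wake"
  }
  state_intervals(starts, ends, labels)
}

# biphasic spike template: positive Gaussian peak, slow negative after-wave
spike_template <- function(fs, width_ms) {
  sd_s <- width_ms / 1000 / 4
  half <- ceiling(8 * sd_s * fs)
  t <- (-half:(3 * half)) / fs
  pos <- exp(-t^2 / (2 * sd_s^2))
  after <- -0.3 * exp(-(t - 5 * sd_s)^2 / (2 * (3 * sd_s)^2))
  list(offsets = -half:(3 * half), wave = pos + after)
}

add_spikes <- function(x, fs, times_s, template, scale) {
  n <- length(x)
  for (tt in times_s) {
    idx <- round(tt * fs) + 1L + template$offsets
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + scale * template$wave[ok]
  }
  x
}

#' Simulate a four-channel recording with ground truth
#'
#' Generates `eeg_l`, `eeg_r`, `hlfp` and `emg` channels per
#' [sim_recording_params()]: spikes are Poisson within each vigilance state at
#' that state's rate and inserted on all EEG/LFP channels (full amplitude on
#' the hLFP, attenuated on cortical EEG, mimicking events that generalize
#' across channels); the hLFP carries theta and delta sinusoids plus 1/f
#' background; the EMG is white noise whose RMS switches at state boundaries.
#' Output is bit-identical for identical seed and parameters.
#'
#' @param params a [sim_recording_params()].
#' @param meta optional metadata list passed to [recording()].
#' @return a `sim_recording`: list with elements `recording`,
#'   `true_spike_times` (s), `true_states` ([state_intervals()]) and
#'   `true_theta_amp`.
#' @export
simulate_recording <- function(params, meta = list()) {
  if (!inherits(params, "sim_recording_params"))
    params <- do.call(sim_recording_params, params)
  p <- params
  n <- round(p$duration_s * p$fs)
  set.seed(p$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 8)  # per-component sub-streams

  set.seed(sub[1])
  states <- draw_states(p$duration_s, p$sleep_fraction, p$sleep_bout_s)

  set.seed(sub[2])
  spike_times <- numeric(0)
  for (i in seq_len(nrow(states))) {
    rate_min <- if (states$state[i] == "wake") p$spike_rate_wake else p$spike_rate_sleep
    len <- states$end_s[i] - states$start_s[i]
    k <- stats::rpois(1, rate_min * len / 60)
    if (k > 0)
      spike_times <- c(spike_times, stats::runif(k, states$start_s[i], states$end_s[i]))
  }
  spike_times <- sort(spike_times)

  t <- (seq_len(n) - 1L) / p$fs
  theta <- p$theta_amp * sin(2 * pi * 8 * t)
  delta <- p$delta_amp * sin(2 * pi * 2.5 * t + pi / 3)

  set.seed(sub[3]); hlfp <- 0.1 * shaped_noise(n, p$noise_exponent) + theta + delta
  set.seed(sub[4]); eeg_l <- 0.05 * shaped_noise(n, p$noise_exponent)
  set.seed(sub[5]); eeg_r <- 0.05 * shaped_noise(n, p$noise_exponent)

  tpl <- spike_template(p$fs, p$spike_width_ms)
  hlfp  <- add_spikes(hlfp, p$fs, spike_times, tpl, p$spike_amp_mV)
  eeg_l <- add_spikes(eeg_l, p$fs, spike_times, tpl, 0.6 * p$spike_amp_mV)
  eeg_r <- add_spikes(eeg_r, p$fs, spike_times, tpl, 0.55 * p$spike_amp_mV)

  set.seed(sub[6])
  emg_rms <- rep(p$emg_wake_rms, n)
  lab <- state_at(states, t)
  emg_rms[lab == "sleep"] <- p$emg_sleep_rms
  emg <- stats::rnorm(n) * emg_rms

  rec <- recording(list(eeg_l = eeg_l, eeg_r = eeg_r, hlfp = hlfp, emg = emg),
                   fs = p$fs, meta = meta)
  structure(list(recording = rec, true_spike_times = spike_times,
                 true_states = states, true_theta_amp = p$theta_amp,
                 params = p),
            class = "sim_recording")
}

#' Parameters for a synthetic behavioral cohort
#'
#' @param n_per_group animals per (genotype x Cre x TMX) cell; at least 2.
#' @param cells data frame with columns `genotype`, `cre`, `tmx`, `endpoint`,
#'   `mean`, `sd` — one row per cell x endpoint (stage latencies in seconds,
#'   activity suppression ratios as proportions).
#' @param seed integer seed.
#' @return a validated `sim_cohort_params` list.
#' @export
sim_cohort_params <- function(n_per_group, cells, seed = 1L) {
  req <- c("genotype", "cre", "tmx", "endpoint", "mean", "sd")
  if (!is.data.frame(cells) || !all(req %in% names(cells)))
    stop("`cells` must be a data frame with columns ", paste(req, collapse = ", "))
  if (!is.numeric(n_per_group) || n_per_group < 2)
    stop("n_per_group must be >= 2")
  if (any(cells$sd <= 0)) stop("all cell sds must be positive")
  structure(list(n_per_group = as.integer(n_per_group), cells = cells,
                 seed = as.integer(seed)),
            class = "sim_cohort_params")
}

#' Simulate a flurothyl seizure-latency cohort
#'
#' Latencies to the three progressive seizure stages — first myoclonic jerk
#' (`clonus`), generalized tonic/clonic seizure (`tc`) and total hind-limb
#' extension (`the`) — are Gaussian per cell, truncated at zero, and enforced
#' monotone increasing within an animal (clonus <= tc <= the) by resampling.
#'
#' @param params a [sim_cohort_params()] whose `cells` contain endpoints
#'   `clonus`, `tc` and `the` for every (genotype, cre, tmx) cell.
#' @param max_retries resampling attempts per animal before giving up.
#' @return a [cohort_table()] with one row per animal x endpoint.
#' @export
simulate_seizure_cohort <- function(params, max_retries = 1000L) {
  stopifnot(inherits(params, "sim_cohort_params"))
  cells <- params$cells
  stages <- c("clonus", "tc", "the")
  if (!all(stages %in% unique(cells$endpoint)))
    stop("cells must define endpoints 'clonus', 'tc' and 'the'")
  set.seed(params$seed)
  groups <- unique(cells[, c("genotype", "cre", "tmx")])
  rows <- list(); aid <- 0L
  for (g in seq_len(nrow(groups))) {
    sel <- cells$genotype == groups$genotype[g] & cells$cre == groups$cre[g] &
      cells$tmx == groups$tmx[g]
    mu <- stats::setNames(cells$mean[sel], cells$endpoint[sel])[stages]
    sd <- stats::setNames(cells$sd[sel], cells$endpoint[sel])[stages]
    if (anyNA(mu) || anyNA(sd))
      stop("cell (", groups$genotype[g], ",", groups$cre[g], ",", groups$tmx[g],
           ") is missing a stage endpoint")
    for (a in seq_len(params$n_per_group)) {
      aid <- aid + 1L
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        v <- stats::rnorm(3, mu, sd)
        if (all(v > 0) && v[1] <= v[2] && v[2] <= v[3]) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not generate monotone positive latencies for cell (",
             groups$genotype[g], ",", groups$cre[g], ",", groups$tmx[g],
             ") after ", max_retries, " retries")
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = sprintf("m%03d", aid), genotype = groups$genotype[g],
        cre = groups$cre[g], tmx = groups$tmx[g],
        endpoint = stages, value = v, stringsAsFactors = FALSE)
    }
  }
  cohort_table(do.call(rbind, rows))
}

#' Simulate a contextual-fear cohort scored by activity suppression
#'
#' For each animal a training activity (0-2 min distance, cm) is drawn
#' log-normally around 300 cm, a target suppression ratio is drawn Gaussian
#' around the cell mean (truncated to (0, 1)), and the test activity is set so
#' that `test / (train + test)` equals that ratio exactly. The returned table
#' carries `train_activity`, `test_activity` and the implied `asr` endpoint.
#'
#' @param params a [sim_cohort_params()] whose `cells` contain an `asr`
#'   endpoint with means strictly inside (0, 1).
#' @return a [cohort_table()].
#' @export
simulate_fear_cohort <- function(params) {
  stopifnot(inherits(params, "sim_cohort_params"))
  cells <- params$cells[params$cells$endpoint == "asr", , drop = FALSE]
  if (nrow(cells) == 0) stop("cells must define an 'asr' endpoint")
  if (any(cells$mean <= 0 | cells$mean >= 1))
    stop("asr cell means must lie strictly inside (0, 1)")
  set.seed(params$seed)
  rows <- list(); aid <- 0L
  for (g in seq_len(nrow(cells))) {
    for (a in seq_len(params$n_per_group)) {
      aid <- aid + 1L
      train <- stats::rlnorm(1, log(300), 0.25)
      r <- stats::rnorm(1, cells$mean[g], cells$sd[g])
      r <- min(max(r, 1e-3), 1 - 1e-3)
      test <- r / (1 - r) * train
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = sprintf("m%03d", aid), genotype = cells$genotype[g],
        cre = cells$cre[g], tmx = cells$tmx[g],
        endpoint = c("train_activity", "test_activity", "asr"),
        value = c(train, test, activity_suppression_ratio(train, test)),
        stringsAsFactors = FALSE)
    }
  }
  cohort_table(do.call(rbind, rows))
}
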