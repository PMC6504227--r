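# Shared fixture builders and independent oracles.
# Simulations run at fs = 250 Hz (above Nyquist for the 1-100 Hz analysis
# range) and short durations to stay inside the CPU budget; the statistical
# laws under test do not depend on fs.

quick_sim <- function(seed = 1, duration_s = 300, fs = 250, ...) {
  simulate_recording(sim_recording_params(duration_s = duration_s, fs = fs,
                                          seed = seed, ...))
}

# four-cell (cre x genotype) cohort cells for one endpoint
asr_cells <- function(means, sds = 0.1) {
  g <- expand.grid(genotype = c("+/+", "+/ls"), cre = c("-", "+"),
                   stringsAsFactors = FALSE)
  data.frame(genotype = g$genotype, cre = g$cre, tmx = "-", endpoint = "asr",
             mean = means, sd = sds, stringsAsFactors = FALSE)
}

seizure_cells <- function(clonus, tc, the, sd = 20) {
  g <- expand.grid(genotype = c("+/+", "+/ls"), cre = c("-", "+"),
                   stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    data.frame(genotype = g$genotype[i], cre = g$cre[i], tmx = "-",
               endpoint = c("clonus", "tc", "the"),
               mean = c(clonus[i], tc[i], the[i]), sd = sd,
               stringsAsFactors = FALSE)
  }))
}

# flat cohort table from per-group value vectors (cre x genotype crossing)
cohort_from_values <- function(values_by_cell) {
  rows <- do.call(rbind, lapply(names(values_by_cell), function(nm) {
    parts <- strsplit(nm, ":")[[1]]  # "cre:genotype"
    v <- values_by_cell[[nm]]
    data.frame(animal_id = paste0(nm, "_", seq_along(v)), genotype = parts[2],
               cre = parts[1], tmx = "-", endpoint = "y", value = v,
               stringsAsFactors = FALSE)
  }))
  cohort_table(rows)
}

# exhaustive per-sample reference spike detector: walks the trace one sample
# at a time, closing a run when the signal drops to/below threshold, then
# merges runs separated by less than the refractory period keeping the
# larger peak. Independent of the rle-based production path.
ref_detect <- function(x, fs, threshold, refractory_s) {
  peaks_t <- c(); peaks_a <- c()
  in_run <- FALSE; best_a <- -Inf; best_i <- NA
  for (i in seq_along(x)) {
    if (x[i] > threshold) {
      if (!in_run) { in_run <- TRUE; best_a <- -Inf }
      if (x[i] > best_a) { best_a <- x[i]; best_i <- i }
    } else if (in_run) {
      in_run <- FALSE
      peaks_t <- c(peaks_t, (best_i - 1) / fs); peaks_a <- c(peaks_a, best_a)
    }
  }
  if (in_run) { peaks_t <- c(peaks_t, (best_i - 1) / fs); peaks_a <- c(peaks_a, best_a) }
  if (length(peaks_t) <= 1)
    return(data.frame(peak_time_s = peaks_t, peak_amp_mV = peaks_a))
  # gap between end of one excursion and start of the next is what the
  # production code compares; reconstruct it from the raw runs
  runs <- rle(x > threshold)
  ends <- cumsum(runs$lengths); starts <- c(1, head(ends, -1) + 1)
  rs <- starts[runs$values]; re <- ends[runs$values]
  merged_t <- peaks_t[1]; merged_a <- peaks_a[1]
  for (k in 2:length(peaks_t)) {
    gap <- (rs[k] - re[k - 1] - 1) / fs
    if (gap < refractory_s) {
      j <- length(merged_t)
      if (peaks_a[k] > merged_a[j]) { merged_t[j] <- peaks_t[k]; merged_a[j] <- peaks_a[k] }
    } else {
      merged_t <- c(merged_t, peaks_t[k]); merged_a <- c(merged_a, peaks_a[k])
    }
  }
  data.frame(peak_time_s = merged_t, peak_amp_mV = merged_a)
}

# recording built directly from channel vectors, defaulting absent channels
make_rec <- function(hlfp = NULL, eeg_l = NULL, eeg_r = NULL, emg = NULL,
                     fs = 250) {
  n <- max(length(hlfp), length(eeg_l), length(eeg_r), length(emg))
  z <- function(x) if (is.null(x)) numeric(n) else x
  recording(list(eeg_l = z(eeg_l), eeg_r = z(eeg_r), hlfp = z(hlfp),
                 emg = z(emg)), fs = fs)
}

# triangular positive pulse of given peak at time t0 (width ~40 ms)
add_pulse <- function(x, fs, t0, peak, width_s = 0.04) {
  i0 <- round(t0 * fs) + 1
  half <- max(1, round(width_s * fs / 2))
  idx <- (i0 - half):(i0 + half)
  shape <- peak * (1 - abs(seq(-half, half)) / (half + 1))
  ok <- idx >= 1 & idx <= length(x)
  x[idx[ok]] <- x[idx[ok]] + shape[ok]
  x
}

# analytic unit-area Morlet frequency response: amplitude of a unit sinusoid
# at tone frequency f0 seen by the wavelet centred at f
morlet_response <- function(f, f0, n_cycles = 6) {
  sigma_t <- n_cycles / (2 * pi * f)
  0.5 * exp(-sigma_t^2 * (2 * pi * (f - f0))^2 / 2)
}

# hand-rolled amplitude_spectrum for arithmetic oracles
toy_spectrum <- function(freqs, amp, fs = 1) {
  structure(list(freqs_hz = freqs, amp = amp, fs = fs,
                 edge = rep(0L, length(freqs)), n_cycles = 6,
                 normalization = "unit_area"),
            class = "amplitude_spectrum")
}

# amplitude_change built directly from a per-animal x frequency matrix
toy_change <- function(per_animal, freqs = log_freqs()) {
  structure(list(freqs_hz = freqs, per_animal = per_animal,
                 grand_mean = colMeans(per_animal), ci_low = NULL,
                 ci_high = NULL, animals = rownames(per_animal)),
            class = "amplitude_change")
}

# direct enumeration oracle for the sign-flip permutation p (two-sided)
enum_perm_p <- function(x) {
  n <- length(x)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null <- as.vector(signs %*% x) / n
  obs <- mean(x)
  mean(abs(null) >= abs(obs) - 1e-12 * max(1, abs(obs)))
}
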