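fs_spec <- 250

test_that("analysis_window truncates, warns, and rejects bad input", {
  sim <- quick_sim(seed = 51, duration_s = 90)
  win <- analysis_window(sim$recording, minutes = 1)
  expect_equal(duration(win), 60)
  expect_warning(w7 <- analysis_window(sim$recording, minutes = 2), "shorter")
  expect_equal(duration(w7), 90)
  expect_error(analysis_window(sim$recording, minutes = 0), "positive")
})

test_that("morlet contract: Nyquist check, zero trace, increasing freqs", {
  expect_error(morlet_amplitude(rnorm(100), fs = 150), "Nyquist")
  expect_error(morlet_amplitude(c(1, NA, 3), fs = 250), "finite")
  spec <- morlet_amplitude(numeric(fs_spec * 5), fs_spec)
  expect_true(all(spec$amp == 0))
  expect_equal(length(spec$freqs_hz), 50)
  expect_true(all(diff(spec$freqs_hz) > 0))
  expect_equal(range(spec$freqs_hz), c(1, 100))
})

test_that("unit sinusoid matches the analytic unit-area Morlet response within 2%", {
  for (f0 in c(4, 8, 30)) {
    t <- (0:(30 * fs_spec - 1)) / fs_spec
    spec <- morlet_amplitude(sin(2 * pi * f0 * t), fs_spec)
    obs <- epiphys:::time_avg_amp(spec)
    expct <- morlet_response(spec$freqs_hz, f0)
    sel <- expct > 0.05 * max(expct)   # away from the response tails
    expect_lt(max(abs(obs[sel] - expct[sel]) / expct[sel]), 0.02)
  }
})

test_that("band power of a pure tone concentrates in its own band", {
  t <- (0:(30 * fs_spec - 1)) / fs_spec
  spec <- morlet_amplitude(sin(2 * pi * 8 * t), fs_spec)
  pow <- epiphys:::time_avg_amp(spec)^2
  in_theta <- spec$freqs_hz >= 6 & spec$freqs_hz <= 12
  expect_gt(sum(pow[in_theta]) / sum(pow), 0.9)
})

test_that("delta component leaves the theta rows unchanged within 3%", {
  t <- (0:(30 * fs_spec - 1)) / fs_spec
  theta_only <- sin(2 * pi * 8 * t)
  both <- theta_only + sin(2 * pi * 2.5 * t)
  a1 <- epiphys:::time_avg_amp(morlet_amplitude(theta_only, fs_spec))
  a2 <- epiphys:::time_avg_amp(morlet_amplitude(both, fs_spec))
  rows <- band_rows_for_test <- which(morlet_response(log_freqs(), 8) >
                                        0.05 * 0.5)
  expect_lt(max(abs(a2[rows] - a1[rows]) / a1[rows]), 0.03)
})

test_that("amplitude is homogeneous under trace scaling", {
  set.seed(52)
  x <- rnorm(fs_spec * 4)
  s1 <- morlet_amplitude(x, fs_spec)
  s3 <- morlet_amplitude(3 * x, fs_spec)
  expect_equal(s3$amp, 3 * s1$amp, tolerance = 1e-10)
})

test_that("theta/delta ratio: tones, hand-computed oracle, zero-delta flag", {
  t <- (0:(20 * fs_spec - 1)) / fs_spec
  r_theta <- theta_delta_ratio(morlet_amplitude(sin(2 * pi * 8 * t), fs_spec))
  interior <- !r_theta$flagged
  expect_true(all(r_theta$ratio[interior] > 10))
  r_delta <- theta_delta_ratio(morlet_amplitude(sin(2 * pi * 2.5 * t), fs_spec))
  expect_true(all(r_delta$ratio[!r_delta$flagged] < 0.1))

  # 3-sample toy spectrum: exact arithmetic
  toy <- toy_spectrum(freqs = c(2, 8),
                      amp = rbind(c(1, 2, 4), c(3, 3, 2)), fs = 1)
  rr <- theta_delta_ratio(toy, smooth_s = 1)  # window = 1 sample: no smoothing
  expect_equal(rr$ratio, c(9 / 1, 9 / 4, 4 / 16))

  toy0 <- toy_spectrum(freqs = c(2, 8), amp = rbind(c(0, 1), c(1, 1)), fs = 1)
  r0 <- theta_delta_ratio(toy0, smooth_s = 1)
  expect_true(is.infinite(r0$ratio[1]) && r0$flagged[1])
})

test_that("representative window lands on the theta burst; ties break early", {
  t <- (0:(30 * fs_spec - 1)) / fs_spec
  burst_env <- exp(-(t - 11)^2 / (2 * 0.5^2))
  x <- 0.2 * sin(2 * pi * 2.5 * t) + burst_env * sin(2 * pi * 8 * t)
  ratio <- theta_delta_ratio(morlet_amplitude(x, fs_spec))
  win <- select_representative_window(ratio, window_s = 1)
  expect_gte(win[["start_s"]], 9.5)
  expect_lte(win[["end_s"]], 12.5)

  const <- toy_spectrum(freqs = c(2, 8), amp = rbind(rep(1, 100), rep(2, 100)),
                        fs = 10)
  wc <- select_representative_window(theta_delta_ratio(const, smooth_s = 0.1),
                                     window_s = 1)
  expect_equal(wc[["start_s"]], 0)  # constant ratio: earliest window wins
})

test_that("normalized change: identity, scaling, common-rescale invariance", {
  t <- (0:(20 * fs_spec - 1)) / fs_spec
  spec1 <- morlet_amplitude(sin(2 * pi * 8 * t) + 0.3 * sin(2 * pi * 3 * t),
                            fs_spec)
  spec2 <- spec1; spec2$amp <- 2 * spec1$amp
  chg_id <- normalized_amplitude_change(list(a = spec1), list(a = spec1))
  expect_true(all(abs(chg_id$grand_mean) < 1e-12))
  chg_x2 <- normalized_amplitude_change(list(a = spec1), list(a = spec2))
  expect_equal(unname(chg_x2$grand_mean), rep(1, 50))
  # common multiplicative rescaling of both phases changes nothing
  s1b <- spec1; s1b$amp <- 5 * spec1$amp
  s2b <- spec2; s2b$amp <- 5 * spec2$amp
  chg_sc <- normalized_amplitude_change(list(a = s1b), list(a = s2b))
  expect_equal(chg_sc$grand_mean, chg_x2$grand_mean, tolerance = 1e-12)
})

test_that("animals missing a phase are excluded with a warning", {
  t <- (0:(10 * fs_spec - 1)) / fs_spec
  sp <- morlet_amplitude(sin(2 * pi * 8 * t), fs_spec)
  expect_warning(
    chg <- normalized_amplitude_change(list(a = sp, b = sp), list(a = sp)),
    "missing a phase")
  expect_equal(chg$animals, "a")
})

test_that("bootstrap CI: degenerate cases and normal-theory agreement", {
  m1 <- matrix(0.4, 1, 50)
  chg1 <- toy_change(m1)
  chg1 <- bootstrap_ci(chg1)
  expect_equal(chg1$ci_low, chg1$grand_mean)
  expect_match(chg1$ci_note, "single animal")

  m_same <- matrix(rep(0.25, 50 * 6), 6, 50, byrow = TRUE)
  chg_same <- bootstrap_ci(toy_change(m_same), n_boot = 200)
  expect_equal(chg_same$ci_low, chg_same$ci_high)  # zero-width CI

  # Gaussian per-animal changes, n = 30: percentile CI ~ normal-theory CI
  set.seed(53)
  n <- 30
  m <- matrix(rnorm(n * 50, mean = 0.3, sd = 0.2), n, 50)
  chg <- bootstrap_ci(toy_change(m), n_boot = 4000, seed = 7)
  mu <- colMeans(m); se <- apply(m, 2, sd) / sqrt(n)
  half <- 1.96 * se
  expect_lt(max(abs(chg$ci_low - (mu - half)) / half), 0.25)
  expect_lt(max(abs(chg$ci_high - (mu + half)) / half), 0.25)
})

test_that("permutation test: saturation, enumeration oracle, convergence", {
  chg0 <- toy_change(matrix(0, 4, 50))
  expect_equal(band_permutation_test(chg0)$p, 1)

  # n = 5: exhaustive mode must equal direct enumeration over 32 sign patterns
  set.seed(54)
  m5 <- matrix(rnorm(5 * 50, 0.3, 0.3), 5, 50)
  chg5 <- toy_change(m5)
  res <- band_permutation_test(chg5, n_shuffles = 5000)
  expect_equal(res$mode, "exhaustive")
  rows <- which(log_freqs() >= 6 & log_freqs() <= 12)
  expect_equal(res$p, enum_perm_p(rowMeans(m5[, rows])))

  # sampled mode converges to the enumerated p
  set.seed(55)
  m13 <- matrix(rnorm(13 * 50, 0.08, 0.3), 13, 50)
  chg13 <- toy_change(m13)
  res_s <- band_permutation_test(chg13, n_shuffles = 8000, seed = 9)
  expect_equal(res_s$mode, "sampled")
  p_enum <- enum_perm_p(rowMeans(m13[, rows]))
  se <- sqrt(p_enum * (1 - p_enum) / 8000)
  expect_lt(abs(res_s$p - p_enum), 4 * se + 2 / 8000)

  expect_error(band_permutation_test(chg5, band = c(300, 400)), "outside")
})

test_that("a 40% theta-only increase is recovered at ~+0.4, confined to theta", {
  sim_phase <- function(seed, theta_amp) {
    sim <- simulate_recording(sim_recording_params(
      duration_s = 60, fs = fs_spec, spike_rate_wake = 0, spike_rate_sleep = 0,
      sleep_fraction = 0, theta_amp = theta_amp, delta_amp = 0.4, seed = seed))
    morlet_amplitude(sim$recording$channels$hlfp, fs_spec)
  }
  p1 <- lapply(1:7, function(i) sim_phase(1000 + i, 1.0))
  p2 <- lapply(1:7, function(i) sim_phase(2000 + i, 1.4))
  names(p1) <- names(p2) <- sprintf("m%d", 1:7)
  chg <- bootstrap_ci(normalized_amplitude_change(p1, p2), n_boot = 1000,
                      seed = 77)
  f <- chg$freqs_hz
  # at the 8 Hz generator line the change is ~+0.4 and inside the CI
  theta_core <- which(abs(f - 8) < 1)
  expect_lt(abs(mean(chg$grand_mean[theta_core]) - 0.4), 0.08)
  expect_true(all(chg$ci_low[theta_core] < 0.4 + 0.1 &
                    chg$ci_high[theta_core] > 0.4 - 0.1))
  # delta band (driven at 2.5 Hz, equal amplitude in both phases): ~0 within
  # the bootstrap CI everywhere; tight at the delta line itself, where the
  # sinusoid dominates the 1/f noise
  delta_rows <- which(f >= 1 & f <= 4)
  expect_true(all(chg$ci_low[delta_rows] <= 0.02 &
                    chg$ci_high[delta_rows] >= -0.02))
  delta_line <- which(abs(f - 2.5) < 0.5)
  expect_lt(max(abs(chg$grand_mean[delta_line])), 0.05)
  perm <- band_permutation_test(chg, band = c(6, 12))
  expect_lt(perm$p, 0.05)
})

test_that("spectra export as CSV matrices", {
  t <- (0:(2 * fs_spec - 1)) / fs_spec
  spec <- morlet_amplitude(sin(2 * pi * 8 * t), fs_spec, freqs = log_freqs(10))
  path <- tempfile(fileext = ".csv")
  write_amplitude_spectrum(spec, path)
  back <- read.csv(path)
  expect_equal(dim(back), c(10, 2 * fs_spec + 1))
  expect_equal(back$freq_hz, spec$freqs_hz, tolerance = 1e-8)
  unlink(path)
})
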