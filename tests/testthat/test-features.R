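# Filters, Welch spectra, band power, EMG amplitude, coherence and the
# feature table.

fs <- 1000
tt <- seq_len(10 * fs) / fs

test_that("notch filter rejects the line frequency and spares the pass band", {
  s50 <- sin(2 * pi * 50 * tt)
  s10 <- sin(2 * pi * 10 * tt)
  expect_lt(sqrt(mean(notch_filter(s50, fs)^2)), 0.1 * sqrt(mean(s50^2)))
  expect_lt(abs(sqrt(mean(notch_filter(s10, fs)^2)) / sqrt(mean(s10^2)) - 1),
            0.05)
  expect_error(notch_filter(s10, fs, freq = 600), "fs/2")
})

test_that("notch suppression of a mixed tone is visible in the periodogram", {
  x <- sin(2 * pi * 10 * tt) + sin(2 * pi * 50 * tt)
  y <- notch_filter(x, fs)
  # FFT oracle: peak heights straight from the discrete transform
  peak <- function(z, f) Mod(fft(z))[f * 10 + 1]  # 0.1 Hz resolution
  expect_lt(peak(y, 50) / peak(x, 50), 10^(-20 / 20))
  expect_gt(peak(y, 10) / peak(x, 10), 0.95)
})

test_that("EMG band-pass attenuates out-of-band tones and passes in-band", {
  s5 <- sin(2 * pi * 5 * tt)
  s100 <- sin(2 * pi * 100 * tt)
  expect_lt(sqrt(mean(bandpass_emg(s5, fs)^2)),
            10^(-20 / 20) * sqrt(mean(s5^2)))
  expect_lt(abs(sqrt(mean(bandpass_emg(s100, fs)^2)) / sqrt(mean(s100^2)) - 1),
            0.05)
  expect_error(bandpass_emg(s5, fs, low = 300, high = 200))
})

test_that("band-passed white noise keeps the spectrally integrated variance", {
  set.seed(21)
  x <- rnorm(2e5)
  y <- bandpass_emg(x, fs)
  # spectral integration oracle: |H|^4 over frequency (filtfilt = twice)
  bf <- signal::butter(4, c(20, 200) / (fs / 2), type = "pass")
  H <- signal::freqz(bf, n = 8192, Fs = fs)
  expected_ratio <- mean(Mod(H$h)^4)
  expect_lt(abs(var(y) / var(x) - expected_ratio) / expected_ratio, 0.05)
})

test_that("epoch segmentation counts and truncation follow the half-open rule", {
  expect_identical(ncol(segment_epochs(rnorm(7200 * 10), fs = 10)), 720L)
  m <- segment_epochs(rnorm(25 * 100), fs = 100, epoch_len_s = 10)
  expect_identical(dim(m), c(1000L, 2L))
  expect_warning(short <- segment_epochs(rnorm(5), fs = 10, epoch_len_s = 10),
                 "shorter")
  expect_identical(ncol(short), 0L)
  # nine default-length recordings yield 6480 epochs
  expect_identical(9L * ncol(segment_epochs(rnorm(7200 * 5), fs = 5)), 6480L)
})

test_that("band power localizes a tone and vanishes on silence", {
  x <- sin(2 * pi * 6 * tt)
  p <- band_power(x, fs)
  expect_identical(names(which.max(p)), "theta")
  expect_true(all(p[["theta"]] >= 10 * p[names(p) != "theta"]))
  expect_identical(unname(band_power(numeric(10 * fs), fs)), rep(0, 7))
  expect_error(band_power(rnorm(fs), fs), "2 s")
  expect_error(band_power(rnorm(10 * 50), fs = 50), "band edge")
})

test_that("white-noise PSD is flat at the analytic one-sided level 2/fs", {
  set.seed(22)
  reps <- 100
  means <- replicate(reps, band_power(rnorm(10 * fs), fs))
  level <- rowMeans(means)       # per band
  se <- apply(means, 1, sd) / sqrt(reps)
  expect_true(all(abs(level - 2 / fs) < 3 * se))
})

test_that("Welch PSD conserves variance and matches an independent oracle", {
  set.seed(23)
  # Parseval: sum of PSD bins x bin width ~ variance (white noise)
  ratio <- replicate(20, {
    x <- rnorm(10 * fs)
    wf <- somnopark:::welch_fft(x, fs)
    sum(somnopark:::welch_psd(wf)) * 1 / var(x)   # 1 Hz bins
  })
  expect_lt(abs(mean(ratio) - 1), 0.01)

  # independent plain-loop Welch implementation
  x <- rnorm(10 * fs)
  oracle <- local({
    N <- fs; w <- 0.5 * (1 - cos(2 * pi * seq_len(N) / N))
    starts <- seq(0, length(x) - N, by = N / 2)
    acc <- numeric(N %/% 2 + 1)
    for (s0 in starts) {
      X <- fft(x[(s0 + 1):(s0 + N)] * w)[1:(N %/% 2 + 1)]
      acc <- acc + Mod(X)^2
    }
    P <- acc / length(starts) / (fs * sum(w^2))
    P[2:(length(P) - 1)] <- 2 * P[2:(length(P) - 1)]
    P
  })
  mine <- somnopark:::welch_psd(somnopark:::welch_fft(x, fs))
  expect_lt(max(abs(mine - oracle)), 1e-10)
})

test_that("EMG amplitude is the mean absolute value", {
  expect_identical(emg_amplitude(rep(2, 100)), 2)
  expect_identical(emg_amplitude(rep(c(-3, 3), 50)), 3)
  set.seed(24)
  x <- rnorm(10000)
  expect_lt(abs(emg_amplitude(x) - sqrt(2 / pi)), 3 / sqrt(10000))
  expect_error(emg_amplitude(numeric(0)), "empty")
})

test_that("coherence is 1 for identical signals and ~1/K for independent ones", {
  set.seed(25)
  x <- rnorm(10 * fs)
  expect_true(all(abs(coherence_bands(x, x, fs) - 1) < 1e-6))

  reps <- 300
  cmc <- replicate(reps, {
    coherence_bands(rnorm(10 * 200), rnorm(10 * 200), fs = 200,
                    bands = data.frame(band = "b", low = 10, high = 60))
  })
  # K = 19 averaged windows; 50% Hann overlap leaves them slightly
  # correlated, so the bias sits just above 1/19
  expect_lt(abs(mean(cmc) - 1 / 19), 0.015)
  expect_warning(z <- coherence_bands(numeric(10 * fs), x, fs), "silent")
  expect_identical(unname(z), rep(0, 7))
  expect_error(coherence_bands(x, x[-1], fs), "mismatch")
})

test_that("feature extraction yields the documented table shape", {
  cfg <- generator_config(duration_s = 120)
  h <- sample_hypnogram(cfg, seed = 31)
  r <- synthesize_recording(cfg, h, "lesion", seed = 32)
  ft <- extract_features(r, h)
  expect_s3_class(ft, "somno_features")
  expect_identical(nrow(ft), 12L)
  expect_identical(names(ft),
                   c("rat_id", "group", "state",
                     paste0("pow_frontal_", band_scheme()$band),
                     paste0("pow_occipital_", band_scheme()$band),
                     "emg_amp",
                     paste0("cmc_frontal_", band_scheme()$band),
                     paste0("cmc_occipital_", band_scheme()$band)))
  expect_identical(ft$state, as.character(h$labels))
  num <- as.matrix(ft[, -(1:3)])
  expect_true(all(is.finite(num)))
  expect_true(all(num[, grep("^cmc", colnames(num))] >= 0))
  expect_true(all(num[, grep("^cmc", colnames(num))] <= 1))
  expect_true(all(num[, grep("^pow", colnames(num))] >= 0))
  # exact epoch multiple: nothing dropped
  expect_identical(nrow(extract_features(r)), 12L)
  expect_error(extract_features(r, sample_hypnogram(
    generator_config(duration_s = 240), seed = 1)), "match")
})

test_that("feature rows are epoch-local up to filter ring-down", {
  cfg <- generator_config(duration_s = 50)
  h <- make_hypnogram(rep("WAKE", 5))
  r <- synthesize_recording(cfg, h, "sham", seed = 33)
  ft1 <- extract_features(r, h)
  r2 <- r
  idx <- 20001:30000  # epoch 3
  r2$frontal[idx] <- r2$frontal[idx] * 3
  ft2 <- extract_features(r2, h)
  m1 <- as.matrix(ft1[, -(1:3)]); m2 <- as.matrix(ft2[, -(1:3)])
  expect_gt(m2[3, "pow_frontal_delta"] / m1[3, "pow_frontal_delta"], 4)
  # other rows move only by the notch filter's ring across the boundary
  rel <- abs(m2[-3, ] - m1[-3, ]) / (abs(m1[-3, ]) + 1e-12)
  expect_lt(max(rel), 0.02)
  # epochs not adjacent to the edit are essentially untouched
  far <- abs(m2[c(1, 5), ] - m1[c(1, 5), ]) / (abs(m1[c(1, 5), ]) + 1e-12)
  expect_lt(max(far), 1e-3)
})

test_that("per-rat min-max normalization scales each rat to [0, 1]", {
  expect_equal(
    {
      tb <- data.frame(rat_id = "a", group = "sham", state = "WAKE",
                       pow_frontal_delta = c(2, 4, 6))
      class(tb) <- c("somno_features", "data.frame")
      normalize_features(tb, keep_raw = character(0))$pow_frontal_delta
    },
    c(0, 0.5, 1))
  tb <- data.frame(rat_id = "a", group = "sham", state = "WAKE",
                   pow_frontal_delta = c(5, 5, 5))
  class(tb) <- c("somno_features", "data.frame")
  expect_identical(normalize_features(tb, keep_raw = character(0))$pow_frontal_delta,
                   c(0, 0, 0))

  # two rats concatenated: per-rat extrema all 0 / 1 (brute-force check)
  set.seed(26)
  tb2 <- data.frame(rat_id = rep(c("r1", "r2"), each = 20),
                    group = "sham", state = "WAKE",
                    pow_frontal_delta = rexp(40), emg_amp = runif(40, 2, 9))
  class(tb2) <- c("somno_features", "data.frame")
  nm <- normalize_features(tb2, keep_raw = "pow_frontal_delta")
  for (rat in c("r1", "r2")) {
    for (col in c("pow_frontal_delta", "emg_amp")) {
      v <- nm[[col]][nm$rat_id == rat]
      expect_identical(range(v), c(0, 1))
    }
  }
  # keep_raw column is bit-identical to the pre-normalization values
  expect_identical(nm$raw_pow_frontal_delta, tb2$pow_frontal_delta)
  expect_true(attr(nm, "normalized"))
})
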