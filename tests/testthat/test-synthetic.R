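# Synthetic cohort generator: hypnogram process, waveform synthesis,
# cohort assembly.

test_that("hypnogram has one label per complete epoch", {
  cfg <- generator_config()  # 7200 s, 10-s epochs
  h <- sample_hypnogram(cfg, seed = 1)
  expect_length(h$labels, 720)
  expect_true(all(h$labels %in% vigilance_states()))

  h1 <- sample_hypnogram(generator_config(duration_s = 10), seed = 1)
  expect_length(h1$labels, 1)
})

test_that("long-run state proportions converge to the stationary target", {
  cfg <- generator_config(duration_s = 72000)
  h <- sample_hypnogram(cfg, seed = 7)
  props <- prop.table(table(h$labels))[vigilance_states()]
  expect_true(all(abs(props - cfg$state_stationary) < 0.03))
})

test_that("REM is entered only from NREM unless the constraint is lifted", {
  cfg <- generator_config(duration_s = 72000)
  h <- sample_hypnogram(cfg, seed = 3)
  runs <- rle(as.character(h$labels))$values
  before_rem <- runs[which(runs == "REM") - 1]
  expect_true(all(before_rem == "NREM"))

  cfg2 <- generator_config(duration_s = 72000, rem_after_nrem_only = FALSE)
  h2 <- sample_hypnogram(cfg2, seed = 3)
  runs2 <- rle(as.character(h2$labels))$values
  before_rem2 <- runs2[which(runs2 == "REM") - 1]
  expect_true("WAKE" %in% before_rem2)
})

test_that("hypnogram sampling is deterministic given the seed", {
  cfg <- generator_config(duration_s = 3000)
  expect_identical(sample_hypnogram(cfg, seed = 5),
                   sample_hypnogram(cfg, seed = 5))
  expect_false(identical(sample_hypnogram(cfg, seed = 5)$labels,
                         sample_hypnogram(cfg, seed = 6)$labels))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(duration_s = -5), "duration_s")
  expect_error(generator_config(epoch_len_s = -1), "epoch_len_s")
  expect_error(sample_hypnogram(generator_config(state_mean_dur_s =
    c(WAKE = 5, NREM = 160, REM = 80)), seed = 1), "epoch_len_s")
  expect_error(generator_config(coupling = list(
    frontal = matrix(2, 3, 7), occipital = matrix(0, 3, 7))), "coupling")
  # mean durations incompatible with the stationary target
  expect_error(sample_hypnogram(generator_config(
    state_mean_dur_s = c(WAKE = 1000, NREM = 20, REM = 20)), seed = 1),
    "incompatible")
})

test_that("synthesized channels share length fs * duration", {
  cfg <- generator_config(duration_s = 60)
  h <- sample_hypnogram(cfg, seed = 2)
  r <- synthesize_recording(cfg, h, "sham", seed = 4)
  expect_length(r$frontal, 60000)
  expect_length(r$occipital, 60000)
  expect_length(r$emg, 60000)
  expect_error(synthesize_recording(cfg, h, "mutant", seed = 1))
  h_bad <- sample_hypnogram(generator_config(duration_s = 120), seed = 2)
  expect_error(synthesize_recording(cfg, h_bad, "sham", seed = 1),
               "inconsistent")
})

test_that("mean absolute EMG amplitude is ordered WAKE > NREM > REM", {
  cfg <- generator_config(duration_s = 300, rat_sd = 0)
  h <- make_hypnogram(rep(c("WAKE", "NREM", "REM"), each = 10))
  r <- synthesize_recording(cfg, h, "sham", seed = 8)
  M <- segment_epochs(r$emg, cfg$fs, 10)
  amp <- colMeans(abs(M))
  st <- as.character(h$labels)
  expect_gt(mean(amp[st == "WAKE"]), mean(amp[st == "NREM"]))
  expect_gt(mean(amp[st == "NREM"]), mean(amp[st == "REM"]))
})

test_that("zero coupling leaves only the coherence estimator's bias", {
  cfg <- single_band_config(300, coupling = 0)
  h <- make_hypnogram(rep("WAKE", 30))
  r <- synthesize_recording(cfg, h, "sham", seed = 9)
  Mo <- segment_epochs(r$occipital, cfg$fs, 10)
  Me <- segment_epochs(r$emg, cfg$fs, 10)
  cmc <- vapply(seq_len(ncol(Mo)), function(e) {
    coherence_bands(Mo[, e], Me[, e], cfg$fs)[["theta"]]
  }, numeric(1))
  # independent-channel bias oracle measured on white noise with the same
  # estimator settings
  set.seed(1)
  bias <- mean(replicate(40, {
    coherence_bands(rnorm(10000), rnorm(10000), cfg$fs)[["theta"]]
  }))
  se <- sd(cmc) / sqrt(length(cmc))
  expect_lt(abs(mean(cmc) - bias), 3 * se + 0.01)
})

test_that("extracted coherence matches the closed-form shared-source value", {
  a <- 25; cc <- 0.004; emg <- 1.5; nf <- 6; fs <- 1000
  cfg <- single_band_config(600, a = a, coupling = cc, emg = emg,
                            noise_floor = nf)
  h <- make_hypnogram(rep("WAKE", 60))
  r <- synthesize_recording(cfg, h, "sham", seed = 10)
  # interior bins of the synthesis band avoid edge-bin dilution
  interior <- data.frame(band = "mid", low = 5.5, high = 7)
  Mo <- segment_epochs(r$occipital, fs, 10)
  Me <- segment_epochs(r$emg, fs, 10)
  est <- vapply(seq_len(ncol(Mo)), function(e) {
    coherence_bands(Mo[, e], Me[, e], fs, bands = interior)[["mid"]]
  }, numeric(1))
  C <- shared_source_coherence(a, cc, B = 3.5, noise_floor = nf,
                               emg = emg, fs = fs)
  # first-order small-sample bias of the K-window averaged estimator
  expected <- C + (1 - C)^2 / 19
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - expected), 3 * se)
})

test_that("raising a band amplitude raises that band's extracted power", {
  h <- make_hypnogram(rep("WAKE", 100))
  mean_alpha <- function(a) {
    cfg <- single_band_config(1000, band = "alpha", a = a)
    r <- synthesize_recording(cfg, h, "sham", seed = 11)
    M <- segment_epochs(r$occipital, cfg$fs, 10)
    mean(vapply(seq_len(ncol(M)), function(e) {
      band_power(M[, e], cfg$fs)[["alpha"]]
    }, numeric(1)))
  }
  p1 <- mean_alpha(18)
  p2 <- mean_alpha(27)
  expect_gt(p2, p1 * 1.5)  # variance scales with amplitude squared
})

test_that("lesion modifiers reshape only the frontal channel", {
  cfg <- generator_config(duration_s = 200, rat_sd = 0)
  h <- make_hypnogram(rep("WAKE", 20))
  sham <- synthesize_recording(cfg, h, "sham", seed = 12)
  les <- synthesize_recording(cfg, h, "lesion", seed = 12)
  pow_of <- function(x) {
    M <- segment_epochs(x, cfg$fs, 10)
    rowMeans(vapply(seq_len(ncol(M)), function(e) band_power(M[, e], cfg$fs),
                    numeric(7)))
  }
  ps <- pow_of(sham$frontal); pl <- pow_of(les$frontal)
  # WAKE modifiers: high-beta x1.5, high-gamma x0.7 in power ~ x2.25 / x0.49
  expect_gt(pl[["hbeta"]] / ps[["hbeta"]], 1.5)
  expect_lt(pl[["hgamma"]] / ps[["hgamma"]], 0.75)
  # same seed, occipital untouched by the lesion
  expect_equal(les$occipital, sham$occipital)
})

test_that("cohorts have the requested size, unique ids and reproduce exactly", {
  cfg <- generator_config(duration_s = 60)
  coh <- generate_cohort(cfg, n_sham = 2, n_lesion = 3, seed = 13)
  expect_length(coh, 5)
  ids <- vapply(coh, function(e) e$recording$rat_id, "")
  expect_length(unique(ids), 5)
  expect_identical(vapply(coh, function(e) e$recording$group, ""),
                   c("sham", "sham", "lesion", "lesion", "lesion"))
  expect_identical(coh, generate_cohort(cfg, 2, 3, seed = 13))
  expect_length(generate_cohort(cfg, 0, 0, seed = 1), 0)
  expect_error(generate_cohort(cfg, -1, 2, seed = 1))
})

test_that("nine default-length hypnograms carry 6480 epochs", {
  cfg <- generator_config()
  total <- sum(vapply(1:9, function(i) {
    length(sample_hypnogram(cfg, seed = i)$labels)
  }, numeric(1)))
  expect_identical(total, 6480)
})
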