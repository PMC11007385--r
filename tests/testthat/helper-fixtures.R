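# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# short-recording mid-size cohort used by screening / protocol tests
fixture_config <- function(duration_s = 900) {
  generator_config(duration_s = duration_s)
}

# 6 + 6 rats x 15 min: large enough that every vigilance state carries a
# usable number of epochs per group (REM is the scarce one)
fixture_cohort <- function() {
  memo("cohort_6x6", function() {
    generate_cohort(fixture_config(), n_sham = 6, n_lesion = 6, seed = 42)
  })
}

fixture_features <- function() {
  memo("features_6x6", function() {
    normalize_features(extract_cohort_features(fixture_cohort()))
  })
}

# hand-built hypnogram (bypasses the bout sampler) for controlled synthesis
make_hypnogram <- function(labels, epoch_len_s = 10) {
  structure(
    list(epoch_len_s = epoch_len_s,
         labels = factor(labels, levels = vigilance_states())),
    class = "somno_hypnogram"
  )
}

# single-band generator config: only `band` is active, flat across states,
# with constant EMG scale and couplings; used for closed-form coherence and
# band-power oracles
single_band_config <- function(duration_s, band = "theta", a = 25,
                               coupling = 0, emg = 1.5, noise_floor = 6) {
  bands <- band_scheme()$band
  z <- matrix(0, 3, 7, dimnames = list(vigilance_states(), bands))
  amp <- z; amp[, band] <- a
  cpl <- z; cpl[, band] <- coupling
  generator_config(
    duration_s = duration_s,
    band_amp = list(frontal = z, occipital = amp),
    coupling = list(frontal = z, occipital = cpl),
    emg_amp = c(WAKE = emg, NREM = emg, REM = emg),
    noise_floor = noise_floor,
    rat_sd = 0,
    lesion_mod = matrix(1, 3, 7)
  )
}

# closed-form magnitude-squared coherence of the shared-source model, using
# one-sided spectral densities: source density a^2/B in [low, high], white
# noise densities 2*sigma^2/fs
shared_source_coherence <- function(a, coupling, B, noise_floor, emg, fs) {
  s_src <- a^2 / B
  s_ecog_noise <- 2 * noise_floor^2 / fs
  s_emg_noise <- 2 * emg^2 / fs
  num <- (coupling * s_src)^2
  den <- (s_src + s_ecog_noise) * (coupling^2 * s_src + s_emg_noise)
  num / den
}
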