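# Synthetic ECoG/EMG cohort generator.
#
# Emulates 2-h rodent polysomnography: a semi-Markov hypnogram over
# WAKE/NREM/REM, then per-channel waveforms built from band-limited Gaussian
# sources whose amplitudes follow the state sequence, a white noise floor,
# broadband EMG scaled per state, and shared band-limited sources injected
# into both an ECoG channel and the EMG to produce controllable
# corticomuscular coherence.

#' Configuration for the synthetic ECoG/EMG generator
#'
#' Collects every tunable of the synthetic cohort: sampling, epoching, the
#' state process (mean bout durations and long-run proportions), per-state
#' band-limited source amplitudes for the two cortical sites, multiplicative
#' lesion modifiers applied to frontal amplitudes in lesioned animals,
#' per-state EMG scale, ECoG--EMG coupling weights per (site, state, band),
#' and the white-noise floor.
#'
#' Defaults encode the qualitative contrasts the generator is meant to
#' reproduce: EMG amplitude ordered WAKE > NREM > REM; occipital and frontal
#' delta + alpha + low-beta power elevated in NREM; occipital theta
#' corticomuscular coherence peaking in REM and lowest in NREM; frontal delta
#' coherence peaking in NREM; and, in the lesion group, elevated frontal
#' high-beta/low-gamma in WAKE and REM, a state-dependent alpha shift, and a
#' uniform high-gamma reduction across all states (uniform so that it
#' survives only in unnormalized power, state-dependent effects survive
#' per-rat min--max normalization).
#'
#' @param fs Sampling rate in Hz.
#' @param duration_s Recording length in seconds.
#' @param epoch_len_s Epoch length in seconds; `fs * epoch_len_s` must be a
#'   whole number of samples.
#' @param state_mean_dur_s Named numeric (WAKE, NREM, REM): mean bout
#'   duration per state, seconds. Each must be >= `epoch_len_s`.
#' @param state_stationary Named numeric (WAKE, NREM, REM): target long-run
#'   state proportions; must sum to 1.
#' @param band_amp List with elements `frontal` and `occipital`, each a
#'   3 x 7 matrix (rows WAKE/NREM/REM, columns the seven bands) of
#'   band-limited source amplitudes (root-mean-square, arbitrary uV-like
#'   units).
#' @param lesion_mod 3 x 7 matrix of multiplicative modifiers applied to the
#'   frontal `band_amp` rows for lesion-group animals.
#' @param emg_amp Named numeric (WAKE, NREM, REM): broadband EMG scale.
#' @param coupling List with elements `frontal` and `occipital`, each a
#'   3 x 7 matrix in \[0, 1\]: the weight with which each shared band source is
#'   injected into the EMG (the ECoG receives the full source).
#' @param noise_floor White-noise amplitude added to each ECoG channel.
#' @param rat_sd Inter-animal heterogeneity: log-normal standard deviation of
#'   the rat-specific multiplicative factors drawn per (site, state, band)
#'   for the ECoG amplitudes (and, at half this value, per state for the EMG
#'   scale). Emulates electrode-placement and signal-amplitude differences
#'   between animals; 0 disables it.
#' @param rem_after_nrem_only Logical; if `TRUE` (default) REM bouts can only
#'   be entered from NREM.
#' @return An object of class `somno_config`.
#' @seealso [sample_hypnogram()], [synthesize_recording()], [generate_cohort()]
#' @examples
#' cfg <- generator_config(duration_s = 600)
#' cfg$state_stationary
#' @export
generator_config <- function(fs = 1000,
                             duration_s = 7200,
                             epoch_len_s = 10,
                             state_mean_dur_s = c(WAKE = 60, NREM = 160, REM = 80),
                             state_stationary = c(WAKE = 1548, NREM = 4164, REM = 768) / 6480,
                             band_amp = default_band_amp(),
                             lesion_mod = default_lesion_mod(),
                             emg_amp = c(WAKE = 3, NREM = 1.5, REM = 0.5),
                             coupling = default_coupling(),
                             noise_floor = 6,
                             rat_sd = 0.1,
                             rem_after_nrem_only = TRUE) {
  check_scalar_number(fs, "fs")
  check_scalar_number(duration_s, "duration_s")
  check_scalar_number(epoch_len_s, "epoch_len_s")
  if (abs(fs * epoch_len_s - round(fs * epoch_len_s)) > 1e-9) {
    stop("fs * epoch_len_s must be an integer number of samples", call. = FALSE)
  }
  states <- vigilance_states()
  state_mean_dur_s <- state_mean_dur_s[states]
  state_stationary <- state_stationary[states]
  if (any(!is.finite(state_mean_dur_s)) || any(state_mean_dur_s <= 0)) {
    stop("state_mean_dur_s must be positive for WAKE, NREM and REM", call. = FALSE)
  }
  if (any(!is.finite(state_stationary)) || any(state_stationary < 0) ||
      abs(sum(state_stationary) - 1) > 1e-6) {
    stop("state_stationary must be nonnegative and sum to 1", call. = FALSE)
  }
  bands <- band_scheme()$band
  band_amp <- lapply(band_amp, as_state_band_matrix, bands = bands)
  coupling <- lapply(coupling, as_state_band_matrix, bands = bands)
  lesion_mod <- as_state_band_matrix(lesion_mod, bands)
  stopifnot(all(c("frontal", "occipital") %in% names(band_amp)),
            all(c("frontal", "occipital") %in% names(coupling)))
  if (any(unlist(band_amp) < 0) || any(lesion_mod < 0)) {
    stop("amplitudes and lesion modifiers must be nonnegative", call. = FALSE)
  }
  cp <- unlist(coupling)
  if (any(cp < 0) || any(cp > 1)) {
    stop("coupling weights must lie in [0, 1]", call. = FALSE)
  }
  emg_amp <- emg_amp[states]
  if (any(!is.finite(emg_amp)) || any(emg_amp < 0)) {
    stop("emg_amp must be nonnegative for all three states", call. = FALSE)
  }
  check_scalar_number(noise_floor, "noise_floor", positive = FALSE)
  if (noise_floor < 0) stop("noise_floor must be >= 0", call. = FALSE)
  check_scalar_number(rat_sd, "rat_sd", positive = FALSE)
  if (rat_sd < 0) stop("rat_sd must be >= 0", call. = FALSE)
  structure(
    list(fs = fs, duration_s = duration_s, epoch_len_s = epoch_len_s,
         state_mean_dur_s = state_mean_dur_s,
         state_stationary = state_stationary,
         band_amp = band_amp, lesion_mod = lesion_mod, emg_amp = emg_amp,
         coupling = coupling, noise_floor = noise_floor, rat_sd = rat_sd,
         rem_after_nrem_only = isTRUE(rem_after_nrem_only)),
    class = "somno_config"
  )
}

# coerce a 3 x 7 (state x band) matrix, attaching canonical dimnames
as_state_band_matrix <- function(m, bands) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(3L, length(bands)))) {
    stop("state-by-band matrices must be 3 x 7 (WAKE/NREM/REM x bands)",
         call. = FALSE)
  }
  dimnames(m) <- list(vigilance_states(), bands)
  m
}

#' @rdname generator_config
#' @details `default_band_amp()`, `default_lesion_mod()` and
#'   `default_coupling()` return the preset state-by-band matrices described
#'   above; they are exported so users can start from the defaults and modify
#'   single entries.
#' @export
default_band_amp <- function() {
  bands <- band_scheme()$band
  # rows WAKE, NREM, REM; columns delta..hgamma; RMS amplitude of the
  # band-limited source. NREM elevates delta/alpha/low-beta; occipital theta
  # is prominent in WAKE and REM (hippocampal theta seen from the occipital
  # screw); gamma bands are state-flat so group contrasts come from
  # lesion_mod alone.
  occ <- rbind(
    WAKE = c(40, 45, 18, 14, 10, 8, 6),
    NREM = c(88, 25, 32, 22, 10, 8, 6),
    REM  = c(40, 50, 18, 14, 10, 8, 6)
  )
  fro <- rbind(
    WAKE = c(40, 28, 18, 14, 10, 8, 6),
    NREM = c(85, 30, 30, 22, 10, 8, 6),
    REM  = c(42, 30, 18, 14, 10, 8, 6)
  )
  colnames(occ) <- colnames(fro) <- bands
  list(frontal = fro, occipital = occ)
}

#' @rdname generator_config
#' @export
default_lesion_mod <- function() {
  bands <- band_scheme()$band
  m <- rbind(
    WAKE = c(1, 1, 1.30, 1, 1.50, 1.45, 0.70),
    NREM = c(1, 1, 0.85, 1, 1.00, 1.00, 0.70),
    REM  = c(1, 1, 1.30, 1, 1.50, 1.45, 0.70)
  )
  colnames(m) <- bands
  m
}

#' @rdname generator_config
#' @export
default_coupling <- function() {
  bands <- band_scheme()$band
  zero <- matrix(0, 3, 7, dimnames = list(vigilance_states(), bands))
  # Weights are the amplitude fraction of each band source injected into
  # the EMG. Because broadband EMG noise is spectrally dilute (density
  # 2*emg_amp^2/fs per Hz), small fractions already produce large in-band
  # coherence; these defaults place the expected occipital theta coherence
  # near 0.3/0.05/0.7 and the frontal delta coherence near 0.1/0.6/0.1 in
  # WAKE/NREM/REM under the default amplitudes (closed form:
  # C = (c a)^2/B / ((c a)^2/B + 2 emg_amp^2/fs), B the band width).
  occ <- zero
  occ["WAKE", "theta"] <- 0.0037
  occ["NREM", "theta"] <- 0.0012
  occ["REM", "theta"] <- 0.0013
  fro <- zero
  fro["WAKE", "delta"] <- 0.0021
  fro["NREM", "delta"] <- 0.0018
  fro["REM", "delta"] <- 0.00033
  list(frontal = fro, occipital = occ)
}

#' @export
print.somno_config <- function(x, ...) {
  cat("<somno_config>\n")
  cat(sprintf("  fs %g Hz, duration %g s, epoch %g s (%d epochs)\n",
              x$fs, x$duration_s, x$epoch_len_s,
              floor(x$duration_s / x$epoch_len_s)))
  cat(sprintf("  stationary WAKE/NREM/REM: %s\n",
              paste(sprintf("%.3f", x$state_stationary), collapse = "/")))
  cat(sprintf("  mean bout durations: %s s\n",
              paste(x$state_mean_dur_s, collapse = "/")))
  cat(sprintf("  EMG scale: %s; noise floor %g\n",
              paste(x$emg_amp, collapse = "/"), x$noise_floor))
  invisible(x)
}

# Solve the embedded (bout-to-bout) transition probabilities that make the
# semi-Markov chain's long-run occupancy match `state_stationary` given the
# configured mean bout durations. Visit rates are proportional to
# proportion / mean duration; the free branch probabilities are
# q = P(NREM -> REM), r = P(REM -> WAKE) and w = P(WAKE -> REM)
# (w fixed: 0 under the REM-after-NREM constraint, else 0.2).
solve_transitions <- function(config) {
  p <- config$state_stationary
  m <- config$state_mean_dur_s
  pi_v <- (p / m) / (p["NREM"] / m["NREM"])  # visit rates, NREM = 1
  w <- if (config$rem_after_nrem_only) 0 else 0.2
  q <- unname(pi_v["REM"] - pi_v["WAKE"] * w)
  r <- unname((pi_v["WAKE"] - (1 - q)) / pi_v["REM"])
  if (!is.finite(q) || !is.finite(r) || q < 0 || q > 1 || r < 0 || r > 1) {
    stop("state_mean_dur_s and state_stationary are incompatible: ",
         "no valid bout transition probabilities exist", call. = FALSE)
  }
  # rows: current state; columns: next state (no self-transitions)
  P <- rbind(
    WAKE = c(0, 1 - w, w),
    NREM = c(1 - q, 0, q),
    REM  = c(r, 1 - r, 0)
  )
  colnames(P) <- vigilance_states()
  P
}

#' Sample a ground-truth hypnogram
#'
#' Draws a semi-Markov sequence of vigilance-state bouts: bout durations are
#' geometric at epoch granularity around the configured per-state means, and
#' bout-to-bout transitions are solved so that long-run state occupancy
#' converges to `config$state_stationary`. By default REM can only be entered
#' from NREM.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; the result is fully determined by it.
#' @return An object of class `somno_hypnogram`: a list with `epoch_len_s`
#'   and `labels`, a factor over WAKE/NREM/REM with one entry per epoch
#'   (`floor(duration_s / epoch_len_s)` entries).
#' @examples
#' h <- sample_hypnogram(generator_config(duration_s = 600), seed = 1)
#' table(h$labels)
#' @export
sample_hypnogram <- function(config, seed) {
  stopifnot(inherits(config, "somno_config"))
  n_epochs <- floor(config$duration_s / config$epoch_len_s)
  if (n_epochs < 1) {
    stop("duration shorter than one epoch", call. = FALSE)
  }
  if (any(config$state_mean_dur_s < config$epoch_len_s)) {
    stop("state_mean_dur_s must be >= epoch_len_s for all states", call. = FALSE)
  }
  states <- vigilance_states()
  P <- solve_transitions(config)
  mean_ep <- config$state_mean_dur_s / config$epoch_len_s
  labels <- with_seed(seed, {
    out <- integer(0)
    s <- sample(3L, 1L, prob = config$state_stationary)
    while (length(out) < n_epochs) {
      len <- stats::rgeom(1L, 1 / mean_ep[s]) + 1L
      out <- c(out, rep.int(s, len))
      s <- sample(3L, 1L, prob = P[s, ])
    }
    out[seq_len(n_epochs)]
  })
  structure(
    list(epoch_len_s = config$epoch_len_s,
         labels = factor(states[labels], levels = states)),
    class = "somno_hypnogram"
  )
}

#' @export
print.somno_hypnogram <- function(x, ...) {
  cat(sprintf("<somno_hypnogram> %d epochs x %g s\n",
              length(x$labels), x$epoch_len_s))
  print(table(x$labels))
  invisible(x)
}

# Unit-variance band-limited Gaussian noise, synthesized in the frequency
# domain: a complex Gaussian spectrum restricted to [low, high] Hz, inverse
# transformed. Exactly flat in-band power spectral density 1/(high - low).
band_noise <- function(n, fs, low, high) {
  k <- seq_len(floor((n - 1) / 2))
  f <- k * fs / n
  inband <- which(f >= low & f <= high)
  m <- length(inband)
  if (m == 0L) return(numeric(n))
  X <- complex(length.out = n)
  z <- complex(real = rnorm(m), imaginary = rnorm(m))
  X[inband + 1L] <- z
  X[n - inband + 1L] <- Conj(z)
  Re(fft(X, inverse = TRUE)) / (2 * sqrt(m))
}

# Per-sample gain envelope from per-state values: piecewise constant over
# epochs with a raised-cosine cross-fade of `fade_s` seconds centred on each
# boundary where the gain changes, suppressing boundary broadband leakage.
state_envelope <- function(values3, state_idx_epoch, samples_per_epoch, n,
                           fs, fade_s = 0.1) {
  g_epoch <- unname(values3)[state_idx_epoch]
  env <- rep(g_epoch, each = samples_per_epoch)
  if (length(env) < n) env <- c(env, rep(env[length(env)], n - length(env)))
  env <- env[seq_len(n)]
  fade <- round(fade_s * fs)
  if (fade >= 2) {
    half <- fade %/% 2
    w <- 0.5 * (1 - cos(pi * seq_len(fade) / (fade + 1)))
    chg <- which(diff(g_epoch) != 0)
    for (b in chg) {
      p <- b * samples_per_epoch
      lo <- p - half + 1L
      hi <- lo + fade - 1L
      if (lo >= 1L && hi <= n) {
        env[lo:hi] <- g_epoch[b] * (1 - w) + g_epoch[b + 1L] * w
      }
    }
  }
  env
}

#' Synthesize one ECoG/EMG recording from a hypnogram
#'
#' Builds the three channels sample by sample from the state sequence. Each
#' ECoG channel is a sum over the seven bands of band-limited Gaussian
#' sources with state-dependent RMS amplitude (`band_amp`, times
#' `lesion_mod` on the frontal channel for lesion-group animals) plus a
#' white-noise floor. The EMG is broadband Gaussian noise scaled by
#' `emg_amp[state]`; in addition, each band source is injected into the EMG
#' with weight `coupling[site][state][band]` times its ECoG amplitude, which
#' yields a controllable corticomuscular coherence with a closed-form
#' expected value. Gain envelopes are cross-faded over 0.1 s at epoch
#' boundaries.
#'
#' @param config A [generator_config()].
#' @param hypnogram A [sample_hypnogram()] result consistent with `config`.
#' @param group `"sham"` or `"lesion"`.
#' @param seed Integer seed; the recording is fully determined by it.
#' @param rat_id Identifier stored in the recording.
#' @return An object of class `somno_recording`: list with `rat_id`, `group`,
#'   `fs`, and numeric channels `frontal`, `occipital`, `emg` of length
#'   `fs * duration_s`.
#' @examples
#' cfg <- generator_config(duration_s = 60)
#' h <- sample_hypnogram(cfg, seed = 1)
#' r <- synthesize_recording(cfg, h, "sham", seed = 2)
#' length(r$emg) / cfg$fs
#' @export
synthesize_recording <- function(config, hypnogram, group = c("sham", "lesion"),
                                 seed, rat_id = "rat") {
  stopifnot(inherits(config, "somno_config"),
            inherits(hypnogram, "somno_hypnogram"))
  group <- match.arg(group)
  n_epochs <- floor(config$duration_s / config$epoch_len_s)
  if (length(hypnogram$labels) != n_epochs ||
      hypnogram$epoch_len_s != config$epoch_len_s) {
    stop("hypnogram is inconsistent with the generator config", call. = FALSE)
  }
  n <- round(config$fs * config$duration_s)
  L <- round(config$fs * config$epoch_len_s)
  bands <- band_scheme()
  st_idx <- as.integer(hypnogram$labels)

  rat_sd <- if (is.null(config$rat_sd)) 0 else config$rat_sd
  channels <- with_seed(seed, {
    # rat-specific heterogeneity factors, drawn first so channel synthesis
    # consumes the RNG stream identically for every rat_sd
    rat_fac <- list(
      frontal = matrix(exp(rnorm(21, 0, rat_sd)), 3, 7),
      occipital = matrix(exp(rnorm(21, 0, rat_sd)), 3, 7)
    )
    emg_fac <- exp(rnorm(3, 0, rat_sd / 2))
    emg_shared <- numeric(n)
    ecog <- list()
    for (site in c("frontal", "occipital")) {
      amp <- config$band_amp[[site]] * rat_fac[[site]]
      if (site == "frontal" && group == "lesion") {
        amp <- amp * config$lesion_mod
      }
      acc <- config$noise_floor * rnorm(n)
      for (b in seq_len(nrow(bands))) {
        s <- band_noise(n, config$fs, bands$low[b], bands$high[b])
        a_env <- state_envelope(amp[, b], st_idx, L, n, config$fs)
        acc <- acc + a_env * s
        cpl <- config$coupling[[site]][, b]
        if (any(cpl > 0)) {
          c_env <- state_envelope(amp[, b] * cpl, st_idx, L, n, config$fs)
          emg_shared <- emg_shared + c_env * s
        }
      }
      ecog[[site]] <- acc
    }
    e_env <- state_envelope(config$emg_amp * emg_fac, st_idx, L, n, config$fs)
    list(frontal = ecog$frontal, occipital = ecog$occipital,
         emg = e_env * rnorm(n) + emg_shared)
  })

  structure(
    c(list(rat_id = rat_id, group = group, fs = config$fs), channels),
    class = "somno_recording"
  )
}

#' @export
print.somno_recording <- function(x, ...) {
  cat(sprintf("<somno_recording> %s (%s): 3 channels x %d samples @ %g Hz\n",
              x$rat_id, x$group, length(x$emg), x$fs))
  invisible(x)
}

#' Generate a cohort of annotated recordings
#'
#' Draws `n_sham + n_lesion` rats, each with its own hypnogram and recording,
#' using per-rat seeds derived deterministically from `seed`.
#'
#' @param config A [generator_config()].
#' @param n_sham,n_lesion Number of sham / lesion animals (>= 0).
#' @param seed Master integer seed.
#' @return An object of class `somno_cohort`: a list of elements
#'   `list(recording =, hypnogram =)` with unique `rat_id`s
#'   (`sham_1 ... , lesion_1 ...`).
#' @examples
#' cfg <- generator_config(duration_s = 60)
#' coh <- generate_cohort(cfg, n_sham = 1, n_lesion = 1, seed = 7)
#' vapply(coh, function(x) x$recording$rat_id, "")
#' @export
generate_cohort <- function(config, n_sham = 9, n_lesion = 9, seed = 1) {
  stopifnot(inherits(config, "somno_config"))
  if (n_sham < 0 || n_lesion < 0) {
    stop("n_sham and n_lesion must be >= 0", call. = FALSE)
  }
  groups <- c(rep("sham", n_sham), rep("lesion", n_lesion))
  ids <- c(sprintf("sham_%d", seq_len(n_sham)),
           sprintf("lesion_%d", seq_len(n_lesion)))
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    hyp <- sample_hypnogram(config, seed = derive_seed(seed, i, 1L))
    rec <- synthesize_recording(config, hyp, groups[i],
                                seed = derive_seed(seed, i, 2L),
                                rat_id = ids[i])
    out[[i]] <- list(recording = rec, hypnogram = hyp)
  }
  structure(out, class = "somno_cohort")
}

#' @export
print.somno_cohort <- function(x, ...) {
  grp <- vapply(x, function(e) e$recording$group, "")
  cat(sprintf("<somno_cohort> %d rats (%d sham, %d lesion)\n",
              length(x), sum(grp == "sham"), sum(grp == "lesion")))
  invisible(x)
}
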