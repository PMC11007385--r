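# Per-epoch feature extraction: conditioning filters, Welch spectra,
# band powers, EMG amplitude and corticomuscular coherence.

#' Power-line notch filter
#'
#' Second-order IIR notch (quality factor `q`) applied zero-phase with
#' [signal::filtfilt()]: narrow rejection at `freq` with negligible
#' pass-band distortion.
#'
#' @param x Numeric amplitude series.
#' @param fs Sampling rate, Hz.
#' @param freq Notch centre frequency, Hz (default 50, power-line).
#' @param q Quality factor (centre / -3 dB width).
#' @return Filtered series, same length as `x`.
#' @examples
#' t <- seq(0, 1, by = 1 / 1000)
#' y <- notch_filter(sin(2 * pi * 50 * t), fs = 1000)
#' sqrt(mean(y^2))  # 50 Hz tone almost removed
#' @export
notch_filter <- function(x, fs, freq = 50, q = 30) {
  check_scalar_number(fs, "fs")
  if (freq <= 0 || freq >= fs / 2) {
    stop("notch frequency must lie in (0, fs/2)", call. = FALSE)
  }
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::filtfilt(signal::Arma(b = b / a[1], a = a / a[1]), x)
}

#' EMG conditioning band-pass
#'
#' 4th-order Butterworth band-pass (default 20--200 Hz), applied zero-phase.
#'
#' @inheritParams notch_filter
#' @param low,high Band edges, Hz; `0 < low < high < fs/2`.
#' @return Filtered series, same length as `x`.
#' @export
bandpass_emg <- function(x, fs, low = 20, high = 200) {
  check_scalar_number(fs, "fs")
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Split a signal or recording into fixed-length epochs
#'
#' Non-overlapping, contiguous, half-open windows of `epoch_len_s` seconds;
#' a trailing partial window is discarded.
#'
#' @param x Numeric series or a `somno_recording`.
#' @param fs Sampling rate (ignored for recordings, which carry their own).
#' @param epoch_len_s Epoch length, seconds.
#' @return For a numeric series, a `samples x epochs` matrix (zero columns,
#'   with a warning, if the input is shorter than one epoch). For a
#'   recording, a list with matrices `frontal`, `occipital`, `emg` and the
#'   epoch count `n_epochs`.
#' @examples
#' ncol(segment_epochs(rnorm(25 * 100), fs = 100, epoch_len_s = 10))  # 2
#' @export
segment_epochs <- function(x, fs = NULL, epoch_len_s = 10) {
  if (inherits(x, "somno_recording")) {
    mats <- lapply(x[c("frontal", "occipital", "emg")], segment_epochs,
                   fs = x$fs, epoch_len_s = epoch_len_s)
    return(c(mats, list(n_epochs = ncol(mats$emg))))
  }
  check_scalar_number(epoch_len_s, "epoch_len_s")
  check_scalar_number(fs, "fs")
  L <- round(fs * epoch_len_s)
  k <- floor(length(x) / L)
  if (k == 0L) {
    warning("signal shorter than one epoch; returning no epochs")
    return(matrix(numeric(0), nrow = L, ncol = 0))
  }
  matrix(x[seq_len(k * L)], nrow = L, ncol = k)
}

# Windowed FFT matrix for the Welch estimator: Hann windows of `window_s`
# seconds at `overlap` fractional overlap. Returns complex matrix
# (frequency bins x windows) plus the scale that converts |X|^2 sums into
# one-sided PSD density.
welch_fft <- function(x, fs, window_s = 1, overlap = 0.5) {
  N <- round(window_s * fs)
  if (length(x) < N) stop("epoch shorter than one Welch window", call. = FALSE)
  step <- max(1L, round(N * (1 - overlap)))
  starts <- seq(0L, length(x) - N, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(N) / N))  # periodic Hann
  idx <- outer(seq_len(N), starts, `+`)
  M <- matrix(x[idx], nrow = N) * w
  X <- mvfft(M)
  nf <- N %/% 2 + 1L
  list(X = X[seq_len(nf), , drop = FALSE],
       freq = (seq_len(nf) - 1L) * fs / N,
       K = length(starts),
       # one-sided density scale; interior bins are doubled by the caller
       scale = 1 / (fs * sum(w^2)))
}

# Averaged one-sided auto-PSD from a welch_fft result.
welch_psd <- function(wf) {
  P <- rowMeans(Re(wf$X * Conj(wf$X))) * wf$scale
  nf <- length(P)
  P[2:(nf - 1L)] <- 2 * P[2:(nf - 1L)]
  P
}

# indices of PSD bins whose centre frequency lies inside each band;
# a bin tied exactly on a 0.5-Hz edge belongs to the lower band
band_bin_index <- function(freq, bands) {
  lapply(seq_len(nrow(bands)), function(b) {
    which(freq >= bands$low[b] & freq <= bands$high[b])
  })
}

#' Mean spectral power in the seven bands
#'
#' Welch power spectral density of one epoch (1-s Hann windows, 50\%
#' overlap -> 1 Hz resolution, 19 windows for a 10-s epoch), then the mean
#' of the one-sided PSD bins whose centre frequency falls inside each band.
#' Units: amplitude squared per Hz.
#'
#' @param x Numeric epoch (>= 2 s of signal).
#' @param fs Sampling rate, Hz; `fs/2` must reach the highest band edge.
#' @param bands A [band_scheme()]-style data frame.
#' @param window_s,overlap Welch window length (s) and fractional overlap.
#' @return Named numeric vector of 7 nonnegative band powers.
#' @examples
#' fs <- 1000
#' x <- sin(2 * pi * 6 * seq_len(10 * fs) / fs)
#' which.max(band_power(x, fs))  # theta
#' @export
band_power <- function(x, fs, bands = band_scheme(), window_s = 1,
                       overlap = 0.5) {
  check_bands(bands)
  if (length(x) < 2 * fs) stop("epoch must be at least 2 s long", call. = FALSE)
  if (fs / 2 < max(bands$high)) {
    stop("fs/2 below the highest band edge", call. = FALSE)
  }
  wf <- welch_fft(x, fs, window_s, overlap)
  P <- welch_psd(wf)
  idx <- band_bin_index(wf$freq, bands)
  out <- vapply(idx, function(i) mean(P[i]), numeric(1))
  names(out) <- bands$band
  out
}

#' Mean absolute EMG amplitude of an epoch
#'
#' @param x Non-empty numeric epoch (typically the band-passed EMG).
#' @return `mean(abs(x))`.
#' @export
emg_amplitude <- function(x) {
  if (length(x) == 0L) stop("empty epoch", call. = FALSE)
  mean(abs(x))
}

#' Band-averaged corticomuscular coherence
#'
#' Magnitude-squared coherence
#' \eqn{C(f) = |S_{xy}(f)|^2 / (S_{xx}(f) S_{yy}(f))} estimated with
#' averaged overlapping Hann windows (same estimator settings as
#' [band_power()]), then averaged over the bins of each band. A silent
#' (all-zero) channel yields 0 in every band with a warning rather than an
#' error, keeping batch extraction total.
#'
#' @param x,y Equal-length numeric epochs (ECoG and EMG).
#' @inheritParams band_power
#' @return Named numeric vector of 7 values in \[0, 1\].
#' @export
coherence_bands <- function(x, y, fs, bands = band_scheme(), window_s = 1,
                            overlap = 0.5) {
  check_bands(bands)
  if (length(x) != length(y)) stop("epoch length mismatch", call. = FALSE)
  if (all(x == 0) || all(y == 0)) {
    warning("silent channel: coherence undefined, returning 0")
    return(stats::setNames(numeric(nrow(bands)), bands$band))
  }
  wx <- welch_fft(x, fs, window_s, overlap)
  wy <- welch_fft(y, fs, window_s, overlap)
  if (wx$K < 4L) stop("epoch too short for >= 4 averaging windows", call. = FALSE)
  Sxx <- rowMeans(Re(wx$X * Conj(wx$X)))
  Syy <- rowMeans(Re(wy$X * Conj(wy$X)))
  Sxy <- rowMeans(wx$X * Conj(wy$X))
  C <- Mod(Sxy)^2 / (Sxx * Syy)
  C[!is.finite(C)] <- 0
  C <- pmin(pmax(C, 0), 1)
  idx <- band_bin_index(wx$freq, bands)
  out <- vapply(idx, function(i) mean(C[i]), numeric(1))
  names(out) <- bands$band
  out
}

feature_columns <- function(bands = band_scheme()$band) {
  c(paste0("pow_frontal_", bands), paste0("pow_occipital_", bands),
    "emg_amp",
    paste0("cmc_frontal_", bands), paste0("cmc_occipital_", bands))
}

#' Extract the per-epoch feature table of a recording
#'
#' Applies the 50-Hz notch to all three channels, cuts them into identical
#' epochs, and computes per epoch: the seven band powers for each ECoG
#' site, the mean absolute amplitude of the 20--200 Hz band-passed EMG, and
#' the seven band-averaged corticomuscular coherence values for each site.
#' Coherence is computed against the notch-filtered (not band-passed) EMG:
#' the delta and theta coherence bands lie below the EMG conditioning
#' pass-band, where a band-passed EMG retains only filter leakage.
#' State labels are attached when a hypnogram is supplied.
#'
#' @param recording A `somno_recording`.
#' @param hypnogram Optional `somno_hypnogram` whose epoch count matches the
#'   recording.
#' @param bands A [band_scheme()]-style data frame.
#' @param epoch_len_s Epoch length, seconds.
#' @param notch_freq Power-line frequency for [notch_filter()].
#' @param emg_band Length-2 numeric, [bandpass_emg()] edges.
#' @return A data frame of class `somno_features`: columns `rat_id`, `group`,
#'   `state` (`NA` when no hypnogram), `pow_<site>_<band>` (14), `emg_amp`,
#'   `cmc_<site>_<band>` (14); one row per complete epoch.
#' @export
extract_features <- function(recording, hypnogram = NULL,
                             bands = band_scheme(), epoch_len_s = 10,
                             notch_freq = 50, emg_band = c(20, 200)) {
  stopifnot(inherits(recording, "somno_recording"))
  check_bands(bands)
  fs <- recording$fs
  fro <- notch_filter(recording$frontal, fs, notch_freq)
  occ <- notch_filter(recording$occipital, fs, notch_freq)
  emg_raw <- notch_filter(recording$emg, fs, notch_freq)
  emg_bp <- bandpass_emg(recording$emg, fs, emg_band[1], emg_band[2])
  Mf <- segment_epochs(fro, fs, epoch_len_s)
  Mo <- segment_epochs(occ, fs, epoch_len_s)
  Me <- segment_epochs(emg_raw, fs, epoch_len_s)
  Mb <- segment_epochs(emg_bp, fs, epoch_len_s)
  n_ep <- ncol(Me)
  if (!is.null(hypnogram)) {
    stopifnot(inherits(hypnogram, "somno_hypnogram"))
    if (length(hypnogram$labels) != n_ep) {
      stop("hypnogram epoch count does not match the recording", call. = FALSE)
    }
  }
  cols <- feature_columns(bands$band)
  out <- matrix(NA_real_, nrow = n_ep, ncol = length(cols),
                dimnames = list(NULL, cols))
  nb <- nrow(bands)
  for (e in seq_len(n_ep)) {
    wf_f <- welch_fft(Mf[, e], fs)
    wf_o <- welch_fft(Mo[, e], fs)
    wf_e <- welch_fft(Me[, e], fs)
    idx <- band_bin_index(wf_f$freq, bands)
    Pf <- welch_psd(wf_f); Po <- welch_psd(wf_o)
    Sff <- rowMeans(Re(wf_f$X * Conj(wf_f$X)))
    Soo <- rowMeans(Re(wf_o$X * Conj(wf_o$X)))
    See <- rowMeans(Re(wf_e$X * Conj(wf_e$X)))
    Cf <- Mod(rowMeans(wf_f$X * Conj(wf_e$X)))^2 / (Sff * See)
    Co <- Mod(rowMeans(wf_o$X * Conj(wf_e$X)))^2 / (Soo * See)
    Cf[!is.finite(Cf)] <- 0; Co[!is.finite(Co)] <- 0
    Cf <- pmin(pmax(Cf, 0), 1); Co <- pmin(pmax(Co, 0), 1)
    for (b in seq_len(nb)) {
      out[e, b] <- mean(Pf[idx[[b]]])
      out[e, nb + b] <- mean(Po[idx[[b]]])
      out[e, 2 * nb + 1 + b] <- mean(Cf[idx[[b]]])
      out[e, 3 * nb + 1 + b] <- mean(Co[idx[[b]]])
    }
    out[e, 2 * nb + 1] <- mean(abs(Mb[, e]))
  }
  df <- data.frame(
    rat_id = recording$rat_id,
    group = recording$group,
    state = if (is.null(hypnogram)) NA_character_
            else as.character(hypnogram$labels[seq_len(n_ep)]),
    out,
    stringsAsFactors = FALSE
  )
  attr(df, "normalized") <- FALSE
  class(df) <- c("somno_features", "data.frame")
  df
}

#' Extract and stack features for a whole cohort
#'
#' @param cohort A `somno_cohort` from [generate_cohort()].
#' @param ... Passed on to [extract_features()].
#' @return A `somno_features` data frame with one row per epoch per rat.
#' @export
extract_cohort_features <- function(cohort, ...) {
  stopifnot(inherits(cohort, "somno_cohort"))
  tabs <- lapply(cohort, function(e) {
    extract_features(e$recording, e$hypnogram, ...)
  })
  out <- do.call(rbind, tabs)
  attr(out, "normalized") <- FALSE
  class(out) <- c("somno_features", "data.frame")
  out
}

#' Per-rat min--max normalization of the feature table
#'
#' Scales every feature column to \[0, 1\] within each recording (each
#' `rat_id`), so no statistic leaks between animals or between train and
#' test sets; a constant column maps to 0. Columns listed in `keep_raw` are
#' additionally retained unscaled under a `raw_` prefix (default: frontal
#' high-gamma power, whose group contrast is uniform across states and is
#' therefore erased by per-rat scaling).
#'
#' @param table A `somno_features` data frame.
#' @param keep_raw Character vector of feature columns to copy unscaled.
#' @param scope `"rat"` (default) scales within each recording; `"cohort"`
#'   scales over the pooled table.
#' @return The normalized table; `attr(, "normalized")` is `TRUE` and raw
#'   copies appear as `raw_<name>` columns.
#' @export
normalize_features <- function(table, keep_raw = "pow_frontal_hgamma",
                               scope = c("rat", "cohort")) {
  stopifnot(inherits(table, "somno_features"), nrow(table) > 0)
  scope <- match.arg(scope)
  feat <- intersect(feature_columns(), names(table))
  missing_raw <- setdiff(keep_raw, names(table))
  if (length(missing_raw)) {
    stop("keep_raw columns not present: ", paste(missing_raw, collapse = ", "),
         call. = FALSE)
  }
  for (col in keep_raw) {
    table[[paste0("raw_", col)]] <- table[[col]]
  }
  grp <- if (scope == "rat") table$rat_id else rep("all", nrow(table))
  for (g in unique(grp)) {
    i <- which(grp == g)
    for (col in feat) {
      v <- table[[col]][i]
      rng <- range(v)
      table[[col]][i] <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1])
                         else 0
    }
  }
  attr(table, "normalized") <- TRUE
  table
}
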