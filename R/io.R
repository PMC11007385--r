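# On-disk formats: EDF recordings (with a plain-CSV fallback), hypnogram
# and feature-table CSVs, generator configuration JSON, model archives.

# fixed-width ASCII field, right-padded; numbers are reformatted until they
# fit so the written value is exactly the one used for scaling
edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

edf_num <- function(x, width = 8) {
  digits <- 7
  s <- formatC(x, format = "g", digits = digits)
  while (nchar(s) > width && digits > 1) {
    digits <- digits - 1
    s <- formatC(x, format = "g", digits = digits)
  }
  s
}

#' Write a recording to EDF
#'
#' Minimal continuous EDF: one file per rat with channels FRONTAL,
#' OCCIPITAL and EMG in microvolts, 1-s data records, 16-bit samples scaled
#' to each channel's physical range. A trailing partial second is dropped.
#'
#' @param recording A `somno_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "somno_recording"))
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export needs integer fs", call. = FALSE)
  fs <- as.integer(round(fs))
  chans <- list(FRONTAL = recording$frontal, OCCIPITAL = recording$occipital,
                EMG = recording$emg)
  ndr <- min(vapply(chans, length, 0L)) %/% fs
  if (ndr < 1) stop("recording shorter than one data record", call. = FALSE)
  ns <- length(chans)

  phys <- lapply(chans, function(x) {
    r <- range(x[seq_len(ndr * fs)])
    if (r[1] == r[2]) r[2] <- r[1] + 1
    # round-trip through the 8-char ASCII representation
    c(as.numeric(edf_num(r[1])) - abs(r[1]) * 1e-6 - 1e-9,
      as.numeric(edf_num(r[2])) + abs(r[2]) * 1e-6 + 1e-9)
  })

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_field(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr(sprintf("%s %s", recording$rat_id, recording$group), 80)
  wr("somnopark synthetic recording", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256L * (ns + 1L)), 8)
  wr("", 44)
  wr(as.character(ndr), 8)
  wr("1", 8)
  wr(as.character(ns), 4)
  for (nm in names(chans)) wr(nm, 16)
  for (nm in names(chans)) wr("synthetic", 80)
  for (nm in names(chans)) wr("uV", 8)
  for (nm in names(chans)) wr(edf_num(phys[[nm]][1]), 8)
  for (nm in names(chans)) wr(edf_num(phys[[nm]][2]), 8)
  for (nm in names(chans)) wr("-32768", 8)
  for (nm in names(chans)) wr("32767", 8)
  for (nm in names(chans)) wr("none", 80)
  for (nm in names(chans)) wr(as.character(fs), 8)
  for (nm in names(chans)) wr("", 32)

  dig <- array(0L, dim = c(fs, ns, ndr))
  for (s in seq_len(ns)) {
    x <- chans[[s]][seq_len(ndr * fs)]
    pm <- as.numeric(edf_num(phys[[s]][1])); px <- as.numeric(edf_num(phys[[s]][2]))
    d <- as.integer(round((x - pm) / (px - pm) * 65535 - 32768))
    dig[, s, ] <- pmin(pmax(d, -32768L), 32767L)
  }
  writeBin(as.vector(dig), con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads a continuous EDF file with equal sampling rate on every channel.
#' Channels named FRONTAL/OCCIPITAL/EMG are mapped back onto a
#' `somno_recording`; otherwise the first three channels are used in order.
#'
#' @param path EDF file path.
#' @param rat_id,group Metadata for the returned recording; defaults parse
#'   the patient-id header field written by [write_edf()].
#' @return A `somno_recording`.
#' @export
read_edf <- function(path, rat_id = NULL, group = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                       # version
  patient <- rd(80)
  rd(80); rd(8); rd(8)        # recording id, date, time
  rd(8)                       # header bytes
  rd(44)
  ndr <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)       # transducer
  for (i in seq_len(ns)) rd(8)        # dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)       # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)

  raw <- readBin(con, integer(), n = ndr * sum(spr), size = 2L,
                 endian = "little")
  dat <- vector("list", ns)
  for (s in seq_len(ns)) dat[[s]] <- numeric(ndr * spr[s])
  off <- 0L
  for (r in seq_len(ndr)) {
    for (s in seq_len(ns)) {
      seg <- raw[(off + 1L):(off + spr[s])]
      dat[[s]][((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        (seg - dmin[s]) / (dmax[s] - dmin[s]) * (pmax_[s] - pmin_[s]) + pmin_[s]
      off <- off + spr[s]
    }
  }
  names(dat) <- labels
  pick <- function(nm, i) if (nm %in% labels) dat[[nm]] else dat[[i]]
  meta <- strsplit(patient, " ", fixed = TRUE)[[1]]
  if (is.null(rat_id)) rat_id <- if (length(meta) >= 1) meta[1] else "rat"
  if (is.null(group)) {
    group <- if (length(meta) >= 2 && meta[2] %in% c("sham", "lesion")) {
      meta[2]
    } else "sham"
  }
  structure(
    list(rat_id = rat_id, group = group, fs = spr[1] / dur,
         frontal = pick("FRONTAL", 1), occipital = pick("OCCIPITAL", 2),
         emg = pick("EMG", 3)),
    class = "somno_recording"
  )
}

#' Hypnogram CSV input/output
#'
#' Columns: `epoch_index` (0-based), `onset_s`, `label` in WAKE/NREM/REM.
#'
#' @param hypnogram A `somno_hypnogram`.
#' @param path CSV file path.
#' @param epoch_len_s Fallback epoch length when a read file holds a single
#'   epoch (otherwise inferred from onsets).
#' @return `write_hypnogram_csv()`: the path, invisibly;
#'   `read_hypnogram_csv()`: a `somno_hypnogram`.
#' @export
write_hypnogram_csv <- function(hypnogram, path) {
  stopifnot(inherits(hypnogram, "somno_hypnogram"))
  n <- length(hypnogram$labels)
  df <- data.frame(epoch_index = seq_len(n) - 1L,
                   onset_s = (seq_len(n) - 1L) * hypnogram$epoch_len_s,
                   label = as.character(hypnogram$labels))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @export
read_hypnogram_csv <- function(path, epoch_len_s = 10) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("epoch_index", "onset_s", "label") %in% names(df)))
  bad <- setdiff(unique(df$label), vigilance_states())
  if (length(bad)) {
    stop("unknown state labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) >= 2) epoch_len_s <- as.numeric(df$onset_s[2] - df$onset_s[1])
  epoch_len_s <- as.numeric(epoch_len_s)
  structure(
    list(epoch_len_s = epoch_len_s,
         labels = factor(df$label, levels = vigilance_states())),
    class = "somno_hypnogram"
  )
}

#' Feature-table CSV input/output
#'
#' @param table A `somno_features` data frame.
#' @param path CSV file path.
#' @return `write_features_csv()`: the path, invisibly;
#'   `read_features_csv()`: a `somno_features` data frame (normalization
#'   state inferred from the presence of `raw_` columns).
#' @export
write_features_csv <- function(table, path) {
  stopifnot(inherits(table, "somno_features"))
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  attr(df, "normalized") <- any(grepl("^raw_", names(df)))
  class(df) <- c("somno_features", "data.frame")
  df
}

#' Plain-CSV recording fallback
#'
#' Three columns `frontal`, `occipital`, `emg`, one row per sample.
#'
#' @param recording A `somno_recording`.
#' @param path CSV file path.
#' @param fs,rat_id,group Metadata applied when reading.
#' @return `write_recording_csv()`: the path, invisibly;
#'   `read_recording_csv()`: a `somno_recording`.
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "somno_recording"))
  write.csv(data.frame(frontal = recording$frontal,
                       occipital = recording$occipital,
                       emg = recording$emg),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path, fs = 1000, rat_id = "rat", group = "sham") {
  df <- read.csv(path)
  stopifnot(all(c("frontal", "occipital", "emg") %in% names(df)))
  structure(list(rat_id = rat_id, group = group, fs = fs,
                 frontal = df$frontal, occipital = df$occipital,
                 emg = df$emg),
            class = "somno_recording")
}

#' Generator configuration JSON input/output
#'
#' @param config A [generator_config()].
#' @param path JSON file path.
#' @return `write_generator_config()`: the path, invisibly;
#'   `read_generator_config()`: a validated `somno_config`.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "somno_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  generator_config(
    fs = as.numeric(x$fs), duration_s = as.numeric(x$duration_s),
    epoch_len_s = as.numeric(x$epoch_len_s),
    state_mean_dur_s = stats::setNames(unlist(x$state_mean_dur_s),
                                       vigilance_states()),
    state_stationary = stats::setNames(unlist(x$state_stationary),
                                       vigilance_states()),
    band_amp = x$band_amp, lesion_mod = x$lesion_mod,
    emg_amp = stats::setNames(unlist(x$emg_amp), vigilance_states()),
    coupling = x$coupling, noise_floor = as.numeric(x$noise_floor),
    rat_sd = if (is.null(x$rat_sd)) 0.1 else as.numeric(x$rat_sd),
    rem_after_nrem_only = x$rem_after_nrem_only
  )
}

#' Save / load a trained model archive
#'
#' A directory holding `model.json` (task, selected hyperparameters,
#' feature list, class levels, package version) next to `fit.rds`, the
#' fitted kernel machine.
#'
#' @param model A `somno_model`.
#' @param dir Archive directory (created if needed).
#' @return `save_model()`: `dir`, invisibly; `load_model()`: a
#'   `somno_model`.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "somno_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(task = model$task, C = model$C, gamma = model$gamma,
               cv_accuracy = model$cv_accuracy, features = model$features,
               levels = model$levels,
               somnopark_version = as.character(utils::packageVersion("somnopark")))
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  saveRDS(model$fit, file.path(dir, "fit.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  structure(
    list(task = meta$task, fit = readRDS(file.path(dir, "fit.rds")),
         C = as.numeric(meta$C), gamma = as.numeric(meta$gamma),
         cv_accuracy = as.numeric(meta$cv_accuracy),
         features = meta$features, levels = meta$levels,
         tuning = NULL, config = NULL),
    class = "somno_model"
  )
}
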