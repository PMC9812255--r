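#' The 23-pair bipolar derivation table
#'
#' The standard longitudinal/transverse bipolar montage used throughout the
#' package: 23 electrode pairs over the 10-20 positions. Differencing
#' neighbouring electrodes suppresses the common reference and reduces (but
#' does not eliminate) volume-conduction effects.
#'
#' @return A data frame with columns `anode` and `cathode`, 23 rows, in the
#'   canonical channel order used for every adjacency matrix in the package.
#' @export
bipolar_pairs_23 <- function() {
  p <- matrix(c(
    "F8", "F4",  "F7", "F3",  "F4", "C4",  "F3", "C3",  "F4", "FZ",
    "FZ", "CZ",  "F3", "FZ",  "T4", "C4",  "T3", "C3",  "C4", "CZ",
    "C3", "CZ",  "CZ", "PZ",  "C4", "P4",  "C3", "P3",  "T4", "T6",
    "T3", "T5",  "P4", "PZ",  "P3", "PZ",  "T6", "O2",  "T5", "O1",
    "P4", "O2",  "P3", "O1",  "O1", "O2"), ncol = 2, byrow = TRUE)
  data.frame(anode = p[, 1], cathode = p[, 2], stringsAsFactors = FALSE)
}

#' Derivation labels of the default bipolar montage
#' @return Character vector of 23 labels such as `"F8-F4"`.
#' @export
bipolar_labels_23 <- function() {
  p <- bipolar_pairs_23()
  paste0(p$anode, "-", p$cathode)
}

#' Re-reference a recording to bipolar derivations
#'
#' Output channel i is `anode_i - cathode_i`; labels become `"A-B"` strings.
#' With the default table the result is the 23-derivation montage of
#' [bipolar_pairs_23()], in that fixed order.
#'
#' @param rec An `eeg_recording` whose labels include every electrode named
#'   in `pairs`.
#' @param pairs Data frame with columns `anode` and `cathode` (defaults to
#'   the 23-pair table).
#' @return An `eeg_recording` with one channel per pair.
#' @export
apply_bipolar_montage <- function(rec, pairs = bipolar_pairs_23()) {
  stopifnot(inherits(rec, "eeg_recording"))
  miss <- setdiff(unique(c(pairs$anode, pairs$cathode)), rec$channel_labels)
  if (length(miss)) {
    stop("montage error: electrode label(s) not in recording: ",
         paste(miss, collapse = ", "))
  }
  out <- rec$samples[pairs$anode, , drop = FALSE] -
         rec$samples[pairs$cathode, , drop = FALSE]
  recording(out, fs = rec$fs,
            channel_labels = paste0(pairs$anode, "-", pairs$cathode),
            subject_id = rec$subject_id, group = rec$group,
            eye_state = rec$eye_state)
}

#' Clinical EEG frequency bands
#'
#' Band edges in Hz: Delta 0.5-4, Theta 4-8, Alpha 8-13, Beta 13-30,
#' Gamma 30-48, Full 0.5-48. The full band's upper edge of 48 Hz doubles as
#' the anti-alias cutoff ahead of decimation to the 100 Hz working rate.
#'
#' @param name Optional band name; if given, a single-row data frame.
#' @return Data frame with columns `band`, `low_hz`, `high_hz`.
#' @export
eeg_bands <- function(name = NULL) {
  b <- data.frame(
    band = c("Delta", "Theta", "Alpha", "Beta", "Gamma", "Full"),
    low_hz = c(0.5, 4, 8, 13, 30, 0.5),
    high_hz = c(4, 8, 13, 30, 48, 48),
    stringsAsFactors = FALSE)
  if (is.null(name)) return(b)
  row <- b[match(tolower(name), tolower(b$band)), ]
  if (anyNA(row$band)) stop("unknown band: ", name)
  row
}

band_spec <- function(band) {
  if (is.character(band)) band <- eeg_bands(band)
  stopifnot(is.data.frame(band), all(c("low_hz", "high_hz") %in% names(band)))
  band
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass of the
#' given order to every channel. Zero-phase filtering preserves the phase
#' structure the phase-synchronisation estimators depend on.
#'
#' @param rec An `eeg_recording`.
#' @param band A band name (see [eeg_bands()]) or a data frame with
#'   `low_hz`/`high_hz`.
#' @param order Butterworth order (default 4).
#' @return The filtered recording (same shape and rate).
#' @export
bandpass_filter <- function(rec, band, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"), order >= 1L)
  band <- band_spec(band)
  nyq <- rec$fs / 2
  if (band$low_hz < 0 || band$high_hz <= band$low_hz || band$high_hz > nyq) {
    stop(sprintf("band [%g, %g] Hz invalid at fs = %g Hz (Nyquist %g)",
                 band$low_hz, band$high_hz, rec$fs, nyq))
  }
  wl <- band$low_hz / nyq
  wh <- min(band$high_hz / nyq, 0.999)
  bf <- if (wl <= 0) signal::butter(order, wh, type = "low")
        else signal::butter(order, c(wl, wh), type = "pass")
  out <- t(apply(rec$samples, 1, function(ch) signal::filtfilt(bf, ch)))
  rec$samples <- matrix(out, nrow = n_channels(rec),
                        dimnames = dimnames(rec$samples))
  rec
}

#' Anti-aliased resampling to a lower rate
#'
#' Low-pass filters (zero-phase Butterworth, cutoff at 80% of the target
#' Nyquist and never above 48 Hz) and then decimates by the integer factor
#' `fs / target_fs`. `target_fs == fs` is the identity.
#'
#' @param rec An `eeg_recording`.
#' @param target_fs Target rate in Hz; must divide `rec$fs`.
#' @param antialias_hz Anti-alias cutoff; default `min(48, 0.8 * target_fs/2)`.
#' @return The decimated recording with `fs = target_fs`.
#' @export
resample_recording <- function(rec, target_fs,
                               antialias_hz = min(48, 0.4 * target_fs)) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs > rec$fs) stop("target_fs exceeds the recording rate")
  if (target_fs == rec$fs) return(rec)
  ratio <- rec$fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("target_fs must divide the recording rate (integer decimation)")
  }
  ratio <- as.integer(round(ratio))
  bf <- signal::butter(8, antialias_hz / (rec$fs / 2), type = "low")
  filt <- t(apply(rec$samples, 1, function(ch) signal::filtfilt(bf, ch)))
  keep <- seq(1L, n_samples(rec), by = ratio)
  rec$samples <- matrix(filt[, keep], nrow = n_channels(rec),
                        dimnames = list(rec$channel_labels, NULL))
  rec$fs <- target_fs
  rec
}

#' Segment a recording into fixed-length windows
#'
#' Cuts each recording into consecutive windows of `window` samples
#' (optionally overlapping); any incomplete tail is discarded. Windows are
#' half-open 0-based sample ranges `[start, start + window)`. At the default
#' 25 samples and 100 Hz each window is a 0.25 s "mini-epoch", the unit
#' classification sample.
#'
#' @param rec An `eeg_recording`.
#' @param window Window length in samples (default 25).
#' @param overlap Overlap between consecutive windows in samples (default 0).
#' @param band Optional band tag to stamp on each window.
#' @param epoch_index Source-epoch index propagated into each window.
#' @return A list of `mini_epoch` objects (possibly empty), each holding
#'   `x` (channels x window matrix), `band`, `label`-free metadata
#'   (`subject_id`, `group`, `eye_state`, `epoch_index`, `window_index`).
#' @export
segment_epochs <- function(rec, window = 25L, overlap = 0L, band = NA,
                           epoch_index = 1L) {
  stopifnot(inherits(rec, "eeg_recording"), window >= 1L,
            overlap >= 0L, overlap < window)
  step <- window - overlap
  n <- n_samples(rec)
  count <- if (n < window) 0L else (n - overlap) %/% step
  if (count == 0L) return(list())
  band_name <- if (is.data.frame(band)) band$band else as.character(band)
  lapply(seq_len(count), function(k) {
    start <- (k - 1L) * step
    structure(
      list(x = rec$samples[, (start + 1L):(start + window), drop = FALSE],
           band = band_name, subject_id = rec$subject_id, group = rec$group,
           eye_state = rec$eye_state, epoch_index = epoch_index,
           window_index = k),
      class = "mini_epoch")
  })
}

#' @export
print.mini_epoch <- function(x, ...) {
  cat(sprintf("<mini_epoch> %d x %d  subject %s  group %s  %s  epoch %d  window %d\n",
              nrow(x$x), ncol(x$x), x$subject_id, x$group, x$eye_state,
              x$epoch_index, x$window_index))
  invisible(x)
}

#' Train/validation/test split with k-fold partition
#'
#' Two modes. `"mini-epoch"` selects `train_frac` of the windows *within
#' each source epoch stratum* (subject x eye state x epoch) for
#' training/validation and leaves the remainder as the test set, so every
#' epoch contributes to both sides; a k-fold partition is then drawn over
#' the train/validation indices. `"subject-hand-out"` assigns whole
#' subjects: `train_frac` of each group's subjects to train/validation, the
#' rest to test.
#'
#' @param meta Data frame with one row per sample and columns `subject_id`,
#'   `group`, `eye_state`, `epoch_index` (as produced by [build_dataset()]).
#' @param train_frac Fraction for train/validation (default 2/3).
#' @param k Number of cross-validation folds over train/validation
#'   (default 10).
#' @param seed Integer seed; the split is a pure function of `meta` and the
#'   seed.
#' @param mode `"mini-epoch"` or `"subject-hand-out"`.
#' @return An object of class `"dataset_split"`: list with integer vectors
#'   `train_val_ids`, `test_ids`, list `cv_folds` (disjoint, covering
#'   `train_val_ids`, sizes differing by at most one), and `seed`.
#' @export
split_dataset <- function(meta, train_frac = 2 / 3, k = 10L, seed = 1L,
                          mode = c("mini-epoch", "subject-hand-out")) {
  mode <- match.arg(mode)
  stopifnot(nrow(meta) > 0, train_frac > 0, train_frac < 1)
  set.seed(seed)
  idx <- seq_len(nrow(meta))
  if (mode == "mini-epoch") {
    strat <- interaction(meta$subject_id, meta$eye_state, meta$epoch_index,
                         drop = TRUE)
    train_val <- unlist(lapply(split(idx, strat), function(ii) {
      n_tr <- round(length(ii) * train_frac)
      sort(sample(ii, n_tr))
    }), use.names = FALSE)
    train_val <- sort(train_val)
  } else {
    train_val <- integer(0)
    for (g in unique(meta$group)) {
      subj <- unique(meta$subject_id[meta$group == g])
      n_tr <- round(length(subj) * train_frac)
      tr_subj <- sample(subj, n_tr)
      train_val <- c(train_val, idx[meta$group == g &
                                      meta$subject_id %in% tr_subj])
    }
    train_val <- sort(train_val)
  }
  test <- setdiff(idx, train_val)
  if (k > length(train_val)) {
    stop("k exceeds the size of the train/validation set")
  }
  shuffled <- sample(train_val)
  folds <- split(shuffled, rep_len(seq_len(k), length(shuffled)))
  folds <- lapply(unname(folds), sort)
  structure(list(train_val_ids = train_val, test_ids = test,
                 cv_folds = folds, seed = seed, mode = mode),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> mode %s: %d train/val + %d test, %d folds (seed %d)\n",
              x$mode, length(x$train_val_ids), length(x$test_ids),
              length(x$cv_folds), x$seed))
  invisible(x)
}
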