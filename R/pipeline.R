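# Fast single-window adjacency builders. These vectorise the exported
# pairwise estimators over all channel pairs of one window; tests assert
# they agree with the pairwise adjacency() route.

pc_matrix <- function(xw) {
  C <- suppressWarnings(stats::cor(t(xw)))
  C[is.na(C)] <- 0
  W <- abs(C)
  diag(W) <- 0
  list(W = W, signed = C)
}

# Welch cross-spectral matrices: one n x n complex matrix per frequency bin
welch_csd_matrix <- function(xw, fs, seg_len = 12L, overlap = 0.5) {
  n <- nrow(xw); T <- ncol(xw)
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq(1L, T - seg_len + 1L, by = step)
  if (length(starts) < 2L) {
    stop("degenerate spectral estimate: fewer than 2 sub-segments")
  }
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1))
  nf <- seg_len %/% 2 + 1L
  S <- array(0i, c(n, n, nf))
  for (s in starts) {
    Fseg <- stats::mvfft(t(xw[, s:(s + seg_len - 1L), drop = FALSE]) * win)
    for (f in seq_len(nf)) {
      Ff <- Fseg[f, ]
      S[, , f] <- S[, , f] + Ff %*% Conj(t(Ff))
    }
  }
  list(S = S / length(starts), freqs = (0:(nf - 1L)) * fs / seg_len)
}

msc_ipc_matrix <- function(xw, fs, band, what = c("msc", "ipc"),
                           seg_len = 12L, overlap = 0.5) {
  what <- match.arg(what)
  cs <- welch_csd_matrix(xw, fs, seg_len, overlap)
  sel <- band_bins(cs$freqs, band)
  n <- nrow(xw)
  acc <- matrix(0, n, n)
  for (f in sel) {
    Sf <- cs$S[, , f]
    auto <- Re(diag(Sf))
    den <- sqrt(auto %o% auto)
    acc <- acc + if (what == "msc") Mod(Sf)^2 / den^2 else abs(Im(Sf / den))
  }
  W <- acc / length(sel)
  diag(W) <- 0
  W
}

wc_matrix <- function(xw, fs, band, n_freqs = 8L, smooth_len = 7L,
                      omega0 = 6, kernels = NULL) {
  n <- nrow(xw); T <- ncol(xw)
  if (smooth_len < 3L) {
    stop("degenerate estimate: wavelet coherence requires smooth_len >= 3")
  }
  if (is.null(kernels)) {
    kernels <- morlet_kernels(T, wavelet_freqs(band, fs, n_freqs), fs, omega0)
  }
  V <- T - smooth_len + 1L
  if (V < 1L) stop("window shorter than the smoothing length")
  # banded moving-average operator: only time points with full smoothing
  # support are kept, matching the centered-filter valid region
  Sm <- matrix(0, V, T)
  for (v in seq_len(V)) Sm[v, v:(v + smooth_len - 1L)] <- 1 / smooth_len
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  i1 <- pairs[, 1]; i2 <- pairs[, 2]
  acc <- numeric(nrow(pairs))
  for (Kf in kernels) {
    Wf <- Kf %*% t(xw)                        # T x n complex
    A <- Sm %*% (Mod(Wf)^2)                   # V x n smoothed auto-spectra
    P <- Sm %*% (Wf[, i1, drop = FALSE] * Conj(Wf[, i2, drop = FALSE]))
    wc <- Mod(P) / sqrt(A[, i1, drop = FALSE] * A[, i2, drop = FALSE])
    acc <- acc + colMeans(wc)
  }
  W <- matrix(0, n, n)
  W[pairs] <- acc / length(kernels)
  W + t(W)
}

#' Assemble a labelled, adjacency-annotated window dataset
#'
#' Runs the full preprocessing chain over a list of recordings: band-pass
#' filter at the native rate (zero-phase Butterworth), decimate to the
#' working rate, compute instantaneous phases on the filtered epoch (for
#' the phase-based estimators), segment into windows, and compute one
#' adjacency matrix per window with the chosen connectivity method.
#'
#' @param recordings List of `eeg_recording` objects (e.g. from
#'   [generate_cohort()], or EDF/archive files via [read_recording()]).
#' @param band Band name or data frame (see [eeg_bands()]).
#' @param method Connectivity method (see [adjacency()]).
#' @param window,overlap Segmentation parameters in samples.
#' @param target_fs Working rate in Hz (default 100).
#' @param positive Group label coded 1; defaults to the alphabetically
#'   first group.
#' @param filter_order Butterworth order.
#' @param ... Estimator parameters (`seg_len`, `overlap_frac`, `n_freqs`,
#'   `smooth_len`, `omega0`) forwarded to the adjacency builders.
#' @return An object of class `"eeg_dataset"`: list with `x`
#'   (`[n x window x B]`), `w` (`[n x n x B]`), `y` (0/1), `meta` (data
#'   frame: `subject_id`, `group`, `eye_state`, `epoch_index`,
#'   `window_index`), `method`, `band`, `fs`, `positive`,
#'   `channel_labels`.
#' @export
build_dataset <- function(recordings, band = "Full", method = "wc",
                          window = 25L, overlap = 0L, target_fs = 100,
                          positive = NULL, filter_order = 4L, ...) {
  method <- match.arg(tolower(method), fc_methods)
  band <- band_spec(band)
  stopifnot(length(recordings) >= 1L)
  dots <- list(...)
  xs <- list(); ws <- list(); meta <- list()
  kernels <- NULL
  if (method == "wc") {
    kernels <- morlet_kernels(window,
                              wavelet_freqs(band, target_fs,
                                            dots$n_freqs %||% 8L),
                              target_fs, dots$omega0 %||% 6)
  }
  epoch_counter <- new.env()
  for (rec in recordings) {
    rec_f <- bandpass_filter(rec, band, order = filter_order)
    if (rec_f$fs != target_fs) rec_f <- resample_recording(rec_f, target_fs)
    key <- paste(rec$subject_id, rec$eye_state, sep = "|")
    ep_idx <- (get0(key, envir = epoch_counter, ifnotfound = 0L)) + 1L
    assign(key, ep_idx, envir = epoch_counter)
    phases <- NULL
    if (method %in% c("plv", "pli")) {
      phases <- t(apply(rec_f$samples, 1, function(ch) {
        instantaneous_phase(ch, dt = 1 / target_fs)$phi
      }))
    }
    wins <- segment_epochs(rec_f, window = window, overlap = overlap,
                           band = band, epoch_index = ep_idx)
    for (mw in wins) {
      start <- (mw$window_index - 1L) * (window - overlap)
      cols <- (start + 1L):(start + window)
      W <- switch(method,
        pc  = pc_matrix(mw$x)$W,
        msc = msc_ipc_matrix(mw$x, target_fs, band, "msc",
                             seg_len = dots$seg_len %||% 12L,
                             overlap = dots$overlap_frac %||% 0.5),
        ipc = msc_ipc_matrix(mw$x, target_fs, band, "ipc",
                             seg_len = dots$seg_len %||% 12L,
                             overlap = dots$overlap_frac %||% 0.5),
        wc  = wc_matrix(mw$x, target_fs, band,
                        smooth_len = dots$smooth_len %||% 7L,
                        kernels = kernels),
        plv = plv_matrix(phases[, cols, drop = FALSE]),
        pli = pli_matrix(phases[, cols, drop = FALSE]))
      xs[[length(xs) + 1L]] <- mw$x
      ws[[length(ws) + 1L]] <- W
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = mw$subject_id, group = mw$group,
        eye_state = mw$eye_state, epoch_index = ep_idx,
        window_index = mw$window_index, stringsAsFactors = FALSE)
    }
  }
  if (!length(xs)) stop("no complete windows: recordings shorter than the window")
  meta <- do.call(rbind, meta)
  groups <- sort(unique(meta$group))
  if (length(groups) > 2L) stop("more than two groups in the recordings")
  positive <- positive %||% groups[1]
  x <- simplify2array(xs); dimnames(x) <- NULL
  w <- simplify2array(ws); dimnames(w) <- NULL
  structure(
    list(x = x, w = w, y = as.integer(meta$group == positive), meta = meta,
         method = method, band = band$band, fs = target_fs,
         positive = positive,
         channel_labels = recordings[[1]]$channel_labels),
    class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  cat(sprintf("<eeg_dataset> %d windows of %d x %d (%s band, %s adjacency) @ %g Hz\n",
              dim(x$x)[3], dim(x$x)[1], dim(x$x)[2], x$band,
              toupper(x$method), x$fs))
  tab <- table(x$meta$group)
  cat("  groups:", paste(sprintf("%s = %d", names(tab), tab), collapse = ", "),
      sprintf(" (positive class: %s)\n", x$positive))
  invisible(x)
}

#' Train and evaluate one classifier run on a split dataset
#'
#' Convenience wrapper tying the pieces together: split the dataset (one
#' cross-validation fold becomes the validation set), fit [stgcn()] on the
#' train/validation side, and evaluate the checkpoint on the held-out test
#' windows.
#'
#' @param dataset An `eeg_dataset` from [build_dataset()].
#' @param config An [stgcn_config()].
#' @param split A `dataset_split` from [split_dataset()]; built from
#'   `seed` if omitted.
#' @param val_fold Which cross-validation fold serves as validation.
#' @param seed Seed for splitting and training.
#' @return List with the fitted `model`, the `split`, and `test` (the
#'   [evaluate_model()] result on the held-out windows).
#' @export
run_classification <- function(dataset, config = stgcn_config(),
                               split = NULL, val_fold = 1L, seed = 1L) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  if (is.null(split)) split <- split_dataset(dataset$meta, seed = seed)
  val_idx <- split$cv_folds[[val_fold]]
  train_idx <- setdiff(split$train_val_ids, val_idx)
  fit <- stgcn(dataset$x, dataset$w, dataset$y, config = config,
               train_idx = train_idx, val_idx = val_idx, seed = seed)
  test <- evaluate_model(fit, dataset$x[, , split$test_ids, drop = FALSE],
                         dataset$w[, , split$test_ids, drop = FALSE],
                         dataset$y[split$test_ids])
  list(model = fit, split = split, test = test)
}

#' One run of the planted-effect classification benchmark
#'
#' The package's standard in-silico benchmark under frozen study
#' conditions: a two-group cohort (6 subjects per group, three 12-s
#' eyes-closed epochs each) with a posterior coupling deficit of
#' `delta_kappa` in the patient-like group, Gamma-band signals with
#' wavelet-coherence adjacency (smoothing 21 samples — the longest smoother
#' a 25-sample window supports, so the coherence null stays below 1), and
#' an ST-GCN (or T-CNN baseline) with channel widths (8, 16) trained for 60
#' epochs. The split is subject-hand-out (4 of 6 subjects per group train,
#' the other 2 test): held-out accuracy measures generalisation to unseen
#' subjects, and with `delta_kappa = 0` it must sit at chance — windows of
#' train and test subjects share nothing label-related. One of five
#' cross-validation folds over the training subjects' windows serves as
#' validation for checkpoint selection. Everything — cohort, adjacency,
#' splits, training — derives from `seed`.
#'
#' @param seed Integer seed for the whole run.
#' @param delta_kappa Planted posterior coupling difference (0 for the
#'   exchangeable null).
#' @param variant `"stgcn"` or `"tcnn"`.
#' @param n_subjects Subjects per group.
#' @param epochs Training epochs.
#' @return List with `accuracy` (held-out test accuracy), `model`, `split`
#'   and the `dataset`.
#' @export
benchmark_run <- function(seed, delta_kappa = 0.6,
                          variant = c("stgcn", "tcnn"), n_subjects = 6L,
                          epochs = 60L) {
  variant <- match.arg(variant)
  bm <- two_group_benchmark(n_subjects = n_subjects, n_epochs = 3L,
                            eye_states = "EC", delta_kappa = delta_kappa,
                            seed = seed)
  ds <- build_dataset(bm$recordings, band = "Gamma", method = "wc",
                      smooth_len = 21L)
  sp <- split_dataset(ds$meta, train_frac = 2 / 3, k = 5L, seed = seed,
                      mode = "subject-hand-out")
  cfg <- stgcn_config(channels = c(8L, 16L), epochs = epochs,
                      variant = variant)
  run <- run_classification(ds, cfg, split = sp, seed = seed)
  list(accuracy = run$test$accuracy, model = run$model, split = sp,
       dataset = ds, planted_pairs = bm$planted_pairs)
}
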