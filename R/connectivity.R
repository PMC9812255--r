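#' Pearson correlation between two signals
#'
#' Instantaneous linear interdependence in the time domain,
#' `E[(x - mu_x)(y - mu_y)] / (sigma_x sigma_y)`, in `[-1, 1]`.
#'
#' @param x,y Numeric vectors of equal length (>= 2) with nonzero variance.
#' @return Signed scalar correlation.
#' @export
fc_pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero-variance input")
  }
  stats::cor(x, y)
}

# Welch cross-spectral estimate with Hann taper. Returns the one-sided
# frequency grid and averaged auto/cross spectra; normalisation constants
# cancel in every coherence-type ratio built from it.
welch_spectra <- function(x, y, fs, seg_len = 12L, overlap = 0.5) {
  n <- length(x)
  stopifnot(length(y) == n)
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  if (length(starts) < 2L) {
    stop("degenerate spectral estimate: fewer than 2 sub-segments ",
         "(coherence would be identically 1)")
  }
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1))  # Hann
  nf <- seg_len %/% 2 + 1L
  Sxx <- Syy <- numeric(nf); Sxy <- complex(nf)
  for (s in starts) {
    seg <- s:(s + seg_len - 1L)
    fx <- stats::fft(x[seg] * win)[1:nf]
    fy <- stats::fft(y[seg] * win)[1:nf]
    Sxx <- Sxx + Mod(fx)^2
    Syy <- Syy + Mod(fy)^2
    Sxy <- Sxy + fx * Conj(fy)
  }
  list(freqs = (0:(nf - 1L)) * fs / seg_len,
       Sxx = Sxx / length(starts), Syy = Syy / length(starts),
       Sxy = Sxy / length(starts), n_subsegments = length(starts),
       window = "hann")
}

# Indices of the frequency bins falling inside a band; if the grid is too
# coarse to place a bin inside the band, the bin nearest the band centre is
# used so narrow bands never yield an empty average.
band_bins <- function(freqs, band) {
  band <- band_spec(band)
  sel <- which(freqs >= band$low_hz & freqs <= band$high_hz)
  if (!length(sel)) sel <- which.min(abs(freqs - (band$low_hz + band$high_hz) / 2))
  sel
}

#' Magnitude squared coherence, band-averaged
#'
#' Welch-estimated `|Sxy|^2 / (Sxx Syy)` averaged over the frequency bins
#' inside `band`. The estimate needs at least two (Hann-tapered, 50%
#' overlapping by default) sub-segments: on a single segment coherence is
#' identically 1.
#'
#' @param x,y Numeric vectors of equal length.
#' @param band Band name or data frame (see [eeg_bands()]).
#' @param fs Sampling rate in Hz.
#' @param seg_len Welch sub-segment length in samples (default 12).
#' @param overlap Fractional sub-segment overlap (default 0.5).
#' @return Scalar in `[0, 1]`.
#' @export
fc_msc <- function(x, y, band = "Full", fs, seg_len = 12L, overlap = 0.5) {
  sp <- welch_spectra(x, y, fs, seg_len, overlap)
  sel <- band_bins(sp$freqs, band)
  mean(Mod(sp$Sxy[sel])^2 / (sp$Sxx[sel] * sp$Syy[sel]))
}

#' Imaginary part of coherency, band-averaged
#'
#' Band mean of `|Im(Sxy / sqrt(Sxx Syy))|`. Zero-lag (volume-conducted)
#' coupling is purely real in the coherency, so this measure suppresses it.
#'
#' @inheritParams fc_msc
#' @return Scalar in `[0, 1]`.
#' @export
fc_ipc <- function(x, y, band = "Full", fs, seg_len = 12L, overlap = 0.5) {
  sp <- welch_spectra(x, y, fs, seg_len, overlap)
  sel <- band_bins(sp$freqs, band)
  coh <- sp$Sxy[sel] / sqrt(sp$Sxx[sel] * sp$Syy[sel])
  mean(abs(Im(coh)))
}

#' Morlet continuous wavelet transform
#'
#' Complex Morlet transform `Wx(t, f)` on a fixed frequency grid, computed
#' by direct convolution with L2-normalised kernels (edges zero-padded).
#' The kernel at frequency `f` has Gaussian envelope `sigma_t =
#' omega0 / (2 pi f)` seconds, truncated at 3 sigma.
#'
#' @param x Numeric vector.
#' @param freqs Frequencies in Hz.
#' @param fs Sampling rate in Hz.
#' @param omega0 Morlet centre-frequency parameter (default 6).
#' @return Complex matrix `[length(x) x length(freqs)]`.
#' @export
morlet_cwt <- function(x, freqs, fs, omega0 = 6) {
  K <- morlet_kernels(length(x), freqs, fs, omega0)
  out <- sapply(K, function(M) M %*% x)
  matrix(out, nrow = length(x))
}

# One T x T convolution matrix per frequency: row t holds conj(psi_f(u - t)).
morlet_kernels <- function(T, freqs, fs, omega0 = 6) {
  lapply(freqs, function(f) {
    sigma_t <- omega0 / (2 * pi * f)
    half <- max(1L, ceiling(3 * sigma_t * fs))
    u <- (-half):half
    k <- exp(2i * pi * f * u / fs) * exp(-(u / fs)^2 / (2 * sigma_t^2))
    k <- k / sqrt(sum(Mod(k)^2))
    M <- matrix(0 + 0i, T, T)
    for (t in seq_len(T)) {
      uu <- t + u
      ok <- uu >= 1L & uu <= T
      M[t, uu[ok]] <- Conj(k[ok])
    }
    M
  })
}

# log-spaced analysis frequencies inside a band, bounded into (0, fs/2)
wavelet_freqs <- function(band, fs, n_freqs = 8L) {
  band <- band_spec(band)
  lo <- max(band$low_hz, 0.5)
  hi <- min(band$high_hz, fs / 2 * 0.999)
  exp(seq(log(lo), log(hi), length.out = n_freqs))
}

# centered moving average along rows of a (possibly complex) matrix;
# rows without a full smoothing window come back NA
time_smooth <- function(M, len) {
  sm <- function(A) {
    out <- stats::filter(A, rep(1 / len, len), sides = 2)
    matrix(out, nrow = nrow(A))
  }
  if (is.complex(M)) sm(Re(M)) + 1i * sm(Im(M)) else sm(M)
}

#' Wavelet coherence, band- and time-averaged
#'
#' Morlet wavelet coherence `|<Wx Wy*>| / sqrt(<|Wx|^2><|Wy|^2>)` with a
#' centred moving-average time smoothing of length `smooth_len` (the
#' smoothing is essential: without averaging the ratio is identically 1).
#' The time-frequency field is reduced to one scalar by averaging over the
#' band's frequency grid and all fully-smoothed time points.
#'
#' @inheritParams fc_msc
#' @param n_freqs Number of log-spaced analysis frequencies in the band.
#' @param smooth_len Time-smoothing length in samples (>= 3, default 7).
#' @param omega0 Morlet centre-frequency parameter.
#' @return Scalar in `[0, 1]`.
#' @export
fc_wavelet_coherence <- function(x, y, band = "Full", fs, n_freqs = 8L,
                                 smooth_len = 7L, omega0 = 6) {
  if (smooth_len < 3L) {
    stop("degenerate estimate: wavelet coherence requires smooth_len >= 3")
  }
  stopifnot(length(x) == length(y), length(x) >= smooth_len)
  freqs <- wavelet_freqs(band, fs, n_freqs)
  Wx <- morlet_cwt(x, freqs, fs, omega0)
  Wy <- morlet_cwt(y, freqs, fs, omega0)
  Sxy <- time_smooth(Wx * Conj(Wy), smooth_len)
  Sxx <- time_smooth(Mod(Wx)^2, smooth_len)
  Syy <- time_smooth(Mod(Wy)^2, smooth_len)
  wc <- Mod(Sxy) / sqrt(Sxx * Syy)
  mean(wc[!is.na(wc)])
}

#' Instantaneous phase via the analytic signal
#'
#' Computes the Hilbert-transform analytic signal by frequency-domain
#' construction and returns `phi(t) = atan2(xtilde(t), x(t))` in
#' `(-pi, pi]`. Intended for band-limited input; in the pipeline phases are
#' computed on the band-filtered full epoch and sliced per window, keeping
#' the edge-dominated transform away from the short windows.
#'
#' @param x Numeric vector.
#' @param dt Sampling period in seconds.
#' @return An object of class `"phase_series"`: list with `phi`,
#'   `analytic_imag` and `dt`.
#' @export
instantaneous_phase <- function(x, dt) {
  stopifnot(length(x) >= 2, dt > 0)
  if (all(x == 0)) stop("undefined phase: constant-zero input")
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  analytic <- stats::fft(stats::fft(x) * h, inverse = TRUE) / n
  structure(list(phi = atan2(Im(analytic), Re(analytic)),
                 analytic_imag = Im(analytic), dt = dt),
            class = "phase_series")
}

as_phase <- function(p) {
  if (inherits(p, "phase_series")) p$phi else as.numeric(p)
}

#' Phase locking value
#'
#' `|mean(exp(i (phi_x - phi_y)))|` in `[0, 1]`; 1 means a constant phase
#' difference (strict phase synchronisation), values near
#' `sqrt(pi) / (2 sqrt(N))` are the finite-sample chance level for
#' independent phases.
#'
#' @param phix,phiy Phase series (from [instantaneous_phase()]) or numeric
#'   phase vectors in radians, equal length.
#' @return Scalar in `[0, 1]`.
#' @export
fc_plv <- function(phix, phiy) {
  px <- as_phase(phix); py <- as_phase(phiy)
  if (length(px) != length(py)) stop("phase series lengths differ")
  stopifnot(length(px) >= 2)
  Mod(mean(exp(1i * (px - py))))
}

#' Phase lag index
#'
#' `|mean(sign(phi_x - phi_y))|` in `[0, 1]`: the asymmetry of the phase
#' difference distribution around zero. Insensitive to zero-lag coupling; 0
#' is consistent with no coupling, 1 with a fixed-sign phase lag.
#'
#' @inheritParams fc_plv
#' @return Scalar in `[0, 1]`.
#' @export
fc_pli <- function(phix, phiy) {
  px <- as_phase(phix); py <- as_phase(phiy)
  if (length(px) != length(py)) stop("phase series lengths differ")
  stopifnot(length(px) >= 2)
  abs(mean(sign(px - py)))
}

fc_methods <- c("pc", "msc", "ipc", "wc", "plv", "pli")

#' Functional-connectivity adjacency matrix of one window
#'
#' Builds the symmetric, zero-diagonal coupling matrix `W` over all channel
#' pairs of a window with one of the six estimators, without any
#' thresholding. Pearson correlation and (signed) coherency take values of
#' either sign; they are rectified by absolute value into `W` (a graph
#' propagation operator requires nonnegative weights) and the signed values
#' are retained in `signed_raw`.
#'
#' @param mini A `mini_epoch` (from [segment_epochs()]) or a channels x
#'   samples numeric matrix.
#' @param method One of `"pc"`, `"msc"`, `"ipc"`, `"wc"`, `"plv"`, `"pli"`.
#' @param fs Sampling rate in Hz of the window samples.
#' @param band Band used by the spectral/wavelet estimators and stamped on
#'   the result.
#' @param phases Optional channels x samples matrix of instantaneous phases
#'   for this window (sliced from the full-epoch analytic signal); if
#'   missing, PLV/PLI compute phases on the window itself.
#' @param ... Estimator parameters passed through (`seg_len`, `overlap`,
#'   `n_freqs`, `smooth_len`, `omega0`).
#' @return An object of class `"adjacency_matrix"`: list with `W`, `method`,
#'   `band` and (for pc) `signed_raw`.
#' @export
adjacency <- function(mini, method = fc_methods, fs = 100, band = "Full",
                      phases = NULL, ...) {
  method <- match.arg(tolower(method), fc_methods)
  x <- if (inherits(mini, "mini_epoch")) mini$x else as.matrix(mini)
  n <- nrow(x)
  labs <- rownames(x) %||% paste0("ch", seq_len(n))
  W <- matrix(0, n, n, dimnames = list(labs, labs))
  signed <- NULL
  if (method %in% c("plv", "pli")) {
    if (is.null(phases)) {
      phases <- t(apply(x, 1, function(ch) {
        instantaneous_phase(ch, dt = 1 / fs)$phi
      }))
    }
    W <- if (method == "plv") plv_matrix(phases) else pli_matrix(phases)
    dimnames(W) <- list(labs, labs)
  } else {
    f <- switch(method,
      pc  = function(a, b) fc_pearson(a, b),
      msc = function(a, b) fc_msc(a, b, band, fs, ...),
      ipc = function(a, b) fc_ipc(a, b, band, fs, ...),
      wc  = function(a, b) fc_wavelet_coherence(a, b, band, fs, ...))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        v <- tryCatch(f(x[i, ], x[j, ]), error = function(e) {
          stop(sprintf("adjacency %s failed on pair (%s, %s): %s",
                       method, labs[i], labs[j], conditionMessage(e)),
               call. = FALSE)
        })
        W[i, j] <- W[j, i] <- v
      }
    }
    if (method == "pc") {
      signed <- W
      W <- abs(W)
    }
  }
  diag(W) <- 0
  band_name <- if (is.data.frame(band)) band$band else as.character(band)
  structure(list(W = W, method = method, band = band_name,
                 signed_raw = signed),
            class = "adjacency_matrix")
}

#' @export
print.adjacency_matrix <- function(x, ...) {
  off <- x$W[upper.tri(x$W)]
  cat(sprintf("<adjacency_matrix> %s (%s band): %d nodes, mean coupling %.3f, max %.3f\n",
              toupper(x$method), x$band, nrow(x$W), mean(off), max(off)))
  invisible(x)
}

# all-pairs PLV from a channels x samples phase matrix (one matrix product)
plv_matrix <- function(phases) {
  E <- exp(1i * phases)
  W <- Mod(E %*% Conj(t(E))) / ncol(phases)
  diag(W) <- 0
  W
}

# all-pairs PLI; the sign kills the matrix-product shortcut, so loop rows
pli_matrix <- function(phases) {
  n <- nrow(phases)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- sweep(-phases, 2, phases[i, ], "+")  # phi_i - phi_j per sample
    W[i, ] <- abs(rowMeans(sign(d)))
  }
  W <- (W + t(W)) / 2   # symmetric up to numerics already; enforce exactly
  diag(W) <- 0
  W
}
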