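# Independent brute-force oracles. Everything here is written from the
# defining formulas with plain loops, deliberately sharing no code with the
# package implementations it checks.

# direct DFT: X(f_k) = sum_t x_t exp(-2*pi*i*k*t/N), one-sided grid
oracle_dft <- function(x) {
  N <- length(x)
  k <- 0:(N %/% 2)
  vapply(k, function(kk) {
    sum(x * exp(-2i * pi * kk * (0:(N - 1)) / N))
  }, complex(1))
}

# Welch cross-spectra from first principles (Hann taper, 50% overlap)
oracle_welch <- function(x, y, fs, seg_len = 12L) {
  step <- seg_len %/% 2
  starts <- seq(1L, length(x) - seg_len + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(seg_len - 1)) / (seg_len - 1))
  nf <- seg_len %/% 2 + 1L
  Sxx <- Syy <- rep(0, nf); Sxy <- rep(0 + 0i, nf)
  for (s in starts) {
    seg <- s:(s + seg_len - 1L)
    fx <- oracle_dft(x[seg] * win)
    fy <- oracle_dft(y[seg] * win)
    Sxx <- Sxx + Mod(fx)^2; Syy <- Syy + Mod(fy)^2
    Sxy <- Sxy + fx * Conj(fy)
  }
  list(freqs = (0:(nf - 1)) * fs / seg_len, Sxx = Sxx / length(starts),
       Syy = Syy / length(starts), Sxy = Sxy / length(starts))
}

oracle_msc <- function(x, y, fs, lo, hi, seg_len = 12L) {
  w <- oracle_welch(x, y, fs, seg_len)
  sel <- which(w$freqs >= lo & w$freqs <= hi)
  if (!length(sel)) sel <- which.min(abs(w$freqs - (lo + hi) / 2))
  mean(Mod(w$Sxy[sel])^2 / (w$Sxx[sel] * w$Syy[sel]))
}

oracle_ipc <- function(x, y, fs, lo, hi, seg_len = 12L) {
  w <- oracle_welch(x, y, fs, seg_len)
  sel <- which(w$freqs >= lo & w$freqs <= hi)
  if (!length(sel)) sel <- which.min(abs(w$freqs - (lo + hi) / 2))
  mean(abs(Im(w$Sxy[sel] / sqrt(w$Sxx[sel] * w$Syy[sel]))))
}

# direct-summation Morlet transform (no matrix shortcuts)
oracle_cwt <- function(x, f, fs, omega0 = 6) {
  T <- length(x)
  sigma_t <- omega0 / (2 * pi * f)
  half <- max(1L, ceiling(3 * sigma_t * fs))
  u <- (-half):half
  k <- exp(2i * pi * f * u / fs) * exp(-(u / fs)^2 / (2 * sigma_t^2))
  k <- k / sqrt(sum(Mod(k)^2))
  out <- complex(T)
  for (t in seq_len(T)) {
    acc <- 0 + 0i
    for (m in seq_along(u)) {
      src <- t + u[m]
      if (src >= 1 && src <= T) acc <- acc + x[src] * Conj(k[m])
    }
    out[t] <- acc
  }
  out
}

oracle_wc <- function(x, y, freqs, fs, smooth_len = 7L, omega0 = 6) {
  T <- length(x)
  half <- (smooth_len - 1L) %/% 2L
  vals <- c()
  for (f in freqs) {
    Wx <- oracle_cwt(x, f, fs, omega0)
    Wy <- oracle_cwt(y, f, fs, omega0)
    for (t in (half + 1L):(T - half)) {
      win <- (t - half):(t + half)
      sxy <- mean(Wx[win] * Conj(Wy[win]))
      sxx <- mean(Mod(Wx[win])^2)
      syy <- mean(Mod(Wy[win])^2)
      vals <- c(vals, Mod(sxy) / sqrt(sxx * syy))
    }
  }
  mean(vals)
}

oracle_plv <- function(phix, phiy) {
  s <- 0 + 0i
  for (j in seq_along(phix)) s <- s + exp(1i * (phix[j] - phiy[j]))
  Mod(s / length(phix))
}

oracle_pli <- function(phix, phiy) {
  abs(mean(sign(phix - phiy)))
}

# spectral-domain graph filter: U diag(sum_k theta_k T_k(lambda_scaled)) U' x
oracle_cheb_spectral <- function(W, x, theta, lambda_max = NULL) {
  d <- rowSums(W)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- diag(nrow(W)) - diag(dinv) %*% W %*% diag(dinv)
  e <- eigen((L + t(L)) / 2, symmetric = TRUE)
  lm <- if (is.null(lambda_max)) max(e$values) else lambda_max
  lam <- 2 * e$values / lm - 1
  cheb <- function(k, z) {
    if (k == 0) rep(1, length(z))
    else if (k == 1) z
    else {
      tm2 <- rep(1, length(z)); tm1 <- z
      for (kk in 2:k) { tk <- 2 * z * tm1 - tm2; tm2 <- tm1; tm1 <- tk }
      tm1
    }
  }
  g <- rep(0, length(lam))
  for (k in seq_along(theta)) g <- g + theta[k] * cheb(k - 1, lam)
  e$vectors %*% (g * (t(e$vectors) %*% x))
}

# naive sliding-window temporal convolution
oracle_tconv <- function(Y, Gamma) {
  M <- dim(Y)[1]; n <- dim(Y)[2]; Ci <- dim(Y)[3]
  Kt <- dim(Gamma)[1]; Co <- dim(Gamma)[3]
  out <- array(0, c(M - Kt + 1, n, Co))
  for (t in seq_len(M - Kt + 1)) for (v in seq_len(n)) for (co in seq_len(Co)) {
    acc <- 0
    for (k in seq_len(Kt)) for (ci in seq_len(Ci)) {
      acc <- acc + Gamma[k, ci, co] * Y[t + k - 1, v, ci]
    }
    out[t, v, co] <- acc
  }
  out
}

unwrap_phase <- function(phi) {
  d <- diff(phi)
  d <- (d + pi) %% (2 * pi) - pi
  cumsum(c(phi[1], d))
}

random_adjacency <- function(n, density = 1) {
  A <- matrix(stats::runif(n * n), n)
  A[stats::runif(n * n) > density] <- 0
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

# small deterministic recording fixture: mixed sinusoids plus noise
sine_recording <- function(n_ch = 3, secs = 4, fs = 100, freqs = c(5, 10, 20),
                           noise = 0.1, seed = 1) {
  set.seed(seed)
  t <- seq(0, secs - 1 / fs, by = 1 / fs)
  x <- t(sapply(seq_len(n_ch), function(i) {
    sin(2 * pi * freqs[(i - 1) %% length(freqs) + 1] * t +
          stats::runif(1, 0, 2 * pi)) + stats::rnorm(length(t), 0, noise)
  }))
  recording(x, fs = fs, subject_id = "fix01", group = "HC", eye_state = "EC")
}
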