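test_that("pearson correlation matches hand-computed values", {
  expect_equal(fc_pearson(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(fc_pearson(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(fc_pearson(c(1, 0, 1, 0), c(1, 1, 0, 0)), 0.0)
  expect_error(fc_pearson(rep(1, 5), 1:5), "zero-variance")
})

test_that("coherence estimators match the direct-DFT Welch oracle", {
  set.seed(21)
  for (rep in 1:5) {
    x <- rnorm(16)
    y <- 0.6 * x + rnorm(16)
    lo <- 5; hi <- 45
    expect_equal(fc_msc(x, y, data.frame(low_hz = lo, high_hz = hi), fs = 100,
                        seg_len = 8L),
                 oracle_msc(x, y, 100, lo, hi, seg_len = 8L),
                 tolerance = 1e-8)
    expect_equal(fc_ipc(x, y, data.frame(low_hz = lo, high_hz = hi), fs = 100,
                        seg_len = 8L),
                 oracle_ipc(x, y, 100, lo, hi, seg_len = 8L),
                 tolerance = 1e-8)
  }
})

test_that("magnitude squared coherence behaves at its limits", {
  set.seed(3)
  fs <- 100
  x <- rnorm(25)
  expect_equal(fc_msc(x, x, "Full", fs), 1.0, tolerance = 1e-10)
  expect_error(fc_msc(x, x, "Full", fs, seg_len = 25L), "degenerate")

  # independent white noise over many sub-segments sits well below 1
  set.seed(4)
  reps <- replicate(300, {
    a <- rnorm(200); b <- rnorm(200)
    fc_msc(a, b, "Full", fs, seg_len = 12L)
  })
  expect_lt(mean(reps), 0.35)

  # noiseless LTI relation (delayed scaled copy) keeps coherence ~ 1
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  xs <- sin(2 * pi * 10 * t)
  ys <- 0.5 * c(rep(0, 3), xs[1:(length(xs) - 3)])
  expect_gt(fc_msc(xs[20:180], ys[20:180], "Alpha", fs), 0.95)
})

test_that("imaginary coherency vanishes at zero lag and sees quadrature", {
  fs <- 100
  set.seed(5)
  x <- rnorm(100)
  expect_equal(fc_ipc(x, x, "Full", fs), 0.0, tolerance = 1e-10)

  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  a <- sin(2 * pi * 10 * t) + rnorm(length(t), 0, 0.05)
  b <- sin(2 * pi * 10 * t - pi / 2) + rnorm(length(t), 0, 0.05)
  expect_gt(fc_ipc(a, b, data.frame(low_hz = 8, high_hz = 13), fs), 0.8)

  set.seed(6)
  reps <- replicate(300, fc_ipc(rnorm(100), rnorm(100), "Full", fs))
  expect_lt(mean(reps), 0.3)
})

test_that("Morlet transform and wavelet coherence match direct convolution", {
  set.seed(7)
  x <- rnorm(16); y <- rnorm(16)
  freqs <- c(10, 20, 35)
  W <- morlet_cwt(x, freqs, 100)
  for (k in seq_along(freqs)) {
    expect_equal(W[, k], oracle_cwt(x, freqs[k], 100), tolerance = 1e-8)
  }
  got <- fc_wavelet_coherence(x, y, data.frame(low_hz = 10, high_hz = 35),
                              fs = 100, n_freqs = 3L)
  want <- oracle_wc(x, y, stgcneeg:::wavelet_freqs(
    data.frame(low_hz = 10, high_hz = 35), 100, 3L), 100)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("wavelet coherence hits its limits and the noise floor", {
  fs <- 100
  set.seed(8)
  x <- rnorm(50)
  expect_equal(fc_wavelet_coherence(x, x, "Gamma", fs), 1.0, tolerance = 1e-10)
  expect_error(fc_wavelet_coherence(x, x, "Gamma", fs, smooth_len = 1L),
               "degenerate")

  # constant-lag narrowband copy stays highly coherent
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  a <- sin(2 * pi * 38 * t) + rnorm(length(t), 0, 0.05)
  b <- sin(2 * pi * 38 * (t - 0.004)) + rnorm(length(t), 0, 0.05)
  expect_gt(fc_wavelet_coherence(a, b, "Gamma", fs, smooth_len = 21L), 0.9)

  # independent broadband noise: well below the coherent regime when the
  # smoother holds several independent samples (high band, long smoothing)
  set.seed(9)
  reps <- replicate(60, fc_wavelet_coherence(rnorm(300), rnorm(300), "Gamma",
                                             fs, smooth_len = 51L))
  expect_lt(mean(reps), 0.5)
})

test_that("instantaneous phase tracks analytic phase of oscillations", {
  fs <- 200
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  f0 <- 8
  ph_cos <- instantaneous_phase(cos(2 * pi * f0 * t), 1 / fs)
  inner <- 50:(length(t) - 50)
  slope <- diff(range(unwrap_phase(ph_cos$phi[inner]))) /
           (length(inner) - 1) * fs
  expect_equal(slope, 2 * pi * f0, tolerance = 0.01 * 2 * pi * f0)

  # sine lags cosine by pi/2
  ph_sin <- instantaneous_phase(sin(2 * pi * f0 * t), 1 / fs)
  d <- (ph_cos$phi - ph_sin$phi)[inner] %% (2 * pi)
  expect_equal(mean(d), pi / 2, tolerance = 0.02)

  # amplitude invariance
  ph2 <- instantaneous_phase(5 * cos(2 * pi * f0 * t), 1 / fs)
  expect_equal(ph2$phi, ph_cos$phi, tolerance = 1e-9)

  expect_error(instantaneous_phase(rep(0, 100), 0.01), "undefined phase")
})

test_that("phase locking value matches its closed-form landmarks", {
  set.seed(10)
  phi <- runif(25, -pi, pi)
  expect_equal(fc_plv(phi, phi + 0.7), 1.0, tolerance = 1e-12)
  expect_equal(fc_plv(phi, phi), 1.0)
  expect_equal(fc_plv(phi, phi + 0.7), oracle_plv(phi, phi + 0.7),
               tolerance = 1e-12)
  expect_error(fc_plv(phi, phi[1:10]), "lengths differ")

  # chance level for independent phases: E[PLV] ~ sqrt(pi)/(2 sqrt(N))
  set.seed(11)
  N <- 25
  null_mean <- mean(replicate(10000, fc_plv(runif(N, -pi, pi), rep(0, N))))
  expect_equal(null_mean, sqrt(pi) / (2 * sqrt(N)), tolerance = 0.05)
})

test_that("phase lag index reads the sign asymmetry of phase differences", {
  set.seed(12)
  phi <- runif(30, -pi, pi)
  expect_equal(fc_pli(phi, phi), 0.0)
  expect_equal(fc_pli(phi + pi / 4, phi), 1.0)
  # symmetric +-c differences cancel exactly
  d <- rep(c(0.3, -0.3), 15)
  expect_equal(fc_pli(phi + d, phi), 0.0)
  expect_equal(fc_pli(phi + d, phi), oracle_pli(phi + d, phi))
})

test_that("adjacency matrices are symmetric, zero-diagonal, in range", {
  set.seed(13)
  xw <- matrix(rnorm(6 * 25), 6)
  for (m in c("pc", "msc", "ipc", "wc", "plv", "pli")) {
    A <- adjacency(xw, method = m, fs = 100, band = "Full")
    expect_identical(A$method, m)
    expect_equal(A$W, t(A$W))
    expect_equal(diag(A$W), rep(0, 6), ignore_attr = TRUE)
    expect_true(all(A$W >= 0 & A$W <= 1 + 1e-12))
  }
  # pc retains the signed matrix
  A <- adjacency(xw, method = "pc")
  expect_false(is.null(A$signed_raw))
  expect_equal(abs(A$signed_raw[1, 2]), A$W[1, 2])
  expect_true(any(A$signed_raw < 0))
})

test_that("identical channels give saturated PLV adjacency", {
  xw <- matrix(rep(cos(seq(0, 6, length.out = 25)), each = 4), 4)
  A <- adjacency(xw, method = "plv", fs = 100)
  off <- A$W[upper.tri(A$W)]
  expect_equal(off, rep(1, length(off)), tolerance = 1e-9)
})

test_that("independent channels give low PLI adjacency on average", {
  set.seed(14)
  vals <- replicate(40, {
    phases <- matrix(runif(5 * 25, -pi, pi), 5)
    A <- stgcneeg:::pli_matrix(phases)
    mean(A[upper.tri(A)])
  })
  expect_lt(mean(vals), 0.25)
})

test_that("estimator properties hold over random signal pairs", {
  set.seed(15)
  for (rep in 1:60) {
    x <- rnorm(25); y <- rnorm(25)
    pc <- fc_pearson(x, y)
    expect_true(pc >= -1 && pc <= 1)
    expect_equal(pc, fc_pearson(y, x))
    m <- fc_msc(x, y, "Full", 100)
    expect_true(m >= 0 && m <= 1 + 1e-12)
    expect_equal(m, fc_msc(y, x, "Full", 100))
    ic <- fc_ipc(x, y, "Full", 100)
    expect_true(ic >= 0 && ic <= 1 + 1e-12)   # Cauchy-Schwarz bound
    expect_equal(ic, fc_ipc(y, x, "Full", 100))
    wcv <- fc_wavelet_coherence(x, y, "Full", 100)
    expect_true(wcv >= 0 && wcv <= 1 + 1e-12)
    expect_equal(wcv, fc_wavelet_coherence(y, x, "Full", 100))
    px <- runif(25, -pi, pi); py <- runif(25, -pi, pi)
    pl <- fc_plv(px, py); pli <- fc_pli(px, py)
    expect_true(pl >= 0 && pl <= 1)
    expect_true(pli >= 0 && pli <= 1)
    expect_equal(pl, fc_plv(py, px))
    expect_equal(pli, fc_pli(py, px))
    # phase measures are amplitude-invariant by construction on phases from
    # rescaled signals
    ph1 <- instantaneous_phase(x, 0.01)$phi
    ph2 <- instantaneous_phase(2.5 * x, 0.01)$phi
    expect_equal(ph1, ph2, tolerance = 1e-9)
  }
})

test_that("fast matrix adjacency paths agree with the pairwise route", {
  set.seed(16)
  xw <- matrix(rnorm(5 * 25), 5)
  fs <- 100
  expect_equal(stgcneeg:::pc_matrix(xw)$W, adjacency(xw, "pc")$W,
               ignore_attr = TRUE)
  for (what in c("msc", "ipc")) {
    expect_equal(stgcneeg:::msc_ipc_matrix(xw, fs, eeg_bands("Full"), what),
                 adjacency(xw, what, fs = fs, band = "Full")$W,
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
  expect_equal(stgcneeg:::wc_matrix(xw, fs, eeg_bands("Full")),
               adjacency(xw, "wc", fs = fs, band = "Full")$W,
               ignore_attr = TRUE, tolerance = 1e-10)
  phases <- matrix(runif(5 * 25, -pi, pi), 5)
  expect_equal(stgcneeg:::plv_matrix(phases),
               adjacency(xw, "plv", fs = fs, phases = phases)$W,
               ignore_attr = TRUE, tolerance = 1e-10)
})
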