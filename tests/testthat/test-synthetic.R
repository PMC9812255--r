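small_cfg <- function(epoch_len_s = 4, ...) {
  cohort_config(n_ad = 1L, n_hc = 1L, n_epochs = 1L, eye_states = "EC",
                epoch_len_s = epoch_len_s, n_channels = 5L,
                oscillators = data.frame(freq = 10, amp = 1), ...)
}

test_that("cohort generation is a pure function of its config", {
  cfg <- cohort_config(n_ad = 2L, n_hc = 2L, n_epochs = 1L,
                       eye_states = "EC", epoch_len_s = 2, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$recordings, b$recordings)
  expect_length(a$recordings, 4L)
  rec <- a$recordings[[1]]
  expect_s3_class(rec, "eeg_recording")
  expect_equal(dim(rec$samples), c(23L, 200L))
  expect_identical(rec$channel_labels, bipolar_labels_23())
  expect_setequal(unique(vapply(a$recordings, `[[`, "", "group")),
                  c("AD", "HC"))
})

test_that("cohort structure mirrors the configured counts", {
  cfg <- cohort_config(n_ad = 3L, n_hc = 2L, n_epochs = 2L,
                       eye_states = c("EC", "EO"), epoch_len_s = 1, seed = 1)
  out <- generate_cohort(cfg)
  expect_length(out$recordings, (3 + 2) * 2 * 2)
  meta <- data.frame(
    group = vapply(out$recordings, `[[`, "", "group"),
    eye = vapply(out$recordings, `[[`, "", "eye_state"))
  expect_equal(sum(meta$group == "AD" & meta$eye == "EC"), 6L)
  expect_equal(sum(meta$group == "HC" & meta$eye == "EO"), 4L)
})

test_that("generated spectra peak at the configured oscillator frequency", {
  cfg <- small_cfg(obs_noise_sd = 0.05, pink_noise_scale = 0.05,
                   freq_jitter_sd = 0, phase_noise_sd = 0.1, seed = 3)
  rec <- generate_cohort(cfg)$recordings[[1]]
  x <- rec$samples[1, ]
  spec <- Mod(stats::fft(x))^2
  freqs <- (seq_along(x) - 1) * cfg$fs / length(x)
  half <- freqs <= cfg$fs / 2
  peak <- freqs[half][which.max(spec[half][-1]) + 1]   # skip DC
  expect_lt(abs(peak - 10), 1 / cfg$epoch_len_s + 0.26)  # within one bin
})

test_that("uncoupled channels show chance-level full-epoch synchrony", {
  cfg <- small_cfg(phase_noise_sd = 1.0, freq_jitter_sd = 0.5, seed = 5,
                   epoch_len_s = 8)
  rec <- generate_cohort(cfg)$recordings[[1]]
  phases <- t(apply(rec$samples, 1, function(ch) {
    instantaneous_phase(ch, 1 / cfg$fs)$phi
  }))
  P <- stgcneeg:::plv_matrix(phases)
  vals <- P[upper.tri(P)]
  chance <- sqrt(pi) / (2 * sqrt(ncol(phases)))
  # drifting phases cannot exceed a small multiple of the iid chance level
  expect_lt(mean(vals), 5 * chance)
  expect_lt(mean(vals), 0.2)
})

test_that("a single strongly coupled pair has the top PLV almost always", {
  hits <- 0L
  for (r in 1:50) {
    K <- matrix(0, 5, 5); K[1, 2] <- K[2, 1] <- 0.9
    cfg <- small_cfg(epoch_len_s = 8,
                     coupling = list(AD = K, HC = matrix(0, 5, 5)),
                     phase_noise_sd = 0.5, freq_jitter_sd = 0.5, seed = 100 + r)
    rec <- generate_cohort(cfg)$recordings[[1]]  # AD subject carries K
    phases <- t(apply(rec$samples, 1, function(ch) {
      instantaneous_phase(ch, 1 / cfg$fs)$phi
    }))
    P <- stgcneeg:::plv_matrix(phases)
    top <- which(P == max(P[upper.tri(P)]), arr.ind = TRUE)
    if (any(top[, 1] == 1 & top[, 2] == 2) || any(top[, 1] == 2 & top[, 2] == 1)) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 45L)
})

test_that("estimated synchrony increases monotonically with coupling", {
  levels <- c(0, 0.25, 0.5, 0.75, 1)
  mean_plv <- sapply(seq_along(levels), function(li) {
    vals <- sapply(1:40, function(r) {
      K <- matrix(0, 2, 2); K[1, 2] <- K[2, 1] <- levels[li]
      cfg <- cohort_config(n_ad = 1L, n_hc = 0L, n_epochs = 1L,
                           eye_states = "EC", epoch_len_s = 3,
                           n_channels = 2L,
                           oscillators = data.frame(freq = 10, amp = 1),
                           coupling = list(AD = K, HC = matrix(0, 2, 2)),
                           phase_noise_sd = 0.5, freq_jitter_sd = 0.5,
                           seed = 1000 * li + r)
      rec <- generate_cohort(cfg)$recordings[[1]]
      p1 <- instantaneous_phase(rec$samples[1, ], 0.01)$phi
      p2 <- instantaneous_phase(rec$samples[2, ], 0.01)$phi
      fc_plv(p1, p2)
    })
    mean(vals)
  })
  expect_gt(stats::cor(levels, mean_plv, method = "spearman"), 0.9)
  expect_gt(mean_plv[5], mean_plv[1])
})

test_that("planted coupling strengths are recovered by full-epoch PLV ranks", {
  n <- 10
  K <- matrix(0, n, n)
  # disjoint planted pairs: graded coupling without transitive clusters
  planted <- cbind(seq(1, 9, by = 2), seq(2, 10, by = 2))
  kv <- c(0.2, 0.4, 0.6, 0.8, 0.9)
  for (r in seq_len(nrow(planted))) {
    K[planted[r, 1], planted[r, 2]] <- K[planted[r, 2], planted[r, 1]] <- kv[r]
  }
  cfg <- cohort_config(n_ad = 1L, n_hc = 0L, n_epochs = 8L, eye_states = "EC",
                       epoch_len_s = 8, n_channels = n,
                       oscillators = data.frame(freq = 10, amp = 1),
                       coupling = list(AD = K, HC = matrix(0, n, n)),
                       phase_noise_sd = 0.3, freq_jitter_sd = 1.0, seed = 62)
  out <- generate_cohort(cfg)
  acc <- matrix(0, n, n)
  for (rec in out$recordings) {
    phases <- t(apply(rec$samples, 1, function(ch) {
      instantaneous_phase(ch, 1 / cfg$fs)$phi
    }))
    acc <- acc + stgcneeg:::plv_matrix(phases)
  }
  acc <- acc / length(out$recordings)
  # rank correlation over the graded coupled pairs (all-pair rank
  # correlations are structurally capped by the 40 zero-kappa ties:
  # even perfect recovery cannot exceed ~0.55 there)
  expect_gt(stats::cor(kv, acc[planted], method = "spearman"), 0.8)
  # and the coupled pairs separate from the uncoupled background
  ut <- upper.tri(K)
  expect_gt(mean(acc[planted]), mean(acc[ut][K[ut] == 0]) + 0.2)
})

test_that("the benchmark plants the effect posterior-only and symmetric", {
  bm <- two_group_benchmark(n_subjects = 1L, n_epochs = 1L, delta_kappa = 0.6,
                            base_kappa = 0.1, seed = 2, epoch_len_s = 1)
  gt <- bm$ground_truth$coupling
  pp <- bm$planted_pairs
  expect_true(all(pp >= 17 & pp <= 23))
  expect_equal(nrow(pp), 10L)
  expect_equal(gt$HC[pp] - gt$AD[pp], rep(0.6, 10))
  expect_equal(gt$AD[pp], rep(0.1, 10))
  offplant <- gt$HC
  offplant[pp] <- 0; offplant[pp[, c(2, 1)]] <- 0
  expect_equal(max(abs(offplant)), 0)
  expect_equal(gt$AD, t(gt$AD))
  # zero effect means exchangeable groups
  bm0 <- two_group_benchmark(n_subjects = 1L, n_epochs = 1L, delta_kappa = 0,
                             base_kappa = 0.1, seed = 2, epoch_len_s = 1)
  expect_identical(bm0$ground_truth$coupling$AD, bm0$ground_truth$coupling$HC)
})

test_that("config validation rejects unstable or malformed coupling", {
  K <- matrix(0.2, 3, 3); diag(K) <- 0
  expect_error(cohort_config(n_channels = 3L, coupling = list(A = K, B = K[1:2, 1:2])),
               "n_channels")
  Kasym <- K; Kasym[1, 2] <- 0.5
  expect_error(cohort_config(n_channels = 3L, coupling = list(A = Kasym, B = K)),
               "symmetric")
  Kbig <- K * 10
  expect_error(cohort_config(n_channels = 3L, coupling = list(A = Kbig, B = K)),
               "\\[0, 1\\]")
  expect_error(cohort_config(n_channels = 3L, fs = 2,
                             coupling = list(A = K * 4.9, B = K)),
               "unstable")
})
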