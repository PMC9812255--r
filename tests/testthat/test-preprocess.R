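test_that("archive round-trips recordings and rejects broken input", {
  rec <- sine_recording(n_ch = 2, secs = 1, fs = 100)
  path <- file.path(withr::local_tempdir(), "rec.tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_identical(back$fs, rec$fs)
  expect_identical(back$group, "HC")

  expect_error(read_recording(file.path(tempdir(), "nope.tsv")), "not found")
  empty <- file.path(withr::local_tempdir(), "empty.tsv")
  file.create(empty)
  expect_error(read_recording(empty), "sidecar|empty")
})

test_that("EDF writer/reader round-trip is exact at stored precision", {
  rec <- sine_recording(n_ch = 3, secs = 2, fs = 100)
  path <- file.path(withr::local_tempdir(), "rec.edf")
  write_edf(rec, path)
  r1 <- read_edf(path)
  expect_identical(r1$channel_labels, rec$channel_labels)
  expect_equal(r1$fs, rec$fs)
  expect_equal(dim(r1$samples), dim(rec$samples))
  # reload agrees to the 16-bit quantisation step: exact at stored precision
  step <- (apply(rec$samples, 1, max) - apply(rec$samples, 1, min)) / 65535
  expect_true(all(abs(r1$samples - rec$samples) <= step + 1e-12))
  # a second round trip drifts by at most one further quantisation step
  path2 <- file.path(withr::local_tempdir(), "rec2.edf")
  write_edf(r1, path2)
  r2 <- read_edf(path2)
  expect_true(all(abs(r2$samples - r1$samples) <= step + 1e-12))
  expect_identical(r1$group, "HC")
  expect_identical(r1$eye_state, "EC")
})

test_that("bipolar montage computes differences, keeps order, is linear", {
  x <- rbind(A = rep(1, 10), B = rep(0, 10), C = 1:10)
  rec <- recording(x, fs = 10, channel_labels = c("A", "B", "C"))
  out <- apply_bipolar_montage(rec, data.frame(anode = "A", cathode = "B"))
  expect_equal(unname(out$samples[1, ]), rep(1, 10))
  expect_identical(out$channel_labels, "A-B")
  self <- apply_bipolar_montage(rec, data.frame(anode = "A", cathode = "A"))
  expect_equal(unname(self$samples[1, ]), rep(0, 10))
  expect_error(apply_bipolar_montage(rec, data.frame(anode = "A", cathode = "Z")),
               "montage error")

  # default 23-pair table on a full electrode set
  electrodes <- unique(unlist(bipolar_pairs_23()))
  set.seed(5)
  big <- recording(matrix(rnorm(length(electrodes) * 50), ncol = 50),
                   fs = 100, channel_labels = electrodes)
  mon <- apply_bipolar_montage(big)
  expect_equal(nrow(mon$samples), 23L)
  expect_identical(mon$channel_labels, bipolar_labels_23())
  expect_identical(mon$channel_labels[1], "F8-F4")
  # linearity under scaling
  big2 <- big; big2$samples <- 3 * big$samples
  expect_equal(apply_bipolar_montage(big2)$samples, 3 * mon$samples)
})

test_that("band filter passes in-band and rejects out-of-band sinusoids", {
  fs <- 100
  t <- seq(0, 6 - 1 / fs, by = 1 / fs)
  rec <- recording(rbind(sin(2 * pi * 10 * t)), fs = fs)
  trim <- 100:(length(t) - 100)

  alpha <- bandpass_filter(rec, "Alpha")
  expect_lt(abs(max(abs(alpha$samples[1, trim])) - 1), 0.05)

  delta <- bandpass_filter(rec, "Delta")
  rms_in <- sqrt(mean(rec$samples[1, trim]^2))
  rms_out <- sqrt(mean(delta$samples[1, trim]^2))
  expect_lt(rms_out / rms_in, 0.05)

  zero <- recording(rbind(rep(0, 200)), fs = fs)
  expect_equal(bandpass_filter(zero, "Alpha")$samples, zero$samples)

  expect_error(bandpass_filter(rec, data.frame(low_hz = 10, high_hz = 60)),
               "invalid")
})

test_that("passband filtering is near-idempotent", {
  fs <- 100
  t <- seq(0, 6 - 1 / fs, by = 1 / fs)
  rec <- recording(rbind(sin(2 * pi * 10 * t)), fs = fs)
  trim <- 100:(length(t) - 100)
  once <- bandpass_filter(rec, "Alpha")
  twice <- bandpass_filter(once, "Alpha")
  a1 <- max(abs(once$samples[1, trim]))
  a2 <- max(abs(twice$samples[1, trim]))
  expect_lt((a1 - a2) / a1, 0.10)
})

test_that("resampling decimates with the expected length and fidelity", {
  fs <- 2000
  t <- seq(0, 12 - 1 / fs, by = 1 / fs)
  rec <- recording(rbind(sin(2 * pi * 5 * t)), fs = fs)
  expect_equal(ncol(rec$samples), 24000L)
  down <- resample_recording(rec, 100)
  expect_equal(ncol(down$samples), 1200L)
  expect_equal(down$fs, 100)
  # identity when target equals the native rate
  expect_identical(resample_recording(rec, fs)$samples, rec$samples)
  # fidelity against direct synthesis at the target rate
  t100 <- seq(0, 12 - 1 / 100, by = 1 / 100)
  direct <- sin(2 * pi * 5 * t100)
  trim <- 50:1150
  expect_gt(stats::cor(down$samples[1, trim], direct[trim]), 0.99)
  expect_error(resample_recording(down, 2000), "exceeds")
})

test_that("segmentation yields floor-law counts and discards tails", {
  rec <- sine_recording(n_ch = 2, secs = 12, fs = 100)
  wins <- segment_epochs(rec, window = 25)
  expect_length(wins, 48L)
  expect_equal(dim(wins[[1]]$x), c(2L, 25L))
  expect_identical(wins[[3]]$window_index, 3L)
  expect_identical(wins[[1]]$group, "HC")
  # window content is the exact half-open slice
  expect_equal(wins[[2]]$x, rec$samples[, 26:50])

  short <- recording(matrix(rnorm(2 * 24), 2), fs = 100)
  expect_length(segment_epochs(short, window = 25), 0L)

  # property: count = floor(n/window) across random lengths
  set.seed(9)
  for (len in sample(1:10000, 25)) {
    r <- recording(matrix(0, 1, len), fs = 100)
    w <- sample(1:50, 1)
    expect_length(segment_epochs(r, window = w), len %/% w)
  }
})

test_that("segment counts with overlap follow the stride law", {
  rec <- recording(matrix(0, 1, 100), fs = 100)
  expect_length(segment_epochs(rec, window = 25, overlap = 5), (100 - 5) %/% 20)
  expect_error(segment_epochs(rec, window = 10, overlap = 10))
})

test_that("mini-epoch splits stratify per epoch and conserve the dataset", {
  meta <- expand.grid(window_index = 1:48, epoch_index = 1:3,
                      eye_state = "EC", subject_id = c("A1", "A2", "H1"),
                      stringsAsFactors = FALSE)
  meta$group <- ifelse(grepl("^A", meta$subject_id), "AD", "HC")
  sp <- split_dataset(meta, train_frac = 2 / 3, k = 10, seed = 4)
  expect_length(sp$train_val_ids, 32L * 9L)
  expect_length(sp$test_ids, 16L * 9L)
  # conservation and disjointness
  expect_setequal(c(sp$train_val_ids, sp$test_ids), seq_len(nrow(meta)))
  expect_length(intersect(sp$train_val_ids, sp$test_ids), 0L)
  # folds partition train/val with near-equal sizes
  expect_setequal(unlist(sp$cv_folds), sp$train_val_ids)
  sizes <- lengths(sp$cv_folds)
  expect_lte(max(sizes) - min(sizes), 1L)
  # every single epoch contributes 32 train + 16 test windows
  strat <- paste(meta$subject_id, meta$epoch_index)
  for (s in unique(strat)) {
    expect_equal(sum(sp$train_val_ids %in% which(strat == s)), 32L)
  }
  # determinism
  sp2 <- split_dataset(meta, train_frac = 2 / 3, k = 10, seed = 4)
  expect_identical(sp$train_val_ids, sp2$train_val_ids)
  expect_identical(sp$cv_folds, sp2$cv_folds)
  expect_error(split_dataset(meta, k = 10000), "exceeds")
})

test_that("subject-hand-out mode keeps whole subjects together", {
  meta <- expand.grid(window_index = 1:10, epoch_index = 1:2, eye_state = "EC",
                      subject_id = sprintf("S%02d", 1:10),
                      stringsAsFactors = FALSE)
  meta$group <- rep(c("AD", "HC"), each = nrow(meta) / 2)
  sp <- split_dataset(meta, train_frac = 0.6, seed = 2, k = 5,
                      mode = "subject-hand-out")
  tr_subj <- unique(meta$subject_id[sp$train_val_ids])
  te_subj <- unique(meta$subject_id[sp$test_ids])
  expect_length(intersect(tr_subj, te_subj), 0L)
  expect_length(tr_subj, 6L)
})
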