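#' Configuration of a synthetic two-group EEG cohort
#'
#' Describes a surrogate resting-state cohort built from coupled narrowband
#' oscillators. Each channel carries one phase oscillator per spectral
#' component; within a group, phases interact through a Kuramoto-style
#' coupling graph `kappa` (symmetric, zero diagonal, entries in `[0, 1]`,
#' interpreted as cycles/s of maximal phase pull: the drift term is
#' `2 pi kappa_ij sin(phi_j - phi_i)`). On top of the oscillators each
#' channel receives 1/f ("pink") background activity and white observation
#' noise. Channels are detuned by per-epoch Gaussian frequency jitter;
#' without detuning, uncoupled same-frequency oscillators would stay
#' trivially phase-locked and the coupling graph would be unidentifiable.
#'
#' The default cohort structure mirrors a typical two-group clinical
#' resting-state study: 19 patient-like ("AD") and 20 control-like ("HC")
#' subjects, three artefact-free 12-s epochs per eye state (EC and EO),
#' 23 channels named after the bipolar derivation table, 100 Hz.
#'
#' @param n_ad,n_hc Subjects per group.
#' @param n_epochs Epochs per subject per eye state.
#' @param eye_states Character vector of eye states to generate.
#' @param epoch_len_s Epoch length in seconds.
#' @param fs Sampling rate in Hz (generate at 2000 to exercise the
#'   decimation path).
#' @param n_channels Number of channels.
#' @param oscillators Data frame with `freq` (Hz) and `amp`: one component
#'   per clinical band by default (2, 6, 10, 20, 40 Hz) with a shallow
#'   spectral amplitude decay (`amp = 1.5 * f^-0.3`) that keeps every band's
#'   component above the default noise floor.
#' @param coupling Named list with one `n_channels x n_channels` coupling
#'   matrix per group, e.g. `list(AD = ..., HC = ...)`. Defaults to no
#'   coupling in either group.
#' @param phase_noise_sd Phase-diffusion scale in rad/sqrt(s).
#' @param freq_jitter_sd Per-channel, per-epoch frequency jitter sd in Hz.
#' @param obs_noise_sd White observation-noise sd (amplitude units).
#' @param pink_noise_scale Sd of the 1/f background (amplitude units).
#' @param seed Integer seed; cohorts are bit-reproducible given the config.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_ad = 19L, n_hc = 20L, n_epochs = 3L,
                          eye_states = c("EC", "EO"), epoch_len_s = 12,
                          fs = 100, n_channels = 23L,
                          oscillators = data.frame(
                            freq = c(2, 6, 10, 20, 40),
                            amp = 1.5 / c(2, 6, 10, 20, 40)^0.3),
                          coupling = NULL,
                          phase_noise_sd = 0.5, freq_jitter_sd = 0.6,
                          obs_noise_sd = 0.1, pink_noise_scale = 0.15,
                          seed = 1L) {
  n_channels <- as.integer(n_channels)
  if (is.null(coupling)) {
    z <- matrix(0, n_channels, n_channels)
    coupling <- list(AD = z, HC = z)
  }
  stopifnot(length(coupling) == 2L, !is.null(names(coupling)))
  for (g in names(coupling)) {
    K <- coupling[[g]]
    if (!is.matrix(K) || nrow(K) != n_channels || ncol(K) != n_channels) {
      stop("coupling matrices must be n_channels x n_channels")
    }
    if (max(abs(K - t(K))) > 1e-12 || any(diag(K) != 0)) {
      stop("coupling matrices must be symmetric with zero diagonal")
    }
    if (min(K) < 0 || max(K) > 1) stop("coupling entries must lie in [0, 1]")
    if (max(K) * 2 * pi / fs >= 0.5) {
      stop("unstable integration step: kappa * 2*pi * dt must stay below 0.5")
    }
  }
  stopifnot(phase_noise_sd >= 0, freq_jitter_sd >= 0, obs_noise_sd >= 0,
            pink_noise_scale >= 0, epoch_len_s > 0, fs > 0)
  structure(list(n_ad = as.integer(n_ad), n_hc = as.integer(n_hc),
                 n_epochs = as.integer(n_epochs), eye_states = eye_states,
                 epoch_len_s = epoch_len_s, fs = fs,
                 n_channels = n_channels, oscillators = oscillators,
                 coupling = coupling, phase_noise_sd = phase_noise_sd,
                 freq_jitter_sd = freq_jitter_sd, obs_noise_sd = obs_noise_sd,
                 pink_noise_scale = pink_noise_scale,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d + %d subjects (%s), %d epoch(s) x %s, %g s @ %g Hz, %d channels\n",
              x$n_ad, x$n_hc, paste(names(x$coupling), collapse = "/"),
              x$n_epochs, paste(x$eye_states, collapse = "+"),
              x$epoch_len_s, x$fs, x$n_channels))
  invisible(x)
}

# Euler-Maruyama integration of coupled phase oscillators: one phase matrix
# (channels x components) advanced with drift 2*pi*f + 2*pi*K sin coupling
# and diffusion phase_noise_sd * sqrt(dt). Returns channels x time x comp.
integrate_phases <- function(K, freqs_mat, T, dt, noise_sd) {
  n <- nrow(freqs_mat); nb <- ncol(freqs_mat)
  phi <- array(0, c(n, T, nb))
  cur <- matrix(stats::runif(n * nb, -pi, pi), n, nb)
  base <- 2 * pi * freqs_mat * dt
  noise <- if (noise_sd > 0) {
    array(stats::rnorm(n * nb * (T - 1), 0, noise_sd * sqrt(dt)),
          c(n, nb, T - 1))
  } else NULL
  coupled <- any(K != 0)
  phi[, 1, ] <- cur
  if (!coupled && is.null(noise)) {
    for (b in seq_len(nb)) {
      phi[, , b] <- outer(base[, b], 0:(T - 1)) + cur[, b]
    }
  } else if (!coupled) {
    for (b in seq_len(nb)) {
      inc <- cbind(0, matrix(noise[, b, ], n, T - 1)) + base[, b]
      inc[, 1] <- cur[, b]
      phi[, , b] <- t(apply(inc, 1, cumsum))
    }
  } else {
    for (t in 2:T) {
      E <- exp(1i * cur)
      pull <- Im(Conj(E) * (K %*% E))          # sum_j K_ij sin(phi_j - phi_i)
      cur <- cur + base + 2 * pi * pull * dt
      if (!is.null(noise)) cur <- cur + noise[, , t - 1]
      phi[, t, ] <- cur
    }
  }
  phi
}

# 1/f-amplitude background noise, one channel per row, unit sd then scaled
pink_noise <- function(n, T, scale) {
  if (scale <= 0) return(matrix(0, n, T))
  out <- matrix(0, n, T)
  f <- c(1, seq_len(T - 1))                    # avoid DC blow-up
  shape <- 1 / sqrt(pmin(f, T - f + 1))
  for (i in seq_len(n)) {
    spec <- stats::fft(stats::rnorm(T)) * shape
    x <- Re(stats::fft(spec, inverse = TRUE) / T)
    out[i, ] <- scale * x / stats::sd(x)
  }
  out
}

#' Generate a synthetic EEG cohort
#'
#' Simulates every subject x eye state x epoch of the configured cohort.
#' Each epoch draws fresh initial phases, frequency jitter and noise, so
#' subjects carry no stable identity fingerprint beyond their group's
#' coupling graph. The generator is a pure function of the config seed.
#'
#' @param cfg A [cohort_config()].
#' @param keep_phases If `TRUE`, attach the realized oscillator phase
#'   trajectories of every epoch to the ground truth (memory-heavy; meant
#'   for estimator validation).
#' @return A list with `recordings` (list of `eeg_recording`) and
#'   `ground_truth` (list with the coupling graphs, the config, and
#'   optionally `phases`).
#' @export
generate_cohort <- function(cfg, keep_phases = FALSE) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n_channels
  T <- as.integer(round(cfg$epoch_len_s * cfg$fs))
  dt <- 1 / cfg$fs
  labs <- if (n == 23L) bipolar_labels_23() else paste0("ch", seq_len(n))
  groups <- names(cfg$coupling)
  counts <- c(cfg$n_ad, cfg$n_hc)
  osc <- cfg$oscillators
  recordings <- list()
  phases_kept <- if (keep_phases) list() else NULL
  for (gi in seq_along(groups)) {
    K <- cfg$coupling[[groups[gi]]]
    for (s in seq_len(counts[gi])) {
      sid <- sprintf("%s%02d", groups[gi], s)
      for (es in cfg$eye_states) {
        for (ep in seq_len(cfg$n_epochs)) {
          freqs_mat <- matrix(rep(osc$freq, each = n), n) +
            matrix(stats::rnorm(n * nrow(osc), 0, cfg$freq_jitter_sd), n)
          phi <- integrate_phases(K, freqs_mat, T, dt, cfg$phase_noise_sd)
          x <- matrix(0, n, T)
          for (b in seq_len(nrow(osc))) {
            x <- x + osc$amp[b] * cos(phi[, , b])
          }
          x <- x + pink_noise(n, T, cfg$pink_noise_scale)
          if (cfg$obs_noise_sd > 0) {
            x <- x + matrix(stats::rnorm(n * T, 0, cfg$obs_noise_sd), n, T)
          }
          rec <- recording(x, fs = cfg$fs, channel_labels = labs,
                           subject_id = sid, group = groups[gi],
                           eye_state = es)
          key <- sprintf("%s_%s_ep%d", sid, es, ep)
          recordings[[key]] <- rec
          if (keep_phases) phases_kept[[key]] <- phi
        }
      }
    }
  }
  gt <- list(coupling = cfg$coupling, config = cfg)
  if (keep_phases) gt$phases <- phases_kept
  list(recordings = recordings, ground_truth = gt)
}

#' Posterior channel pairs of the 23-derivation montage
#'
#' Channel pairs drawn from the parieto-occipital derivations (P4-PZ,
#' P3-PZ, T6-O2, T5-O1, P4-O2, P3-O1, O1-O2; positions 17-23 of the
#' canonical order), in a fixed canonical order.
#'
#' @param n_pairs Number of pairs (up to 21).
#' @return Two-column integer matrix of channel indices (i < j).
#' @export
posterior_pairs <- function(n_pairs = 10L) {
  post <- 17:23
  all_pairs <- t(utils::combn(post, 2))
  stopifnot(n_pairs >= 1L, n_pairs <= nrow(all_pairs))
  all_pairs[seq_len(n_pairs), , drop = FALSE]
}

#' Two-group benchmark cohort with a planted posterior coupling deficit
#'
#' Builds a cohort in which the control-like ("HC") group carries coupling
#' `base_kappa + delta_kappa` on a designated set of posterior channel
#' pairs while the patient-like ("AD") group keeps only `base_kappa` there
#' — the in-silico analogue of reduced posterior functional connectivity
#' in the patient group. With `delta_kappa = 0` the two groups are
#' exchangeable and every downstream classifier should sit at chance.
#'
#' @param n_subjects Subjects per group.
#' @param n_epochs Epochs per subject per eye state.
#' @param eye_states Eye states to generate (default `"EC"` only).
#' @param delta_kappa Coupling difference planted on the posterior pairs.
#' @param n_pairs Number of posterior pairs carrying the effect.
#' @param base_kappa Background coupling both groups share on those pairs.
#' @param seed Integer seed.
#' @param ... Further arguments to [cohort_config()].
#' @return As [generate_cohort()], plus `planted_pairs` (the index matrix).
#' @export
two_group_benchmark <- function(n_subjects = 6L, n_epochs = 3L,
                                eye_states = "EC", delta_kappa = 0.6,
                                n_pairs = 10L, base_kappa = 0,
                                seed = 1L, ...) {
  stopifnot(delta_kappa >= 0, base_kappa >= 0, base_kappa + delta_kappa <= 1)
  pairs <- posterior_pairs(n_pairs)
  K_ad <- K_hc <- matrix(0, 23, 23)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    K_ad[i, j] <- K_ad[j, i] <- base_kappa
    K_hc[i, j] <- K_hc[j, i] <- base_kappa + delta_kappa
  }
  cfg <- cohort_config(n_ad = n_subjects, n_hc = n_subjects,
                       n_epochs = n_epochs, eye_states = eye_states,
                       coupling = list(AD = K_ad, HC = K_hc), seed = seed,
                       ...)
  out <- generate_cohort(cfg)
  out$planted_pairs <- pairs
  out
}
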