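#' Construct a multichannel EEG recording
#'
#' A `Recording` is the raw-signal container of the pipeline: a channels x
#' samples numeric matrix together with its sampling rate and labels, plus
#' the cohort metadata (subject, group, eye state) carried through every
#' downstream stage.
#'
#' @param samples Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_labels Character vector of unique channel names, one per row.
#' @param subject_id Subject identifier string.
#' @param group Group label, conventionally `"AD"` or `"HC"` (free-form).
#' @param eye_state `"EC"` (eyes closed) or `"EO"` (eyes open), or `NA`.
#' @return An object of class `"eeg_recording"`.
#' @export
recording <- function(samples, fs, channel_labels = NULL,
                      subject_id = NA_character_, group = NA_character_,
                      eye_state = NA_character_) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (ncol(samples) < 1L) stop("recording must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a positive scalar sampling rate in Hz")
  }
  if (is.null(channel_labels)) {
    channel_labels <- if (!is.null(rownames(samples))) rownames(samples)
                      else paste0("ch", seq_len(nrow(samples)))
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(samples)) {
    stop("'channel_labels' must have one entry per channel")
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, fs = as.numeric(fs),
         channel_labels = channel_labels,
         subject_id = as.character(subject_id), group = as.character(group),
         eye_state = as.character(eye_state)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  cat(sprintf("  subject: %s  group: %s  eye state: %s\n",
              x$subject_id, x$group, x$eye_state))
  lab <- x$channel_labels
  if (length(lab) > 6L) lab <- c(lab[1:6], "...")
  cat("  channels:", paste(lab, collapse = ", "), "\n")
  invisible(x)
}

n_channels <- function(rec) nrow(rec$samples)
n_samples  <- function(rec) ncol(rec$samples)

#' Read a recording from disk
#'
#' Two on-disk representations are supported: `"archive"`, a plain-text
#' tab-separated channels x samples matrix plus a JSON sidecar
#' (`<path>.json`) holding labels, sampling rate and metadata; and `"edf"`,
#' the 16-bit European Data Format written by [write_edf()].
#'
#' @param path File path (`.tsv` for archive, `.edf` for EDF).
#' @param format `"archive"` or `"edf"`; default guessed from the extension.
#' @return An `eeg_recording`.
#' @seealso [write_recording()], [write_edf()]
#' @export
read_recording <- function(path, format = c("auto", "archive", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "archive"
  }
  if (!file.exists(path)) stop("cannot read recording: file not found: ", path)
  if (format == "edf") return(read_edf(path))
  if (file.info(path)$size == 0) stop("cannot read recording: empty file: ", path)
  side <- paste0(path, ".json")
  if (!file.exists(side)) {
    stop("archive format error: missing JSON sidecar ", side)
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$channel_labels) || is.null(meta$fs)) {
    stop("archive format error: sidecar must carry 'channel_labels' and 'fs'")
  }
  x <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(x) <- NULL
  recording(x, fs = meta$fs, channel_labels = meta$channel_labels,
            subject_id = meta$subject_id %||% NA_character_,
            group = meta$group %||% NA_character_,
            eye_state = meta$eye_state %||% NA_character_)
}

#' Write a recording as a plain-text archive
#'
#' @param rec An `eeg_recording`.
#' @param path Output `.tsv` path; a `<path>.json` sidecar is written next
#'   to it.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  utils::write.table(rec$samples, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(channel_labels = rec$channel_labels, fs = rec$fs,
               subject_id = rec$subject_id, group = rec$group,
               eye_state = rec$eye_state)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- minimal EDF (European Data Format, 16-bit) reader/writer --------------
# Continuous EDF only: one fixed record duration, no annotations. Samples are
# quantised to the int16 grid spanned by each channel's physical range, the
# format's native precision.

pad <- function(s, n) {
  substr(formatC(as.character(s), width = n, flag = "-"), 1L, n)
}

# shortest decimal representation of each value that fits in 8 bytes
num8 <- function(x) {
  vapply(x, function(v) {
    for (d in 7:1) {
      s <- formatC(v, format = "g", digits = d)
      if (nchar(s) <= 8) return(s)
    }
    formatC(v, format = "e", digits = 0)
  }, "")
}

#' Write a recording to an EDF file
#'
#' Writes standard 16-bit EDF with one-second data records. The recording
#' length must be a whole number of seconds at its sampling rate; values are
#' quantised to each channel's physical min/max range (the format's native
#' 16-bit precision).
#'
#' @param rec An `eeg_recording`.
#' @param path Output `.edf` path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- n_channels(rec); nsamp <- n_samples(rec); fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  if (nsamp %% fs != 0) stop("EDF writer requires a whole number of seconds")
  n_rec <- nsamp %/% fs
  pmin <- apply(rec$samples, 1, min); pmax <- apply(rec$samples, 1, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  # round the physical range to what the 8-byte header fields can carry and
  # quantise against the rounded values, so writer and reader agree exactly
  pmin_s <- num8(pmin); pmax_s <- num8(pmax)
  pmin <- as.numeric(pmin_s); pmax <- as.numeric(pmax_s)
  pmin <- pmin - (pmax - pmin) * 1e-6   # keep all samples inside the range
  pmax <- pmax + (pmax - pmin) * 1e-6
  pmin_s <- num8(pmin); pmax_s <- num8(pmax)
  pmin <- as.numeric(pmin_s); pmax <- as.numeric(pmax_s)
  # header: 256 bytes global + 256 per signal
  con <- file(path, "wb"); on.exit(close(con))
  hdr <- paste0(
    pad("0", 8),
    pad(rec$subject_id, 80),
    pad(paste("group", rec$group, "eye", rec$eye_state), 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (ns + 1), 8), pad("", 44),
    pad(n_rec, 8), pad(1, 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, w) writeChar(paste0(vapply(vals, pad, "", n = w),
                                              collapse = ""), con, eos = NULL)
  field(rec$channel_labels, 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)                      # physical dimension
  field(pmin_s, 8)
  field(pmax_s, 8)
  field(rep(-32768L, ns), 8)
  field(rep(32767L, ns), 8)
  field(rep("", ns), 80)                       # prefiltering
  field(rep(fs, ns), 8)                        # samples per record
  field(rep("", ns), 32)                       # reserved
  scale <- (pmax - pmin) / 65535
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((rec$samples[ch, idx] - pmin[ch]) / scale[ch]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads continuous 16-bit EDF as written by [write_edf()] (equal sampling
#' rate across signals, no annotation channel).
#'
#' @param path Path to the `.edf` file.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("cannot read EDF: file not found: ", path)
  if (file.info(path)$size < 256) stop("cannot read EDF: truncated header: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8)                                   # version
  subject <- rd(80); rec_field <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8)); dur <- as.numeric(rd(8)); ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("EDF format error: no signals declared")
  labs <- vapply(seq_len(ns), function(i) rd(16), "")
  if (any(!nzchar(labs))) stop("EDF format error: missing channel labels")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L) {
    stop("EDF format error: mixed per-signal sampling rates not supported")
  }
  fs <- spr[1] / dur
  x <- matrix(0, ns, n_rec * spr[1])
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      x[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <-
        pmin[ch] + (dig - dmin[ch]) * scale[ch]
    }
  }
  meta <- regmatches(rec_field,
                     regexec("group (\\S+) eye (\\S+)", rec_field))[[1]]
  recording(x, fs = fs, channel_labels = labs, subject_id = subject,
            group = if (length(meta) == 3) meta[2] else NA_character_,
            eye_state = if (length(meta) == 3) meta[3] else NA_character_)
}
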