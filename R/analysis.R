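#' Accuracy grid over eye state x connectivity method x band
#'
#' Collects per-run test accuracies into the canonical results layout: one
#' row per (eye state, connectivity method), one column per band. Each cell
#' may be filled at most once; cells never run are reported as `NA`, not
#' zero.
#'
#' @param results Data frame with columns `eye_state`, `fc_method`, `band`
#'   and `accuracy` (percent, in `[0, 100]`).
#' @param variant Optional model tag stored as an attribute.
#' @return A data frame of class `"accuracy_grid"` with columns
#'   `eye_state`, `fc_method` and one column per band present, ordered
#'   Delta through Full.
#' @export
accuracy_grid <- function(results, variant = NULL) {
  need <- c("eye_state", "fc_method", "band", "accuracy")
  if (!all(need %in% names(results))) {
    stop("results must have columns ", paste(need, collapse = ", "))
  }
  if (any(results$accuracy < 0 | results$accuracy > 100)) {
    stop("accuracies must be percentages in [0, 100]")
  }
  key <- paste(results$eye_state, results$fc_method, results$band)
  if (anyDuplicated(key)) {
    stop("duplicate cell submission: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  band_order <- c("Delta", "Theta", "Alpha", "Beta", "Gamma", "Full")
  bands <- intersect(band_order, unique(results$band))
  bands <- c(bands, setdiff(unique(results$band), band_order))
  rows <- unique(results[, c("eye_state", "fc_method")])
  rows <- rows[order(rows$eye_state, rows$fc_method), , drop = FALSE]
  grid <- rows
  for (b in bands) {
    grid[[b]] <- NA_real_
    sub <- results[results$band == b, ]
    m <- match(paste(grid$eye_state, grid$fc_method),
               paste(sub$eye_state, sub$fc_method))
    grid[[b]][!is.na(m)] <- sub$accuracy[m[!is.na(m)]]
  }
  rownames(grid) <- NULL
  attr(grid, "variant") <- variant
  class(grid) <- c("accuracy_grid", "data.frame")
  grid
}

#' Group-averaged adjacency matrix
#'
#' Element-wise mean of the per-window adjacency matrices of one selection
#' (group, optionally eye state) of a dataset.
#'
#' @param dataset An `eeg_dataset` from [build_dataset()].
#' @param group Group label to select.
#' @param eye_state Optional eye-state filter.
#' @return An object of class `"averaged_adjacency"`: list with the mean
#'   matrix `W`, the number of windows averaged `count`, and the selection
#'   metadata.
#' @export
average_adjacency <- function(dataset, group, eye_state = NULL) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  sel <- dataset$meta$group == group
  if (!is.null(eye_state)) sel <- sel & dataset$meta$eye_state == eye_state
  if (!any(sel)) stop("empty selection: no windows match")
  W <- apply(dataset$w[, , sel, drop = FALSE], c(1, 2), mean)
  dimnames(W) <- list(dataset$channel_labels, dataset$channel_labels)
  structure(list(W = W, count = sum(sel), group = group,
                 eye_state = eye_state %||% "all", method = dataset$method,
                 band = dataset$band),
            class = "averaged_adjacency")
}

#' @export
print.averaged_adjacency <- function(x, ...) {
  off <- x$W[upper.tri(x$W)]
  cat(sprintf("<averaged_adjacency> %s/%s, %s (%s band): mean of %d windows, coupling %.3f (max %.3f)\n",
              x$group, x$eye_state, toupper(x$method), x$band, x$count,
              mean(off), max(off)))
  invisible(x)
}

#' Heatmap of an averaged adjacency matrix
#'
#' @param x An `averaged_adjacency`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.averaged_adjacency <- function(x, ...) {
  n <- nrow(x$W)
  graphics::image(seq_len(n), seq_len(n), t(x$W[n:1, ]), axes = FALSE,
                  xlab = "", ylab = "",
                  main = sprintf("%s %s (%s, %s band)", x$group, x$eye_state,
                                 toupper(x$method), x$band), ...)
  graphics::axis(1, seq_len(n), colnames(x$W), las = 2, cex.axis = 0.5)
  graphics::axis(2, seq_len(n), rev(rownames(x$W)), las = 2, cex.axis = 0.5)
  invisible(x)
}

#' Screen channel pairs against a coupling threshold
#'
#' Lists the channel pairs (i < j) of an averaged adjacency whose mean
#' coupling is strictly below (`mode = "below"`) or at/above
#' (`mode = "above"`) the threshold. The two modes partition the pair set.
#'
#' @param avg An `averaged_adjacency` (or a plain symmetric matrix).
#' @param threshold Coupling threshold (default 0.15).
#' @param mode `"below"` (strict) or `"above"` (at or above).
#' @return Data frame with columns `i`, `j`, `pair`, `value`; possibly
#'   zero rows.
#' @export
threshold_screen <- function(avg, threshold = 0.15,
                             mode = c("below", "above")) {
  mode <- match.arg(mode)
  W <- if (inherits(avg, "averaged_adjacency")) avg$W else as.matrix(avg)
  labs <- rownames(W) %||% paste0("ch", seq_len(nrow(W)))
  idx <- which(upper.tri(W), arr.ind = TRUE)
  vals <- W[idx]
  keep <- if (mode == "below") vals < threshold else vals >= threshold
  out <- data.frame(i = idx[keep, 1], j = idx[keep, 2],
                    pair = paste(labs[idx[keep, 1]], labs[idx[keep, 2]],
                                 sep = " ~ "),
                    value = vals[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$i, out$j), , drop = FALSE]
}
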