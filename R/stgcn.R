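#' Model configuration for [stgcn()]
#'
#' Architecture and optimisation hyperparameters. The trunk is
#' `length(channels)` spatial-temporal blocks; each shortens the time axis
#' by `2 * (Kt - 1)`, so the input length must satisfy
#' `in_len - n_blocks * 2 * (Kt - 1) >= 1`.
#'
#' @param Kt Temporal kernel width (default 3).
#' @param channels Per-block channel widths (default `c(16, 32)`, two
#'   blocks).
#' @param variant `"stgcn"` (graph convolution driven by the per-sample
#'   adjacency) or `"tcnn"` (temporal-only baseline: identical stack with
#'   identity propagation, ignoring the adjacency input).
#' @param epochs Training epochs (default 100).
#' @param batch_size Mini-batch size (default 64).
#' @param lr Adam learning rate (default 1e-3).
#' @param beta1,beta2,eps_adam Adam moment decays and stabiliser.
#' @param ln_scope Layer-norm grouping: `"sample"` (default) normalises each
#'   block output over all nodes, channels and time points jointly, so
#'   between-node amplitude patterns — the main trace the graph propagation
#'   leaves in the activations — survive; `"node"` normalises each node's
#'   (channel, time) slab separately.
#' @return A list of class `"stgcn_config"`.
#' @export
stgcn_config <- function(Kt = 3L, channels = c(16L, 32L),
                         variant = c("stgcn", "tcnn"), epochs = 100L,
                         batch_size = 64L, lr = 1e-3, beta1 = 0.9,
                         beta2 = 0.999, eps_adam = 1e-8,
                         ln_scope = c("sample", "node")) {
  variant <- match.arg(variant)
  ln_scope <- match.arg(ln_scope)
  stopifnot(Kt >= 1L, length(channels) >= 1L, all(channels >= 1L),
            epochs >= 1L, batch_size >= 1L, lr > 0)
  structure(list(Kt = as.integer(Kt), channels = as.integer(channels),
                 variant = variant, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 beta1 = beta1, beta2 = beta2, eps_adam = eps_adam,
                 ln_scope = ln_scope),
            class = "stgcn_config")
}

# accept an [n x M x B] array, a single matrix, or a list of mini_epochs
as_sample_array <- function(x) {
  if (is.list(x) && !is.array(x)) {
    mats <- lapply(x, function(m) {
      if (inherits(m, "mini_epoch")) m$x else as.matrix(m)
    })
    x <- simplify2array(mats)
    dimnames(x) <- NULL
  }
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L)
  x
}

# per-sample renormalized propagation matrices as an [n x n x B] cube;
# a single shared adjacency collapses to one slice
propagation_array <- function(w, n) {
  if (inherits(w, "adjacency_matrix")) w <- w$W
  if (is.list(w) && !is.array(w)) {
    w <- simplify2array(lapply(w, function(a) {
      if (inherits(a, "adjacency_matrix")) a$W else as.matrix(a)
    }))
  }
  if (is.matrix(w)) w <- array(w, c(dim(w), 1L))
  stopifnot(dim(w)[1] == n, dim(w)[2] == n)
  S <- array(0, dim(w))
  for (i in seq_len(dim(w)[3])) S[, , i] <- renorm_propagation(w[, , i])
  S
}

encode_labels <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("y must have exactly two classes")
    list(y = as.numeric(y) - 1, levels = levels(y))
  } else if (is.logical(y)) {
    list(y = as.numeric(y), levels = c("FALSE", "TRUE"))
  } else {
    if (!all(y %in% c(0, 1))) stop("numeric y must be coded 0/1")
    list(y = as.numeric(y), levels = c("0", "1"))
  }
}

#' Fit a spatial-temporal graph convolutional classifier
#'
#' Trains the two-class ST-GCN (or its temporal-CNN baseline) on a batch of
#' fixed-length multichannel windows, each paired with its own
#' functional-connectivity adjacency matrix. Optimisation is Adam on binary
#' cross-entropy; after every epoch the validation loss is evaluated and
#' the parameters achieving the best validation loss are kept as the
#' checkpoint that [predict.stgcn()] uses.
#'
#' @param x Samples: numeric array `[n x M x B]` (channels x time x batch)
#'   or a list of `mini_epoch` objects.
#' @param w Adjacency input: `[n x n x B]` array, a list of
#'   `adjacency_matrix` objects, or a single shared `n x n` matrix.
#'   Converted per sample to the renormalized propagation operator.
#'   Ignored by the `"tcnn"` variant.
#' @param y Labels: 0/1 numeric, logical, or a two-level factor (second
#'   level coded 1).
#' @param config An [stgcn_config()].
#' @param train_idx,val_idx Integer sample indices for training and
#'   validation. If omitted, a fraction `val_frac` of the samples is held
#'   out for validation (seeded) and the rest train.
#' @param val_frac Validation fraction when `val_idx` is missing.
#' @param seed Integer seed controlling initialisation, batch order and the
#'   default validation split.
#' @return An object of class `"stgcn"`.
#' @examples
#' set.seed(1)
#' n <- 4; M <- 9; B <- 60
#' x <- array(rnorm(n * M * B), c(n, M, B))
#' y <- rep(0:1, each = B / 2)
#' x[1, , y == 1] <- x[1, , y == 1] + 2   # planted mean shift
#' w <- array(0.5, c(n, n, B)); for (i in 1:B) diag(w[, , i]) <- 0
#' fit <- stgcn(x, w, y, stgcn_config(channels = 4L, epochs = 20L,
#'                                    batch_size = 16L), seed = 1)
#' mean((predict(fit, x, w) > 0.5) == y)
#' @export
stgcn <- function(x, w, y, config = stgcn_config(), train_idx = NULL,
                  val_idx = NULL, val_frac = 0.1, seed = 1L) {
  stopifnot(inherits(config, "stgcn_config"))
  cl <- match.call()
  x <- as_sample_array(x)
  n <- dim(x)[1]; M <- dim(x)[2]; B <- dim(x)[3]
  lab <- encode_labels(y)
  if (length(lab$y) != B) stop("length(y) must match the number of samples")
  n_blocks <- length(config$channels)
  if (M - n_blocks * 2 * (config$Kt - 1) < 1) {
    stop("configuration error: input length too short for the block stack")
  }
  S <- propagation_array(w, n)
  if (!dim(S)[3] %in% c(1L, B)) stop("w must supply 1 or B adjacency matrices")
  if (is.null(train_idx)) {
    set.seed(seed)
    if (is.null(val_idx)) {
      val_idx <- sort(sample(B, max(1L, round(val_frac * B))))
    }
    train_idx <- setdiff(seq_len(B), val_idx)
  } else if (is.null(val_idx)) {
    val_idx <- integer(0)
  }
  conf_c <- c(unclass(config), list(seed = as.integer(seed)))
  res <- cpp_stgcn_train(x, S, lab$y, as.integer(train_idx),
                         as.integer(val_idx), conf_c)
  history <- as.data.frame(res$history)
  names(history) <- c("epoch", "train_loss", "train_acc", "val_loss", "val_acc")
  fit <- structure(
    list(config = config, params = res$params,
         final_params = res$final_params, history = history,
         best_val_loss = res$best_val_loss,
         checkpoint_epoch = res$checkpoint_epoch,
         n_nodes = n, in_len = M, label_levels = lab$levels,
         train_idx = as.integer(train_idx), val_idx = as.integer(val_idx),
         seed = as.integer(seed), call = cl),
    class = "stgcn")
  fit$fitted <- cpp_stgcn_predict(res$params, x, S, conf_c)
  fit$y <- lab$y
  fit
}

#' @export
print.stgcn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<stgcn> %s: %d block(s) (Kt = %d, channels %s), %d nodes, input length %d\n",
              toupper(cfg$variant), length(cfg$channels), cfg$Kt,
              paste(cfg$channels, collapse = "/"), x$n_nodes, x$in_len))
  cat(sprintf("  trained %d epochs on %d samples (%d validation); checkpoint at epoch %d (val loss %.4f)\n",
              nrow(x$history), length(x$train_idx), length(x$val_idx),
              x$checkpoint_epoch,
              if (is.na(x$best_val_loss)) NA else x$best_val_loss))
  invisible(x)
}

#' @export
summary.stgcn <- function(object, ...) {
  h <- object$history
  flat <- (object$in_len -
             length(object$config$channels) * 2 * (object$config$Kt - 1)) *
          object$n_nodes * utils::tail(object$config$channels, 1)
  npar <- length(unlist(object$params, use.names = FALSE))
  out <- list(config = object$config, n_parameters = npar,
              flatten_length = flat,
              final = h[nrow(h), ], checkpoint_epoch = object$checkpoint_epoch,
              best_val_loss = object$best_val_loss,
              train_accuracy = mean((object$fitted[object$train_idx] > 0.5) ==
                                      (object$y[object$train_idx] > 0.5)))
  class(out) <- "summary.stgcn"
  out
}

#' @export
print.summary.stgcn <- function(x, ...) {
  cat(sprintf("%s with %d parameters (flatten length %d)\n",
              toupper(x$config$variant), x$n_parameters, x$flatten_length))
  cat(sprintf("checkpoint epoch %d, best validation loss %.4f\n",
              x$checkpoint_epoch, x$best_val_loss))
  cat(sprintf("train accuracy at checkpoint: %.3f\n", x$train_accuracy))
  cat("last epoch:\n")
  print(x$final, row.names = FALSE)
  invisible(x)
}

#' @export
coef.stgcn <- function(object, checkpoint = TRUE, ...) {
  if (checkpoint) object$params else object$final_params
}

#' Predict class probabilities from a fitted ST-GCN
#'
#' Uses the best-validation-loss checkpoint parameters.
#'
#' @param object A fitted [stgcn()] model.
#' @param x New samples, `[n x M x B]` array or list of `mini_epoch`s.
#' @param w Adjacency input matching `x` (ignored by the `"tcnn"` variant,
#'   where it may be omitted).
#' @param type `"prob"` for probabilities of the positive class, `"class"`
#'   for hard labels at threshold 0.5.
#' @param ... Unused.
#' @return Numeric probabilities in (0, 1), or a character vector of labels.
#' @export
predict.stgcn <- function(object, x, w = NULL,
                          type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as_sample_array(x)
  stopifnot(dim(x)[1] == object$n_nodes, dim(x)[2] == object$in_len)
  if (is.null(w)) {
    if (object$config$variant != "tcnn") {
      stop("adjacency input 'w' is required for the stgcn variant")
    }
    S <- array(diag(object$n_nodes), c(object$n_nodes, object$n_nodes, 1L))
  } else {
    S <- propagation_array(w, object$n_nodes)
  }
  conf_c <- c(unclass(object$config), list(seed = object$seed))
  p <- cpp_stgcn_predict(object$params, x, S, conf_c)
  if (type == "prob") return(as.numeric(p))
  object$label_levels[(p > 0.5) + 1L]
}

#' @export
fitted.stgcn <- function(object, ...) as.numeric(object$fitted)

#' @export
residuals.stgcn <- function(object, ...) as.numeric(object$y - object$fitted)

#' Plot training and validation curves
#'
#' @param x A fitted [stgcn()] model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.stgcn <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "binary cross-entropy", ...)
  graphics::abline(v = x$checkpoint_epoch, lty = 3, col = "grey40")
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}

#' Evaluate a fitted model on a held-out test set
#'
#' Accuracy at threshold 0.5 plus the confusion counts, computed from the
#' checkpoint parameters.
#'
#' @param object A fitted [stgcn()] model.
#' @param x,w Test samples and adjacency input (see [predict.stgcn()]).
#' @param y True labels (same coding as at fit time).
#' @return List with `accuracy`, `confusion` (2 x 2 table), `n`.
#' @export
evaluate_model <- function(object, x, w, y) {
  yy <- encode_labels(y)$y
  if (!length(yy)) stop("empty test set")
  p <- predict(object, x, w, type = "prob")
  pred <- as.integer(p > 0.5)
  conf <- table(factor(yy, levels = 0:1), factor(pred, levels = 0:1),
                dnn = c("truth", "predicted"))
  list(accuracy = mean(pred == yy), confusion = conf, n = length(yy))
}
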