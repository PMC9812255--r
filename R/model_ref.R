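#' Valid temporal 1-D convolution over a frame stack
#'
#' Convolves along the time axis with the same width-`Kt` kernel at every
#' node: `out[t, v, co] = sum_{k, ci} Gamma[k, ci, co] * Y[t + k - 1, v,
#' ci]`. No padding, so the sequence shortens by `Kt - 1`.
#'
#' @param Y Numeric array `[M x n x Ci]`.
#' @param Gamma Kernel array `[Kt x Ci x Co]`.
#' @param activation `"linear"` (default) or `"relu"` applied to the output.
#' @return Numeric array `[(M - Kt + 1) x n x Co]`.
#' @export
temporal_conv <- function(Y, Gamma, activation = c("linear", "relu")) {
  activation <- match.arg(activation)
  stopifnot(length(dim(Y)) == 3L, length(dim(Gamma)) == 3L)
  M <- dim(Y)[1]; n <- dim(Y)[2]; Ci <- dim(Y)[3]
  Kt <- dim(Gamma)[1]
  if (dim(Gamma)[2] != Ci) stop("kernel input channels must match Y")
  if (M < Kt) stop(sprintf("sequence length %d shorter than kernel width %d", M, Kt))
  Co <- dim(Gamma)[3]
  Mo <- M - Kt + 1L
  out <- array(0, c(Mo, n, Co))
  for (k in seq_len(Kt)) {
    Yk <- Y[k:(k + Mo - 1L), , , drop = FALSE]
    Gk <- matrix(Gamma[k, , ], Ci, Co)
    out <- out + array(matrix(Yk, Mo * n, Ci) %*% Gk, c(Mo, n, Co))
  }
  if (activation == "relu") out <- pmax(out, 0)
  out
}

# layer normalisation with a learnable per-channel affine (gamma, beta);
# scope "sample" normalises the whole block output jointly, scope "node"
# normalises each node's (time, channel) slab; eps matches the trainer
layer_norm <- function(X, gamma, beta, scope = "sample", eps = 1e-5) {
  n <- dim(X)[2]; C <- dim(X)[3]
  if (scope == "sample") {
    m <- mean(X)
    s <- sqrt(mean((X - m)^2) + eps)
    X <- (X - m) / s
    return(sweep(sweep(X, 3, gamma, "*"), 3, beta, "+"))
  }
  for (v in seq_len(n)) {
    slab <- X[, v, , drop = FALSE]
    m <- mean(slab)
    s <- sqrt(mean((slab - m)^2) + eps)
    X[, v, ] <- sweep(sweep((X[, v, , drop = FALSE] - m) / s,
                            3, gamma, "*"), 3, beta, "+")
  }
  X
}

#' One spatial-temporal convolution block
#'
#' The block computes `temporal conv (Gamma0) -> graph conv (Theta, via S)
#' -> ReLU -> temporal conv (Gamma1) -> layer normalisation`, shortening
#' the time axis by `2 (Kt - 1)`.
#'
#' @param X Numeric array `[M x n x Ci]`.
#' @param params List with `G0` (`[Kt x Ci x Cb]`), `Theta` (`[Cb x Cb]`),
#'   `G1` (`[Kt x Cb x Co]`), `ln_gamma`, `ln_beta` (length `Co`).
#' @param S Propagation matrix `[n x n]`; the temporal-only baseline uses
#'   the identity.
#' @param ln_scope Layer-norm grouping, `"sample"` or `"node"` (see
#'   [stgcn_config()]).
#' @return Numeric array `[(M - 2 (Kt - 1)) x n x Co]`.
#' @export
st_conv_block <- function(X, params, S, ln_scope = "sample") {
  Y <- temporal_conv(X, params$G0)
  Z <- graph_conv(Y, S, params$Theta)
  Z <- pmax(Z, 0)
  Z <- temporal_conv(Z, params$G1)
  if (dim(Z)[1] < 1L) stop("block output time length < 1; reduce Kt or blocks")
  layer_norm(Z, params$ln_gamma, params$ln_beta, scope = ln_scope)
}

# reference forward pass: slow but transparent; the compiled trainer is
# tested against this function to 1e-8
stgcn_forward_ref <- function(params, X, S, config) {
  M <- ncol(X); n <- nrow(X)
  x <- array(t(X), c(M, n, 1L))
  Suse <- if (config$variant == "tcnn") diag(n) else S
  for (b in params$blocks) {
    x <- st_conv_block(x, b, Suse, ln_scope = config$ln_scope %||% "sample")
  }
  z <- as.vector(aperm(x, c(2, 3, 1)))   # node fastest, then channel, then time
  logit <- sum(params$head_w * z) + params$head_b
  stats::plogis(logit)
}
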