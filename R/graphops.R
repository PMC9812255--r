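#' Symmetric-normalized graph Laplacian
#'
#' `L = I - D^{-1/2} W D^{-1/2}` for a nonnegative symmetric adjacency `W`
#' with degree `D_ii = sum_j W_ij`. Isolated nodes (zero degree) use the
#' pseudo-inverse convention `D^{-1/2} = 0`, so their Laplacian row is the
#' identity row. For such `W` all eigenvalues of `L` lie in `[0, 2]`.
#'
#' @param W Square symmetric nonnegative matrix.
#' @return The Laplacian matrix `L` (symmetric).
#' @export
normalized_laplacian <- function(W) {
  check_adjacency(W)
  n <- nrow(W)
  d <- rowSums(W)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- diag(n) - (dinv %o% dinv) * W
  (L + t(L)) / 2
}

check_adjacency <- function(W, nonneg = TRUE) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop("W must be a square matrix")
  if (max(abs(W - t(W))) > 1e-10) stop("W must be symmetric")
  if (nonneg && min(W) < 0) {
    stop("W must be nonnegative (rectify signed measures upstream)")
  }
  invisible(TRUE)
}

#' Graph operator bundle
#'
#' Packages the operators derived from one adjacency matrix: the normalized
#' Laplacian `L`, the scaled Laplacian `L_scaled = 2 L / lambda_max - I`
#' used by Chebyshev filters, the renormalized first-order propagation `S`,
#' and optionally the eigendecomposition of `L`.
#'
#' @param W Square symmetric nonnegative adjacency matrix.
#' @param exact_lambda_max If `TRUE`, use the exact largest eigenvalue of
#'   `L`; otherwise the conventional assumption `lambda_max = 2`.
#' @param eigen If `TRUE`, also return eigenvectors `U` and eigenvalues
#'   `Lambda` of `L`.
#' @return An object of class `"graph_operator"` with fields `W`, `L`,
#'   `lambda_max`, `L_scaled`, `S`, and optionally `U`, `Lambda`.
#' @export
graph_operator <- function(W, exact_lambda_max = FALSE, eigen = FALSE) {
  L <- normalized_laplacian(W)
  ev <- NULL
  if (exact_lambda_max || eigen) ev <- base::eigen(L, symmetric = TRUE)
  lambda_max <- if (exact_lambda_max) max(ev$values) else 2
  L_scaled <- 2 * L / lambda_max - diag(nrow(L))
  out <- list(W = W, L = L, lambda_max = lambda_max, L_scaled = L_scaled,
              S = renorm_propagation(W))
  if (eigen) { out$U <- ev$vectors; out$Lambda <- ev$values }
  structure(out, class = "graph_operator")
}

#' @export
print.graph_operator <- function(x, ...) {
  cat(sprintf("<graph_operator> %d nodes, lambda_max = %g%s\n", nrow(x$W),
              x$lambda_max,
              if (is.null(x$U)) "" else " (eigendecomposition attached)"))
  invisible(x)
}

#' Renormalized first-order propagation matrix
#'
#' `S = Dt^{-1/2} (W + I) Dt^{-1/2}` with `Dt_ii = sum_j (W + I)_ij`: the
#' self-loop-augmented, degree-renormalized operator of the first-order
#' spectral graph convolution. A first-order layer computes `theta * S * x`.
#' `S` is symmetric with spectral radius at most 1, and the self-loops make
#' it well-defined even for isolated nodes.
#'
#' @param W Square symmetric nonnegative adjacency matrix.
#' @return The propagation matrix `S`.
#' @export
renorm_propagation <- function(W) {
  check_adjacency(W)
  Wt <- W + diag(nrow(W))
  dinv <- 1 / sqrt(rowSums(Wt))
  S <- (dinv %o% dinv) * Wt
  (S + t(S)) / 2
}

#' Chebyshev-polynomial spectral graph filter
#'
#' Filters a graph signal with `sum_k theta_k T_k(L_scaled) x` using the
#' recurrence `T_0 = I`, `T_1 = L_scaled`, `T_k = 2 L_scaled T_{k-1} -
#' T_{k-2}`. This evaluates a K-hop-localized spectral filter without any
#' eigendecomposition; with `lambda_max = 2` and `theta = c(theta, -theta)`
#' it reduces to the first-order layer `theta (I + D^{-1/2} W D^{-1/2}) x`.
#'
#' @param x Numeric graph signal (length-n vector or n x c matrix).
#' @param gop A `graph_operator` (or an adjacency matrix, converted with
#'   `lambda_max = 2`).
#' @param theta Numeric vector of K polynomial coefficients (K >= 1).
#' @return The filtered signal, same shape as `x`.
#' @export
chebyshev_filter <- function(x, gop, theta) {
  if (is.matrix(gop) && !inherits(gop, "graph_operator")) {
    gop <- graph_operator(gop)
  }
  stopifnot(inherits(gop, "graph_operator"))
  K <- length(theta)
  if (K < 1L) stop("Chebyshev order K must be at least 1")
  was_vector <- is.null(dim(x))
  x <- as.matrix(x)
  Lt <- gop$L_scaled
  Tkm2 <- x
  out <- theta[1] * x
  if (K >= 2L) {
    Tkm1 <- Lt %*% x
    out <- out + theta[2] * Tkm1
    if (K >= 3L) {
      for (k in 3:K) {
        Tk <- 2 * (Lt %*% Tkm1) - Tkm2
        out <- out + theta[k] * Tk
        Tkm2 <- Tkm1
        Tkm1 <- Tk
      }
    }
  }
  if (ncol(out) == 1L && was_vector) drop(out) else out
}

#' Graph convolution of a multichannel frame stack
#'
#' Applies the same first-order graph convolution to every time frame of a
#' `[M x n x Ci]` array: for frame `t` and output channel `j`,
#' `Y[t, , j] = sum_i S %*% X[t, , i] * Theta[i, j]`, i.e.
#' `Y_t = S X_t Theta`.
#'
#' @param X Numeric array `[M x n x Ci]` (frames x nodes x channels).
#' @param S Propagation matrix `[n x n]` (see [renorm_propagation()]).
#' @param Theta Kernel matrix `[Ci x Co]`.
#' @return Numeric array `[M x n x Co]`.
#' @export
graph_conv <- function(X, S, Theta) {
  stopifnot(length(dim(X)) == 3L)
  M <- dim(X)[1]; n <- dim(X)[2]; Ci <- dim(X)[3]
  Theta <- as.matrix(Theta)
  if (nrow(S) != n || ncol(S) != n) stop("S must be n x n")
  if (nrow(Theta) != Ci) stop("Theta rows must match input channels")
  Co <- ncol(Theta)
  out <- array(0, c(M, n, Co))
  for (t in seq_len(M)) {
    out[t, , ] <- S %*% matrix(X[t, , ], n, Ci) %*% Theta
  }
  out
}
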