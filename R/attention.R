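#' Parameters of the per-visit attention encoder
#'
#' Holds the learned projections of a multi-head scaled dot-product
#' attention layer plus a position-wise feed-forward sublayer. With model
#' dimension `c` and `n_heads` heads, each head projects entity vectors
#' into a `d_k = c / n_heads` subspace via query/key/value matrices
#' (`c x d_k` each); head outputs are concatenated and passed through an
#' output projection (`c x c`). The feed-forward sublayer applies
#' `X + relu(X W1) W2` position-wise (`W1: c x f`, `W2: f x c`, no biases).
#'
#' All matrices are drawn from one seeded generator (Gaussian, sd
#' `1/sqrt(c)`).
#'
#' @param dim Model dimension `c` (default 512, matching the method's
#'   published configuration).
#' @param n_heads Number of attention heads (default 8); must divide `dim`.
#' @param ff_dim Inner feed-forward width `f` (default `4 * dim`).
#' @param dropout Dropout rate applied to attention weights during
#'   training (default 0.1); must be in `[0, 1)`.
#' @param seed RNG seed for initialization.
#' @return An object of class `attention_params`.
#' @export
attention_params <- function(dim = 512L, n_heads = 8L, ff_dim = 4L * dim,
                             dropout = 0.1, seed = 1L) {
  dim <- as.integer(dim)
  n_heads <- as.integer(n_heads)
  ff_dim <- as.integer(ff_dim)
  if (dim %% n_heads != 0L) {
    stop("model dimension (", dim, ") must be divisible by n_heads (",
         n_heads, ")", call. = FALSE)
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)", call. = FALSE)
  dk <- dim %/% n_heads
  sd0 <- 1 / sqrt(dim)
  with_seed(seed, {
    mk <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sd0), nr, nc)
    structure(list(
      dim = dim, n_heads = n_heads, d_k = dk, ff_dim = ff_dim,
      dropout = dropout,
      Wq = lapply(seq_len(n_heads), function(i) mk(dim, dk)),
      Wk = lapply(seq_len(n_heads), function(i) mk(dim, dk)),
      Wv = lapply(seq_len(n_heads), function(i) mk(dim, dk)),
      Wo = mk(dim, dim),
      W1 = mk(dim, ff_dim),
      W2 = mk(ff_dim, dim)
    ), class = "attention_params")
  })
}

#' @export
print.attention_params <- function(x, ...) {
  cat("<attention_params> dim =", x$dim, "| heads =", x$n_heads,
      "| d_k =", x$d_k, "| ff_dim =", x$ff_dim, "| dropout =", x$dropout, "\n")
  invisible(x)
}

#' Scaled dot-product attention
#'
#' Computes `softmax(Q K' / sqrt(d)) V` with a numerically stable
#' (max-subtracted) row-wise softmax. Each output row is a convex
#' combination of the rows of `V`. When `options(ehrvec.check = TRUE)` the
#' attention-weight rows are asserted to sum to 1 within 1e-9.
#'
#' @param Q,K,V Numeric matrices, `n x d` each (`K`, `V` with the same
#'   number of rows; `Q` and `K` with the same number of columns).
#' @param return_weights If `TRUE`, also return the attention matrix.
#' @return The `n x d` output matrix, or (with `return_weights`) a list
#'   with `output` and `weights`.
#' @export
scaled_dot_attention <- function(Q, K, V, return_weights = FALSE) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop("Q and K must have the same width", call. = FALSE)
  if (nrow(K) != nrow(V)) stop("K and V must have the same number of rows",
                               call. = FALSE)
  stopifnot_finite(Q, "Q"); stopifnot_finite(K, "K"); stopifnot_finite(V, "V")
  d <- ncol(Q)
  if (d < 1L || nrow(Q) < 1L) stop("Q must be a non-empty matrix", call. = FALSE)
  A <- row_softmax(tcrossprod(Q, K) / sqrt(d))
  if (isTRUE(getOption("ehrvec.check", FALSE))) {
    stopifnot(all(abs(rowSums(A) - 1) < 1e-9), all(A >= 0))
  }
  out <- A %*% V
  if (return_weights) list(output = out, weights = A) else out
}

# forward pass of the full encoder (attention + FFN) over one visit's
# entity-vector matrix X (m x c); returns all intermediates for backprop.
# Dropout masks are drawn from the *current* RNG stream when train_mode.
encoder_forward <- function(X, params, train_mode = FALSE) {
  m <- nrow(X)
  nh <- params$n_heads
  dk <- params$d_k
  p <- params$dropout
  heads <- vector("list", nh)
  for (i in seq_len(nh)) {
    Q <- X %*% params$Wq[[i]]
    K <- X %*% params$Wk[[i]]
    V <- X %*% params$Wv[[i]]
    A <- row_softmax(tcrossprod(Q, K) / sqrt(dk))
    D <- NULL
    At <- A
    if (train_mode && p > 0) {
      D <- matrix((stats::runif(m * m) >= p) / (1 - p), m, m)
      At <- A * D
    }
    heads[[i]] <- list(Q = Q, K = K, V = V, A = A, D = D, At = At,
                       H = At %*% V)
  }
  Hcat <- do.call(cbind, lapply(heads, `[[`, "H"))
  M <- Hcat %*% params$Wo
  G <- M %*% params$W1
  U <- G * (G > 0)
  Z <- M + U %*% params$W2
  list(X = X, heads = heads, Hcat = Hcat, M = M, G = G, U = U, Z = Z)
}

# backward pass: given dZ (m x c), returns gradients for X and all encoder
# parameters (same structure as attention_params weight fields).
encoder_backward <- function(fw, params, dZ) {
  nh <- params$n_heads
  dk <- params$d_k
  dU <- dZ %*% t(params$W2)
  dW2 <- crossprod(fw$U, dZ)
  dG <- dU * (fw$G > 0)
  dW1 <- crossprod(fw$M, dG)
  dM <- dZ + dG %*% t(params$W1)
  dHcat <- dM %*% t(params$Wo)
  dWo <- crossprod(fw$Hcat, dM)
  dX <- matrix(0, nrow(fw$X), ncol(fw$X))
  dWq <- vector("list", nh); dWk <- vector("list", nh); dWv <- vector("list", nh)
  for (i in seq_len(nh)) {
    hd <- fw$heads[[i]]
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    dH <- dHcat[, cols, drop = FALSE]
    dAt <- tcrossprod(dH, hd$V)
    dV <- crossprod(hd$At, dH)
    dA <- if (is.null(hd$D)) dAt else dAt * hd$D
    dS <- hd$A * (dA - rowSums(dA * hd$A))  # softmax jacobian, row-wise
    dS <- dS / sqrt(dk)
    dQ <- dS %*% hd$K
    dK <- crossprod(dS, hd$Q)
    dWq[[i]] <- crossprod(fw$X, dQ)
    dWk[[i]] <- crossprod(fw$X, dK)
    dWv[[i]] <- crossprod(fw$X, dV)
    dX <- dX + tcrossprod(dQ, params$Wq[[i]]) +
      tcrossprod(dK, params$Wk[[i]]) + tcrossprod(dV, params$Wv[[i]])
  }
  list(X = dX, Wq = dWq, Wk = dWk, Wv = dWv, Wo = dWo, W1 = dW1, W2 = dW2)
}

#' Multi-head self-attention over one visit
#'
#' Runs each head's query/key/value projection of `X`, applies
#' [scaled_dot_attention()] per head, concatenates the head outputs and
#' applies the output projection. In training mode, dropout is applied to
#' the attention weights using the current RNG stream (seed it with
#' [set.seed()] or leave `train_mode = FALSE` for deterministic output).
#'
#' @param X `n x c` matrix of the visit's entity vectors.
#' @param params An [attention_params()].
#' @param train_mode Apply attention-weight dropout?
#' @return `n x c` matrix of contextualized vectors.
#' @export
multi_head_attention <- function(X, params, train_mode = FALSE) {
  X <- as.matrix(X)
  if (ncol(X) != params$dim) {
    stop("X has ", ncol(X), " columns; params expect ", params$dim, call. = FALSE)
  }
  stopifnot_finite(X, "X")
  nh <- params$n_heads
  heads <- vector("list", nh)
  p <- params$dropout
  m <- nrow(X)
  for (i in seq_len(nh)) {
    res <- scaled_dot_attention(X %*% params$Wq[[i]], X %*% params$Wk[[i]],
                                X %*% params$Wv[[i]], return_weights = TRUE)
    A <- res$weights
    if (train_mode && p > 0) {
      A <- A * matrix((stats::runif(m * m) >= p) / (1 - p), m, m)
    }
    heads[[i]] <- A %*% (X %*% params$Wv[[i]])
  }
  do.call(cbind, heads) %*% params$Wo
}

#' Position-wise feed-forward sublayer with residual connection
#'
#' Applies `X + relu(X W1) W2` independently to each row.
#'
#' @param X `n x c` matrix.
#' @param params An [attention_params()].
#' @return `n x c` matrix.
#' @export
feed_forward <- function(X, params) {
  X <- as.matrix(X)
  if (ncol(X) != params$dim) {
    stop("X has ", ncol(X), " columns; params expect ", params$dim, call. = FALSE)
  }
  G <- X %*% params$W1
  X + (G * (G > 0)) %*% params$W2
}
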