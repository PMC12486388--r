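# Multiscale attention (MUSE) fusion block.  Three parallel branches over
# the multiview embedding X (rows ordered by residue sequence position) are
# summed with a residual:
#   X_muse = X + Attention(X) + Conv(X) + Pointwise(X)
# Attention is single-head scaled dot-product self-attention; Conv is a
# dynamic depth-wise separable convolution (softmax-weighted mixture of
# depth-wise convolutions with different odd kernel widths, zero-padded at
# the sequence ends) applied to the shared value projection V = X W^V;
# Pointwise is a position-wise two-layer feed-forward network.

#' Initialise MUSE parameters
#'
#' Glorot-uniform projections `W_Q`, `W_K`, `W_V`, `W_O` (the value
#' projection `W_V` is shared between the attention and convolution
#' branches), a depth-wise kernel bank with per-channel weights for each
#' kernel width, learnable kernel-mixing logits `alpha`, the convolution
#' output projection `W_out`, and the position-wise feed-forward parameters
#' `W_1`, `b_1`, `W_2`, `b_2`.
#'
#' @param d Embedding width (896 at model defaults).
#' @param kernels Odd depth-wise kernel widths (default `c(1, 3, 5)`).
#' @param hidden Feed-forward hidden width (default `d`).
#' @return Nested list of parameter matrices; `d_k = d` (single head).
#' @export
init_muse_params <- function(d = 896, kernels = c(1, 3, 5), hidden = d) {
  if (any(kernels %% 2 == 0)) stop("kernel widths must be odd, got ",
                                   paste(kernels, collapse = ", "))
  list(
    # branch output projections damped at init so the fused block starts
    # near the residual identity
    W_Q = glorot(d, d), W_K = glorot(d, d), W_V = glorot(d, d),
    W_O = glorot(d, d) * 0.1,
    kernels = as.integer(kernels),
    kernel_bank = lapply(kernels, function(k) glorot(k, d)),
    alpha = matrix(0, length(kernels), 1),
    W_out = glorot(d, d) * 0.1,
    ffn = list(W1 = glorot(d, hidden), b1 = matrix(0, 1, hidden),
               W2 = glorot(hidden, d) * 0.1, b2 = matrix(0, 1, d)),
    d_k = d
  )
}

# --- tensor-level internals -------------------------------------------------

.self_attention_t <- function(X, prm, d_k) {
  Q <- ag_matmul(X, prm$W_Q)
  K <- ag_matmul(X, prm$W_K)
  V <- ag_matmul(X, prm$W_V)
  S <- ag_softmax_rows(ag_scale(ag_matmul(Q, ag_t(K)), 1 / sqrt(d_k)))
  list(out = ag_matmul(ag_matmul(S, V), prm$W_O), attention = S, V = V)
}

# Depth-wise 1-D convolution along the sequence (rows), zero-padded:
# out[i, c] = sum_{j=1..k} W[j, c] * X[i + j - ceil((k+1)/2), c]
.depthwise_conv_t <- function(X, Wk, k) {
  if (k %% 2 == 0) stop("kernel width must be odd, got ", k)
  n <- nrow(X$value)
  tp <- tape_of(X)
  Xp <- ag_rbind(X, ag_const(matrix(0, 1, ncol(X$value)), tp))
  centre <- ceiling((k + 1) / 2)
  out <- NULL
  for (j in seq_len(k)) {
    idx <- seq_len(n) + j - centre
    idx[idx < 1L | idx > n] <- n + 1L  # zero-pad row
    tap <- ag_mul(ag_rows(Xp, idx), ag_rows(Wk, j))
    out <- if (is.null(out)) tap else ag_add(out, tap)
  }
  out
}

.conv_branch_t <- function(V, prm, ki) {
  ag_matmul(.depthwise_conv_t(V, prm$kernel_bank[[ki]], prm$kernels[ki]), prm$W_out)
}

.dynamic_conv_t <- function(V, prm) {
  nk <- length(prm$kernels)
  mix <- ag_softmax_rows(ag_t(prm$alpha))  # 1 x nk, on the simplex
  out <- NULL
  tp <- tape_of(V)
  for (ki in seq_len(nk)) {
    sel <- matrix(0, nk, 1); sel[ki] <- 1
    wi <- ag_matmul(mix, ag_const(sel, tp))  # 1 x 1 mixing weight
    term <- ag_mul(.conv_branch_t(V, prm, ki), wi)
    out <- if (is.null(out)) term else ag_add(out, term)
  }
  out
}

.pointwise_ffn_t <- function(X, prm) {
  ag_add(ag_matmul(ag_relu(ag_add(ag_matmul(X, prm$ffn$W1), prm$ffn$b1)),
                   prm$ffn$W2), prm$ffn$b2)
}

.muse_fuse_t <- function(X, prm, d_k) {
  att <- .self_attention_t(X, prm, d_k)
  conv <- .dynamic_conv_t(att$V, prm)  # shared value projection
  ffn <- .pointwise_ffn_t(X, prm)
  out <- ag_add(ag_add(ag_add(X, att$out), conv), ffn)
  list(out = out, attention = att$attention)
}

# --- exported matrix-level surface -----------------------------------------

.muse_tape <- function(X, params) {
  tp <- ag_tape()
  prm <- .wrap_params_t(params, tp)
  prm$kernels <- params$kernels
  prm$d_k <- params$d_k
  list(tp = tp, X = ag_const(as.matrix(X), tp), prm = prm)
}

#' Single-head self-attention branch
#'
#' `softmax(Q K^T / sqrt(d_k)) V W_O` with `Q = X W_Q`, `K = X W_K`,
#' `V = X W_V`.
#'
#' @param X `N_v` x d embedding matrix (rows in residue sequence order).
#' @param params MUSE parameter list (see [init_muse_params()]).
#' @return `N_v` x d matrix, with the row-stochastic `N_v` x `N_v`
#'   attention matrix as attribute `"attention"`.
#' @export
self_attention <- function(X, params) {
  w <- .muse_tape(X, params)
  st <- .self_attention_t(w$X, w$prm, params$d_k)
  out <- st$out$value
  attr(out, "attention") <- st$attention$value
  out
}

#' Depth-wise 1-D convolution along the sequence
#'
#' Per-channel convolution centred at each position with zero padding at
#' the sequence boundaries.
#'
#' @param X `N_v` x d matrix.
#' @param Wk `k` x d per-channel tap weights.
#' @return `N_v` x d matrix.
#' @export
depthwise_conv <- function(X, Wk) {
  Wk <- as.matrix(Wk)
  tp <- ag_tape()
  .depthwise_conv_t(ag_const(as.matrix(X), tp), ag_const(Wk, tp), nrow(Wk))$value
}

#' One depth-wise separable convolution branch
#'
#' `Conv_k(X) = DepthConv_k(V_2) W_out` with `V_2 = X W_V` (the value
#' projection shared with the attention branch).
#'
#' @param X `N_v` x d matrix.
#' @param params MUSE parameter list.
#' @param kernel_index Which kernel of the bank to use.
#' @return `N_v` x d matrix.
#' @export
conv_branch <- function(X, params, kernel_index = 1L) {
  w <- .muse_tape(X, params)
  V <- ag_matmul(w$X, w$prm$W_V)
  .conv_branch_t(V, w$prm, kernel_index)$value
}

#' Dynamic convolution: softmax-weighted mixture of kernel widths
#'
#' @param X `N_v` x d matrix.
#' @param params MUSE parameter list (mixing logits `params$alpha`).
#' @return `N_v` x d matrix.
#' @export
dynamic_conv <- function(X, params) {
  w <- .muse_tape(X, params)
  V <- ag_matmul(w$X, w$prm$W_V)
  .dynamic_conv_t(V, w$prm)$value
}

#' Position-wise feed-forward branch
#'
#' `ReLU(X W_1 + b_1) W_2 + b_2`, applied independently at every sequence
#' position.
#'
#' @param X `N_v` x d matrix.
#' @param params MUSE parameter list.
#' @return `N_v` x d matrix.
#' @export
pointwise_ffn <- function(X, params) {
  w <- .muse_tape(X, params)
  .pointwise_ffn_t(w$X, w$prm)$value
}

#' MUSE fusion
#'
#' Element-wise sum of the residual and the three branches:
#' `X + Attention(X) + Conv(X) + Pointwise(X)`.
#'
#' @param X `N_v` x d embedding matrix.
#' @param params MUSE parameter list.
#' @return `N_v` x d fused matrix `X_muse`, with the attention matrix as
#'   attribute `"attention"`.
#' @export
muse_fuse <- function(X, params) {
  w <- .muse_tape(X, params)
  st <- .muse_fuse_t(w$X, w$prm, params$d_k)
  out <- st$out$value
  attr(out, "attention") <- st$attention$value
  out
}

#' Export the self-attention map
#'
#' Computes the `N_v` x `N_v` row-stochastic attention matrix of the MUSE
#' self-attention branch and writes it as TSV.
#'
#' @param X `N_v` x d embedding matrix.
#' @param params MUSE parameter list.
#' @param out_path Output TSV path.
#' @return The attention matrix, invisibly.
#' @export
export_attention_map <- function(X, params, out_path) {
  A <- attr(self_attention(X, params), "attention")
  utils::write.table(A, out_path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(A)
}
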