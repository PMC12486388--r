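# Edge graph attention network (EGAT): attention logits are derived from
# explicitly updated edge features rather than node pairs alone.  Per layer:
#   e_ij' = LeakyReLU(A [h_i || e_ij || h_j])
#   a_ij  = softmax_j( F . e_ij' )          (over incoming edges of i,
#                                            including the self-loop)
#   h_i'  = ReLU(h_i + sum_j a_ij W h_j)    (residual connection)
# Per-layer outputs h^1..h^L are concatenated into the multiscale local
# feature (width L * 128 at defaults).

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

affine_params <- function(d_in, d_out) {
  list(W = glorot(d_in, d_out), b = matrix(0, 1, d_out))
}

#' Initialise EGAT parameters
#'
#' Draws Glorot-uniform initial values for the input projections (node
#' 62->128, edge 2->128) and the per-layer tensors: `A` (edge update from
#' the `[h_i || e_ij || h_j]` concatenation), `F` (attention logit vector)
#' and `W` (node transform).  Uses the current RNG state.
#'
#' @param d_in Node input width (62).
#' @param d_h Node embedding width (128).
#' @param d_e_in Raw edge feature width (2).
#' @param d_e Edge embedding width (128).
#' @param layers Number of EGAT layers (default 5).
#' @return Nested list of parameter matrices.
#' @export
init_egat_params <- function(d_in = 62, d_h = 128, d_e_in = 2, d_e = 128, layers = 5) {
  list(
    node_in = affine_params(d_in, d_h),
    edge_in = affine_params(d_e_in, d_e),
    layers = lapply(seq_len(layers), function(l) {
      # W damped at init so the residual stack starts near the identity
      list(A = glorot(2 * d_h + d_e, d_e),
           F = glorot(d_e, 1),
           W = glorot(d_h, d_h) * 0.1)
    })
  )
}

# --- tensor-level internals -------------------------------------------------

.affine_t <- function(x, prm) ag_add(ag_matmul(x, prm$W), prm$b)

.egat_layer_t <- function(h, e, edges, prm, slope = 0.2) {
  n <- nrow(h$value)
  d_h <- ncol(h$value)
  d_e <- ncol(e$value)
  i <- edges[, 1]; j <- edges[, 2]
  # A [h_i || e_ij || h_j] evaluated block-wise: the h blocks are computed
  # once per node and gathered per edge, instead of per edge
  A_i <- ag_rows(prm$A, seq_len(d_h))
  A_e <- ag_rows(prm$A, d_h + seq_len(d_e))
  A_j <- ag_rows(prm$A, d_h + d_e + seq_len(d_h))
  pre <- ag_add(ag_add(ag_rows(ag_matmul(h, A_i), i), ag_matmul(e, A_e)),
                ag_rows(ag_matmul(h, A_j), j))
  e2 <- ag_leaky_relu(pre, slope)
  z <- ag_matmul(e2, prm$F)
  # numerically stable softmax over incoming edges of each node i
  zmax <- tapply(z$value[, 1], i, max)[as.character(i)]
  zs <- ag_sub(z, ag_const(matrix(zmax, ncol = 1), tape_of(z)))
  ez <- ag_exp(zs)
  denom <- ag_segment_sum(ez, i, n)
  alpha <- ag_div(ez, ag_rows(denom, i))
  Wh <- ag_matmul(h, prm$W)
  msg <- ag_mul(ag_rows(Wh, j), alpha)
  agg <- ag_segment_sum(msg, i, n)
  h2 <- ag_relu(ag_add(h, agg))
  if (any(!is.finite(h2$value))) stop("NaN in EGAT node update")
  list(h = h2, e = e2, alpha = alpha)
}

.egat_stack_t <- function(h0, e0, edges, prms, L) {
  hs <- vector("list", L)
  alphas <- vector("list", L)
  h <- h0; e <- e0
  for (l in seq_len(L)) {
    st <- .egat_layer_t(h, e, edges, prms[[l]])
    h <- st$h; e <- st$e
    hs[[l]] <- h
    alphas[[l]] <- st$alpha
  }
  list(hs = hs, alphas = alphas)
}

.wrap_params_t <- function(prm, tape, requires = FALSE) {
  rapply(prm, function(m) ag_leaf(as.matrix(m), tape, requires_grad = requires),
         classes = c("matrix", "numeric", "array"), how = "replace")
}

# --- exported matrix-level surface -----------------------------------------

#' Project node features into the EGAT embedding space
#'
#' Affine map from the 62-wide node features to the 128-wide EGAT node
#' embedding.
#'
#' @param X `N_v` x 62 node feature matrix.
#' @param params EGAT parameter list (see [init_egat_params()]).
#' @return `N_v` x 128 matrix.
#' @export
egat_input_projection <- function(X, params) {
  as.matrix(X) %*% params$node_in$W + matrix(params$node_in$b, nrow(X),
                                             ncol(params$node_in$b), byrow = TRUE)
}

#' Project raw edge features into the EGAT edge embedding space
#'
#' @param E `N_e` x 2 raw edge feature matrix.
#' @param params EGAT parameter list.
#' @return `N_e` x 128 matrix.
#' @export
egat_edge_projection <- function(E, params) {
  as.matrix(E) %*% params$edge_in$W + matrix(params$edge_in$b, nrow(E),
                                             ncol(params$edge_in$b), byrow = TRUE)
}

#' One EGAT layer
#'
#' @param h `N_v` x 128 node embeddings.
#' @param e `N_e` x 128 edge embeddings.
#' @param edges Integer `N_e` x 2 edge list (self-loops included; every node
#'   must have at least one incoming edge).
#' @param layer_params One element of `init_egat_params()$layers`.
#' @return List with updated `h`, `e` and the attention weights `alpha`
#'   (`N_e` x 1; sums to 1 over the incoming edges of each node).
#' @export
egat_layer <- function(h, e, edges, layer_params) {
  tp <- ag_tape()
  st <- .egat_layer_t(ag_const(as.matrix(h), tp), ag_const(as.matrix(e), tp),
                      edges, .wrap_params_t(layer_params, tp))
  list(h = st$h$value, e = st$e$value, alpha = st$alpha$value)
}

#' Run the EGAT stack
#'
#' Applies `L` EGAT layers and returns the per-layer node features
#' `h^1 .. h^L` (the multiscale local views).
#'
#' @param h0 `N_v` x 128 initial node embeddings.
#' @param e0 `N_e` x 128 initial edge embeddings.
#' @param edges Integer edge list with self-loops.
#' @param params EGAT parameter list.
#' @param L Number of layers (default: all initialised layers).
#' @return List of `L` matrices, each `N_v` x 128, with the per-layer
#'   attention weights as attribute `"alphas"`.
#' @export
egat_stack <- function(h0, e0, edges, params, L = length(params$layers)) {
  stopifnot(L >= 1, L <= length(params$layers))
  tp <- ag_tape()
  st <- .egat_stack_t(ag_const(as.matrix(h0), tp), ag_const(as.matrix(e0), tp),
                      edges, .wrap_params_t(params$layers, tp), L)
  out <- lapply(st$hs, ag_value)
  attr(out, "alphas") <- lapply(st$alphas, ag_value)
  out
}

#' Concatenate per-layer features into the multiscale local feature
#'
#' @param h_list List of `N_v` x d matrices (one per EGAT layer).
#' @return `N_v` x (L*d) matrix; block `l` equals `h_list[[l]]` bit-exactly.
#' @export
multiscale_concat <- function(h_list) {
  stopifnot(length(h_list) >= 1)
  widths <- vapply(h_list, ncol, integer(1))
  if (length(unique(widths)) != 1L) stop("ragged layer widths: ", paste(widths, collapse = ", "))
  do.call(cbind, h_list)
}

# --- ablation fallback ------------------------------------------------------

.gcn_layer_t <- function(h, edges, W, use_relu = TRUE) {
  n <- nrow(h$value)
  i <- edges[, 1]; j <- edges[, 2]
  deg <- tabulate(i, nbins = n)
  coef <- 1 / sqrt(deg[i] * deg[j])
  hW <- ag_matmul(h, W)
  msg <- ag_mul(ag_rows(hW, j), ag_const(matrix(coef, ncol = 1), tape_of(h)))
  agg <- ag_segment_sum(msg, i, n)
  if (use_relu) ag_relu(agg) else agg
}

#' Plain graph-convolution layer (ablation fallback)
#'
#' Symmetric-normalised mean aggregation
#' `h' = ReLU(D^{-1/2} (A + I) D^{-1/2} h W)`, used when the edge-attention
#' pathway is ablated.  The supplied edge list must already contain
#' self-loops.
#'
#' @param h `N_v` x d node features.
#' @param edges Integer edge list with self-loops.
#' @param W d x d' weight matrix.
#' @return `N_v` x d' matrix.
#' @export
gcn_layer <- function(h, edges, W) {
  tp <- ag_tape()
  out <- .gcn_layer_t(ag_const(as.matrix(h), tp), edges,
                      ag_const(as.matrix(W), tp))
  out$value
}
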