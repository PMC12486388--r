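# E(n)-equivariant graph neural network (EGNN).  Each equivariant graph
# convolutional layer (EGCL) computes
#   m_ij = phi_e(h_i, h_j, ||x_i - x_j||^2, e_ij)
#   x_i' = x_i + C * sum_{j in N(i)} (x_i - x_j) * phi_x(m_ij),  C = 1/(M-1)
#   m_i  = sum_{j in N(i)} m_ij
#   h_i' = ReLU(h_i + phi_h(h_i + m_i))
# Node features depend on coordinates only through squared distances, so
# h is invariant to rotations, reflections and translations, while the
# coordinate stream transforms equivariantly.  The difference form
# (x_i - x_j) of the coordinate update preserves translation equivariance;
# a sum-form variant (x_i + x_j), which breaks it, can be selected with
# `coord_sum = TRUE` for comparison.  Aggregation runs over graph
# neighbours (j != i).  Only the last layer's h is used downstream, as the
# global node feature.

# out_scale damps the output layer at initialisation so deep residual
# stacks with neighbourhood sums start near the identity and stay finite;
# the layer equations themselves are unchanged.
mlp2_params <- function(d_in, hidden, d_out, out_scale = 1) {
  list(W1 = glorot(d_in, hidden), b1 = matrix(0, 1, hidden),
       W2 = glorot(hidden, d_out) * out_scale, b2 = matrix(0, 1, d_out))
}

.mlp2_t <- function(x, prm) {
  ag_add(ag_matmul(ag_relu(ag_add(ag_matmul(x, prm$W1), prm$b1)), prm$W2), prm$b2)
}

#' Initialise EGNN parameters
#'
#' Glorot-uniform initial values for the input projection (62->256) and the
#' per-layer networks: `phi_e` (edge message network over
#' `[h_i, h_j, ||x_i - x_j||^2, e_ij]`), `phi_x` (scalar coordinate weight)
#' and `phi_h` (node update), all two-layer perceptrons with ReLU hidden
#' activations.
#'
#' @param d_in Node input width (62).
#' @param d_h Node embedding width (256); also the message width.
#' @param d_edge Raw edge feature width (2).
#' @param hidden Hidden width of the perceptrons (default 128).
#' @param layers Number of EGCL layers (default 7).
#' @return Nested list of parameter matrices.
#' @export
init_egnn_params <- function(d_in = 62, d_h = 256, d_edge = 2, hidden = 128, layers = 7) {
  list(
    node_in = affine_params(d_in, d_h),
    layers = lapply(seq_len(layers), function(l) {
      list(phi_e = mlp2_params(2 * d_h + 1 + d_edge, hidden, d_h, out_scale = 0.1),
           phi_x = mlp2_params(d_h, hidden, 1, out_scale = 1e-3),
           phi_h = mlp2_params(d_h, hidden, d_h, out_scale = 0.1))
    })
  )
}

# --- tensor-level internals -------------------------------------------------

.egcl_step_t <- function(h, x, edges, efeat, prm, coord_sum = FALSE) {
  n <- nrow(h$value)
  keep <- edges[, 1] != edges[, 2]
  ed <- edges[keep, , drop = FALSE]
  i <- ed[, 1]; j <- ed[, 2]
  tp <- tape_of(h)
  ef <- ag_const(as.matrix(if (inherits(efeat, "ag_tensor")) efeat$value else efeat)[keep, , drop = FALSE], tp)
  xi <- ag_rows(x, i); xj <- ag_rows(x, j)
  diff <- ag_sub(xi, xj)
  dist2 <- ag_matmul(ag_pow(diff, 2), ag_const(matrix(1, 3, 1), tp))
  # phi_e first layer evaluated block-wise over [h_i, h_j, d2, e_ij]: node
  # blocks are mapped once per node and gathered per edge
  d_h <- ncol(h$value)
  W1_i <- ag_rows(prm$phi_e$W1, seq_len(d_h))
  W1_j <- ag_rows(prm$phi_e$W1, d_h + seq_len(d_h))
  W1_d <- ag_rows(prm$phi_e$W1, 2L * d_h + 1L)
  W1_e <- ag_rows(prm$phi_e$W1, 2L * d_h + 1L + seq_len(ncol(ef$value)))
  pre <- ag_add(ag_add(ag_rows(ag_matmul(h, W1_i), i),
                       ag_rows(ag_matmul(h, W1_j), j)),
                ag_add(ag_matmul(dist2, W1_d), ag_matmul(ef, W1_e)))
  hidden <- ag_relu(ag_add(pre, prm$phi_e$b1))
  m <- ag_add(ag_matmul(hidden, prm$phi_e$W2), prm$phi_e$b2)
  if (n > 1L) {
    w <- .mlp2_t(m, prm$phi_x)
    xcomb <- if (coord_sum) ag_add(xi, xj) else diff
    xupd <- ag_segment_sum(ag_mul(xcomb, w), i, n)
    x2 <- ag_add(x, ag_scale(xupd, 1 / (n - 1)))
  } else {
    message("single-node graph: EGCL coordinate update is the identity")
    x2 <- x
  }
  mi <- ag_segment_sum(m, i, n)
  h2 <- ag_relu(ag_add(h, .mlp2_t(ag_add(h, mi), prm$phi_h)))
  if (any(!is.finite(h2$value))) stop("NaN in EGCL node update")
  list(h = h2, x = x2)
}

.egnn_stack_t <- function(h0, x0, edges, efeat, prms, Y, coord_sum = FALSE) {
  h <- h0; x <- x0
  for (l in seq_len(Y)) {
    st <- .egcl_step_t(h, x, edges, efeat, prms[[l]], coord_sum = coord_sum)
    h <- st$h; x <- st$x
  }
  list(h = h, x = x)
}

# --- exported matrix-level surface -----------------------------------------

#' Project node features into the EGNN embedding space
#'
#' Affine map from the 62-wide node features to the 256-wide EGNN node
#' embedding.
#'
#' @param X `N_v` x 62 node feature matrix.
#' @param params EGNN parameter list (see [init_egnn_params()]).
#' @return `N_v` x 256 matrix.
#' @export
egnn_input_projection <- function(X, params) {
  as.matrix(X) %*% params$node_in$W + matrix(params$node_in$b, nrow(X),
                                             ncol(params$node_in$b), byrow = TRUE)
}

#' One equivariant graph convolutional layer
#'
#' @param h `N_v` x 256 node features.
#' @param x `N_v` x 3 coordinates (Angstroms).
#' @param edges Integer edge list; self-loops are ignored (sums run over
#'   `j != i`).
#' @param efeat `N_e` x 2 raw edge features aligned with `edges`.
#' @param layer_params One element of `init_egnn_params()$layers`.
#' @param coord_sum Use the sum form `(x_i + x_j)` of the coordinate update
#'   instead of the equivariant difference form (default `FALSE`).
#' @return List with updated `h` and `x`.
#' @export
egcl_step <- function(h, x, edges, efeat, layer_params, coord_sum = FALSE) {
  tp <- ag_tape()
  st <- .egcl_step_t(ag_const(as.matrix(h), tp), ag_const(as.matrix(x), tp),
                     edges, as.matrix(efeat), .wrap_params_t(layer_params, tp),
                     coord_sum = coord_sum)
  list(h = st$h$value, x = st$x$value)
}

#' Run the EGNN stack
#'
#' Applies `Y` EGCL layers and returns the final-layer node features (the
#' global node feature); intermediate coordinates are used internally and
#' discarded.
#'
#' @param h0 `N_v` x 256 initial node embeddings.
#' @param x0 `N_v` x 3 coordinates.
#' @param edges,efeat Edge list and raw edge features.
#' @param params EGNN parameter list.
#' @param Y Number of layers (default: all initialised layers).
#' @param coord_sum See [egcl_step()].
#' @return `N_v` x 256 matrix `h_global`.
#' @export
egnn_stack <- function(h0, x0, edges, efeat, params, Y = length(params$layers),
                       coord_sum = FALSE) {
  stopifnot(Y >= 1, Y <= length(params$layers))
  tp <- ag_tape()
  st <- .egnn_stack_t(ag_const(as.matrix(h0), tp), ag_const(as.matrix(x0), tp),
                      edges, as.matrix(efeat), .wrap_params_t(params$layers, tp),
                      Y, coord_sum = coord_sum)
  st$h$value
}

#' Concatenate global and multiscale local node features
#'
#' @param h_global `N_v` x 256 EGNN output.
#' @param h_local `N_v` x (L*128) multiscale EGAT output.
#' @return `N_v` x 896 embedding matrix `[h_global || h_local]`.
#' @export
concat_views <- function(h_global, h_local) {
  if (nrow(h_global) != nrow(h_local)) {
    stop("row mismatch: ", nrow(h_global), " vs ", nrow(h_local))
  }
  cbind(h_global, h_local)
}
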