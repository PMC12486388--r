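# Focal loss for imbalanced binary node classification, and its
# cross-entropy special case.  Labels use the y in {+1, -1} convention
# (+1 = interface residue); file-level 0/1 labels are mapped internally.

.p_eps <- 1e-7

#' Binary cross-entropy for probability/label pairs
#'
#' `-log(p)` when `y = 1`, `-log(1 - p)` when `y = -1`.  Probabilities are
#' epsilon-clipped to `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' @param p Probabilities in `[0, 1]` (vectorised).
#' @param y Labels in `{+1, -1}` (0 is also accepted as the negative class).
#' @return Per-element loss vector, >= 0.
#' @export
cross_entropy <- function(p, y) {
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  y <- ifelse(y > 0, 1, -1)
  pc <- pmin(1 - .p_eps, pmax(.p_eps, p))
  ifelse(y == 1, -log(pc), -log(1 - pc))
}

#' Focal loss
#'
#' `FL(p_t) = -alpha * (1 - p_t)^gamma * log(p_t)` with `p_t = p` for
#' positive labels and `1 - p` for negatives.  With `alpha = 1`,
#' `gamma = 0` this reduces exactly to the cross-entropy.  Batch losses are
#' means over residues of this per-element value.
#'
#' @param p Probabilities in `[0, 1]`.
#' @param y Labels in `{+1, -1}` (or 0/1).
#' @param alpha Class weighting factor, > 0 (default 0.25).
#' @param gamma Focusing exponent, >= 0 (default 2).
#' @return Per-element loss vector, >= 0.
#' @export
focal_loss <- function(p, y, alpha = 0.25, gamma = 2) {
  stopifnot(alpha > 0, gamma >= 0)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  y <- ifelse(y > 0, 1, -1)
  pc <- pmin(1 - .p_eps, pmax(.p_eps, p))
  pt <- ifelse(y == 1, pc, 1 - pc)
  -alpha * (1 - pt)^gamma * log(pt)
}

# Tensor-level mean focal loss for training.  p is an N x 1 probability
# tensor; y01 a 0/1 numeric vector.  The clip is affine (p*(1-2eps)+eps) so
# gradients flow everywhere.
.focal_loss_t <- function(p, y01, alpha, gamma) {
  tp <- tape_of(p)
  one <- ag_const(matrix(1, 1, 1), tp)
  yv <- ag_const(matrix(as.numeric(y01), ncol = 1), tp)
  pc <- ag_add(ag_scale(p, 1 - 2 * .p_eps), ag_const(matrix(.p_eps, 1, 1), tp))
  pt <- ag_add(ag_mul(pc, yv), ag_mul(ag_sub(one, pc), ag_sub(one, yv)))
  per <- ag_mul(ag_pow(ag_sub(one, pt), gamma), ag_log(pt))
  ag_scale(ag_mean(per), -alpha)
}
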