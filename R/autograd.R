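# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every tensor lives on a "tape" (an environment recording creation order);
# ag_backward() walks the tape in reverse, accumulating gradients into the
# leaves.  Only the operations needed by the model are implemented: dense
# affine maps, pointwise nonlinearities, row softmax, row gather/scatter
# (for edge-indexed message passing), segment sums, and column concatenation.
# Broadcasting is supported for 1x1 scalars, 1xC row vectors (biases) and
# Nx1 column vectors (per-row scalars).

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ag_record <- function(tape, node) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

ag_new <- function(value, tape, parents = list(), backward = NULL, requires = NULL) {
  stopifnot(is.matrix(value))
  if (is.null(requires)) requires <- any(vapply(parents, function(p) p$requires, logical(1)))
  node <- new.env(parent = emptyenv())
  node$tape <- tape
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  node$requires <- requires
  class(node) <- "ag_tensor"
  ag_record(tape, node)
}

ag_leaf <- function(value, tape, requires_grad = TRUE) {
  ag_new(as.matrix(value), tape, requires = requires_grad)
}

ag_const <- function(value, tape) ag_leaf(value, tape, requires_grad = FALSE)

ag_value <- function(x) x$value

# Reduce a gradient to the shape of a (possibly broadcast) operand.
ag_unbroadcast <- function(g, dims) {
  if (nrow(g) == dims[1] && ncol(g) == dims[2]) return(g)
  if (dims[1] == 1L && dims[2] == 1L) return(matrix(sum(g), 1L, 1L))
  if (dims[1] == 1L) return(matrix(colSums(g), 1L, dims[2]))
  if (dims[2] == 1L) return(matrix(rowSums(g), dims[1], 1L))
  stop("incompatible gradient shape")
}

ag_broadcast <- function(v, dims) {
  if (nrow(v) == dims[1] && ncol(v) == dims[2]) return(v)
  if (nrow(v) == 1L && ncol(v) == 1L) return(matrix(v[1L], dims[1], dims[2]))
  if (nrow(v) == 1L) return(matrix(v, dims[1], dims[2], byrow = TRUE))
  if (ncol(v) == 1L) return(matrix(v, dims[1], dims[2]))
  stop("incompatible broadcast")
}

ag_binary_dims <- function(a, b) {
  c(max(nrow(a$value), nrow(b$value)), max(ncol(a$value), ncol(b$value)))
}

ag_add <- function(a, b) {
  d <- ag_binary_dims(a, b)
  val <- ag_broadcast(a$value, d) + ag_broadcast(b$value, d)
  ag_new(val, tape_of(a, b), list(a, b), function(g) {
    list(ag_unbroadcast(g, dim(a$value)), ag_unbroadcast(g, dim(b$value)))
  })
}

ag_sub <- function(a, b) {
  d <- ag_binary_dims(a, b)
  val <- ag_broadcast(a$value, d) - ag_broadcast(b$value, d)
  ag_new(val, tape_of(a, b), list(a, b), function(g) {
    list(ag_unbroadcast(g, dim(a$value)), ag_unbroadcast(-g, dim(b$value)))
  })
}

ag_mul <- function(a, b) {
  d <- ag_binary_dims(a, b)
  av <- ag_broadcast(a$value, d); bv <- ag_broadcast(b$value, d)
  ag_new(av * bv, tape_of(a, b), list(a, b), function(g) {
    list(ag_unbroadcast(g * bv, dim(a$value)), ag_unbroadcast(g * av, dim(b$value)))
  })
}

ag_div <- function(a, b) {
  d <- ag_binary_dims(a, b)
  av <- ag_broadcast(a$value, d); bv <- ag_broadcast(b$value, d)
  ag_new(av / bv, tape_of(a, b), list(a, b), function(g) {
    list(ag_unbroadcast(g / bv, dim(a$value)), ag_unbroadcast(-g * av / (bv * bv), dim(b$value)))
  })
}

ag_scale <- function(a, s) {
  ag_new(a$value * s, tape_of(a), list(a), function(g) list(g * s))
}

ag_matmul <- function(a, b) {
  ag_new(a$value %*% b$value, tape_of(a, b), list(a, b), function(g) {
    list(tcrossprod(g, b$value), crossprod(a$value, g))
  })
}

ag_t <- function(a) {
  ag_new(t(a$value), tape_of(a), list(a), function(g) list(t(g)))
}

ag_relu <- function(a) {
  mask <- a$value > 0
  ag_new(a$value * mask, tape_of(a), list(a), function(g) list(g * mask))
}

ag_leaky_relu <- function(a, slope = 0.2) {
  fac <- slope + (1 - slope) * (a$value > 0)
  ag_new(a$value * fac, tape_of(a), list(a), function(g) list(g * fac))
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ag_new(s, tape_of(a), list(a), function(g) list(g * s * (1 - s)))
}

ag_exp <- function(a) {
  e <- exp(a$value)
  ag_new(e, tape_of(a), list(a), function(g) list(g * e))
}

ag_log <- function(a) {
  ag_new(log(a$value), tape_of(a), list(a), function(g) list(g / a$value))
}

ag_pow <- function(a, p) {
  ag_new(a$value^p, tape_of(a), list(a), function(g) list(g * p * a$value^(p - 1)))
}

ag_softmax_rows <- function(a) {
  z <- a$value - apply(a$value, 1L, max)
  e <- exp(z)
  y <- e / rowSums(e)
  ag_new(y, tape_of(a), list(a), function(g) {
    list(y * (g - rowSums(g * y)))
  })
}

# Gather rows: out[k, ] = a[idx[k], ].  Backward scatter-adds.
ag_rows <- function(a, idx) {
  idx <- as.integer(idx)
  n <- nrow(a$value)
  ag_new(a$value[idx, , drop = FALSE], tape_of(a), list(a), function(g) {
    acc <- rowsum(g, idx)
    out <- matrix(0, n, ncol(g))
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

# Segment sum: out[s, ] = sum of rows of a with groups == s, s in 1..ngroups.
ag_segment_sum <- function(a, groups, ngroups) {
  groups <- as.integer(groups)
  acc <- rowsum(a$value, groups)
  val <- matrix(0, ngroups, ncol(a$value))
  val[as.integer(rownames(acc)), ] <- acc
  ag_new(val, tape_of(a), list(a), function(g) {
    list(g[groups, , drop = FALSE])
  })
}

ag_cbind <- function(...) {
  xs <- list(...)
  widths <- vapply(xs, function(x) ncol(x$value), integer(1))
  val <- do.call(cbind, lapply(xs, ag_value))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ag_new(val, tape_of(xs[[1]]), xs, function(g) {
    lapply(seq_along(xs), function(m) g[, starts[m]:ends[m], drop = FALSE])
  })
}

ag_rbind <- function(a, b) {
  na <- nrow(a$value)
  ag_new(rbind(a$value, b$value), tape_of(a, b), list(a, b), function(g) {
    list(g[seq_len(na), , drop = FALSE], g[-seq_len(na), , drop = FALSE])
  })
}

ag_sum <- function(a) {
  ag_new(matrix(sum(a$value), 1L, 1L), tape_of(a), list(a), function(g) {
    list(matrix(g[1L], nrow(a$value), ncol(a$value)))
  })
}

ag_mean <- function(a) {
  n <- length(a$value)
  ag_new(matrix(mean(a$value), 1L, 1L), tape_of(a), list(a), function(g) {
    list(matrix(g[1L] / n, nrow(a$value), ncol(a$value)))
  })
}

# Dropout with inverted scaling; the mask is constant w.r.t. gradients.
ag_dropout <- function(a, p, training) {
  if (!training || p <= 0) return(a)
  mask <- (matrix(stats::runif(length(a$value)), nrow(a$value)) >= p) / (1 - p)
  ag_new(a$value * mask, tape_of(a), list(a), function(g) list(g * mask))
}

# Affine map X W + b with W, b tensors (b is 1 x C).
ag_affine <- function(x, W, b) ag_add(ag_matmul(x, W), b)

tape_of <- function(...) {
  for (x in list(...)) if (!is.null(x$tape)) return(x$tape)
  stop("no tape")
}

ag_backward <- function(out, tape) {
  if (is.null(out$grad)) out$grad <- matrix(1, nrow(out$value), ncol(out$value))
  for (k in seq.int(tape$n, 1L)) {
    node <- tape$nodes[[k]]
    if (is.null(node$grad) || is.null(node$backward) || !node$requires) next
    gs <- node$backward(node$grad)
    ps <- node$parents
    for (m in seq_along(ps)) {
      p <- ps[[m]]
      g <- gs[[m]]
      if (is.null(g) || !p$requires) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(out)
}
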