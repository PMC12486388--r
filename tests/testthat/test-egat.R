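# Edge graph attention layers: hand-computed oracle, attention simplex,
# residual identity, permutation equivariance, GCN fallback.

toy_edges <- function(n, cutoff = 14, seed = 1) {
  set.seed(seed)
  x <- center_coordinates(matrix(rnorm(n * 3, sd = 5), n, 3))
  edges <- build_adjacency(x, cutoff)
  list(x = x, edges = edges, efeat = edge_features(x, edges, cutoff))
}

test_that("input projections have the configured widths", {
  set.seed(1)
  prm <- init_egat_params()
  X <- matrix(runif(9 * 62), 9, 62)
  H <- egat_input_projection(X, prm)
  expect_equal(dim(H), c(9L, 128L))
  # zero input, zero bias -> zero output
  expect_true(all(egat_input_projection(matrix(0, 4, 62), prm) == 0))
  E <- egat_edge_projection(matrix(runif(10 * 2), 10, 2), prm)
  expect_equal(dim(E), c(10L, 128L))
})

test_that("a 2-node toy layer matches a step-by-step hand computation", {
  # tiny widths so the three update equations can be evaluated by hand
  d_h <- 2; d_e <- 2
  edges <- rbind(c(1L, 1L), c(1L, 2L), c(2L, 2L))
  h <- rbind(c(1, 0), c(0, 1))
  e <- rbind(c(0.5, 0), c(0.1, 0.2), c(0.3, 0.1))
  prm <- list(A = matrix(0.1 * (1:12), 6, 2), F = matrix(c(1, -1), 2, 1),
              W = matrix(c(0.2, 0, 0, 0.2), 2, 2))
  out <- egat_layer(h, e, edges, prm)

  lrelu <- function(z) ifelse(z > 0, z, 0.2 * z)
  e_new <- t(apply(cbind(h[edges[, 1], ], e, h[edges[, 2], ]), 1,
                   function(row) lrelu(row %*% prm$A)))
  expect_equal(out$e, e_new, tolerance = 1e-12)

  z <- as.numeric(e_new %*% prm$F)
  a1 <- exp(z[1:2]) / sum(exp(z[1:2]))  # node 1: edges (1,1), (1,2)
  expect_equal(as.numeric(out$alpha), c(a1, 1), tolerance = 1e-12)

  h1 <- pmax(h[1, ] + a1[1] * prm$W %*% h[1, ] + a1[2] * prm$W %*% h[2, ], 0)
  h2 <- pmax(h[2, ] + 1 * prm$W %*% h[2, ], 0)
  expect_equal(out$h, rbind(as.numeric(h1), as.numeric(h2)), tolerance = 1e-12)
})

test_that("attention weights sum to one over each node's incoming edges", {
  for (seed in 1:20) {
    set.seed(seed)
    g <- toy_edges(n = sample(5:15, 1), seed = seed)
    prm <- init_egat_params()
    h <- matrix(rnorm(nrow(g$x) * 128), ncol = 128)
    e <- matrix(rnorm(nrow(g$edges) * 128), ncol = 128)
    out <- egat_layer(h, e, g$edges, prm$layers[[1]])
    sums <- tapply(out$alpha[, 1], g$edges[, 1], sum)
    expect_lt(max(abs(sums - 1)), 1e-6)
  }
})

test_that("a node with a single incident edge gets attention exactly 1", {
  edges <- rbind(c(1L, 1L), c(2L, 2L))
  set.seed(2)
  prm <- init_egat_params()$layers[[1]]
  out <- egat_layer(matrix(rnorm(2 * 128), 2), matrix(rnorm(2 * 128), 2),
                    edges, prm)
  expect_equal(as.numeric(out$alpha), c(1, 1))
})

test_that("zero node-transform makes the residual stack the identity", {
  set.seed(3)
  g <- toy_edges(8, seed = 3)
  prm <- init_egat_params()
  for (l in seq_along(prm$layers)) prm$layers[[l]]$W[] <- 0
  h0 <- matrix(abs(rnorm(8 * 128)), 8)  # nonnegative input
  e0 <- matrix(rnorm(nrow(g$edges) * 128), ncol = 128)
  hs <- egat_stack(h0, e0, g$edges, prm)
  expect_length(hs, 5L)
  for (h in hs) expect_equal(h, h0)
})

test_that("the stack returns L per-layer views that concatenate to L*128", {
  set.seed(4)
  g <- toy_edges(6, seed = 4)
  prm <- init_egat_params()
  h0 <- matrix(rnorm(6 * 128), 6)
  e0 <- matrix(rnorm(nrow(g$edges) * 128), ncol = 128)
  hs <- egat_stack(h0, e0, g$edges, prm)
  one <- egat_layer(h0, e0, g$edges, prm$layers[[1]])
  expect_equal(hs[[1]], one$h)
  hl <- multiscale_concat(hs)
  expect_equal(dim(hl), c(6L, 640L))
  for (l in 1:5) {
    expect_identical(hl[, (l - 1) * 128 + 1:128], hs[[l]])
  }
  expect_identical(multiscale_concat(hs[1]), hs[[1]])
  expect_error(multiscale_concat(list(h0, h0[, 1:3])), "ragged")
})

test_that("relabelling nodes permutes the layer outputs identically", {
  set.seed(5)
  g <- toy_edges(9, seed = 5)
  prm <- init_egat_params()
  h0 <- matrix(rnorm(9 * 128), 9)
  e0 <- matrix(rnorm(nrow(g$edges) * 128), ncol = 128)
  out <- egat_layer(h0, e0, g$edges, prm$layers[[1]])

  perm <- sample(9)
  inv <- order(perm)
  edges_p <- cbind(inv[g$edges[, 1]], inv[g$edges[, 2]])
  out_p <- egat_layer(h0[perm, ], e0, edges_p, prm$layers[[1]])
  expect_equal(out_p$h, out$h[perm, ], tolerance = 1e-10)
})

test_that("all EGAT parameters receive gradients that match finite differences", {
  set.seed(6)
  g <- toy_edges(10, seed = 6)
  n <- 10
  prm <- init_egat_params(layers = 1)
  h0 <- matrix(rnorm(n * 128, sd = 0.5), n)
  e0 <- matrix(rnorm(nrow(g$edges) * 128, sd = 0.5), ncol = 128)

  loss_of <- function(layer_prm) {
    tp <- ppisite:::ag_tape()
    st <- ppisite:::.egat_layer_t(
      ppisite:::ag_const(h0, tp), ppisite:::ag_const(e0, tp), g$edges,
      ppisite:::.wrap_params_t(layer_prm, tp, requires = TRUE))
    list(loss = ppisite:::ag_sum(ppisite:::ag_pow(st$h, 2)), tape = tp)
  }
  run <- loss_of(prm$layers[[1]])
  ppisite:::ag_backward(run$loss, run$tape)

  tensors <- Filter(function(nd) isTRUE(nd$requires) && is.null(nd$backward),
                    run$tape$nodes[seq_len(run$tape$n)])
  expect_length(tensors, 3L)
  for (tn in tensors) expect_gt(max(abs(tn$grad)), 0)

  # finite-difference spot check on a few entries of each parameter
  for (nm in c("A", "F", "W")) {
    p0 <- prm$layers[[1]][[nm]]
    idx <- sample(length(p0), 3)
    tnsr <- tensors[[match(nm, c("A", "F", "W"))]]
    for (i in idx) {
      h <- 1e-5
      pp <- prm$layers[[1]]; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- prm$layers[[1]]; pm[[nm]][i] <- pm[[nm]][i] - h
      fd <- (loss_of(pp)$loss$value[1] - loss_of(pm)$loss$value[1]) / (2 * h)
      expect_equal(tnsr$grad[i], fd, tolerance = 1e-4)
    }
  }
})

test_that("GCN fallback matches the dense normalised-adjacency product", {
  # 4-node path graph with self-loops, W = I
  edges <- rbind(cbind(1:4, 1:4), c(1, 2), c(2, 1), c(2, 3), c(3, 2),
                 c(3, 4), c(4, 3))
  edges <- edges[order(edges[, 1], edges[, 2]), ]
  storage.mode(edges) <- "integer"
  set.seed(7)
  h <- matrix(rnorm(4 * 3), 4, 3)
  W <- diag(3)
  out <- gcn_layer(h, edges, W)
  A <- matrix(0, 4, 4)
  A[cbind(edges[, 1], edges[, 2])] <- 1
  D <- diag(1 / sqrt(rowSums(A)))
  expect_equal(out, pmax(D %*% A %*% D %*% h %*% W, 0), tolerance = 1e-12)

  # isolated node with self-loop, W = I: ReLU(h)
  e1 <- matrix(c(1L, 1L), 1, 2)
  h1 <- matrix(c(-1, 2), 1, 2)
  expect_equal(gcn_layer(h1, e1, diag(2)), pmax(h1, 0))

  # constant features on a regular graph stay constant
  ring <- rbind(cbind(1:4, 1:4), cbind(1:4, c(2, 3, 4, 1)), cbind(1:4, c(4, 1, 2, 3)))
  ring <- ring[order(ring[, 1], ring[, 2]), ]; storage.mode(ring) <- "integer"
  hc <- matrix(1, 4, 2)
  expect_equal(gcn_layer(hc, ring, diag(2)), hc)
})
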