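# Fold construction, model forward/prediction contracts, and the training
# loop at toy scale (determinism, overfit sanity).

tiny_config <- function(...) {
  model_config(egat_layers = 2, egnn_layers = 2, d_egat = 8, d_egnn = 8,
               head_hidden = 8, kernels = c(1, 3), dropout = 0, ...)
}

tiny_graphs <- function(n_prot = 4, n_res = 10, seed = 1, signal = 2) {
  lapply(seq_len(n_prot), function(i) {
    g <- random_graph(n = n_res, seed = seed + i)
    # inject a strong linear signal so a toy model can overfit quickly
    g$node_features[, 1:8] <- g$node_features[, 1:8] + signal * g$labels
    g
  })
}

test_that("fold splits partition proteins with the 80/20 inner split", {
  ids <- sprintf("p%02d", 1:20)
  folds <- make_folds(ids, k = 5, seed = 3)
  expect_length(folds, 5L)
  all_test <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(all_test, ids)
  expect_equal(length(all_test), 20L)
  for (f in folds) {
    expect_equal(length(f$test), 4L)
    expect_equal(length(f$train), 13L)       # round(0.8 * 16)
    expect_equal(length(f$validation), 3L)
    expect_setequal(c(f$test, f$train, f$validation), ids)
    expect_equal(anyDuplicated(c(f$test, f$train, f$validation)), 0L)
  }
  expect_identical(make_folds(ids, k = 5, seed = 3), folds)
  expect_false(identical(make_folds(ids, k = 5, seed = 4), folds))
  expect_error(make_folds(ids[1:3], k = 5), "at least 5")
  expect_error(make_folds(c("a", "a", "b", "c", "d")), "duplicated")
})

test_that("forward produces probabilities and the fusion ablations differ only downstream", {
  cfg <- tiny_config(seed = 5)
  g <- random_graph(n = 9, seed = 5)
  prm <- init_model_params(cfg)
  p <- forward(g, prm, cfg)
  expect_length(p, 9L)
  expect_true(all(p > 0 & p < 1))
  expect_equal(dim(attr(p, "attention")), c(9L, 9L))
  expect_lt(max(abs(rowSums(attr(p, "attention")) - 1)), 1e-6)

  cfg_c <- tiny_config(seed = 5, fusion = "concat")
  prm_c <- init_model_params(cfg_c)
  p_c <- forward(g, prm_c, cfg_c)
  expect_null(attr(p_c, "attention"))
  # upstream tensors identical across fusion modes (same seed)
  tp1 <- ppisite:::ag_tape()
  emb1 <- ppisite:::.forward_t(g, ppisite:::.wrap_model_params(prm, tp1),
                               cfg, tp1)$X_emb$value
  tp2 <- ppisite:::ag_tape()
  emb2 <- ppisite:::.forward_t(g, ppisite:::.wrap_model_params(prm_c, tp2),
                               cfg_c, tp2)$X_emb$value
  expect_identical(emb1, emb2)

  cfg_sa <- tiny_config(seed = 5, fusion = "self_attention")
  p_sa <- forward(g, init_model_params(cfg_sa), cfg_sa)
  expect_equal(dim(attr(p_sa, "attention")), c(9L, 9L))

  # GCN-substitution ablations run end to end
  for (abl in list(tiny_config(seed = 5, use_egat = FALSE),
                   tiny_config(seed = 5, use_egnn = FALSE))) {
    pa <- forward(g, init_model_params(abl), abl)
    expect_true(all(pa > 0 & pa < 1))
  }
})

test_that("rigid motions of the input leave predictions unchanged", {
  cfg <- tiny_config(seed = 6)
  prm <- init_model_params(cfg)
  g <- random_graph(n = 10, seed = 6)
  p0 <- as.numeric(forward(g, prm, cfg))
  R <- random_rotation()
  g2 <- g
  g2$coords <- g$coords %*% t(R)  # same centred geometry, rotated
  p1 <- as.numeric(forward(g2, prm, cfg))
  expect_lt(max(abs(p1 - p0)) / max(p0), 1e-4)
})

test_that("predict returns calls consistent with the threshold at 0, 0.5 and 1", {
  cfg <- tiny_config(seed = 7, epochs = 1, patience = 1)
  gs <- tiny_graphs(3, seed = 7)
  m <- suppressWarnings(train_model(gs[1:2], gs[3], cfg, quiet = TRUE))
  pred <- predict(m, gs[[3]])
  expect_named(pred, c("protein_id", "residue_number", "probability", "call", "label"))
  expect_true(all(pred$call == as.integer(pred$probability >= 0.5)))
  expect_true(all(predict(m, gs[[3]], threshold = 0)$call == 1L))
  expect_true(all(predict(m, gs[[3]], threshold = 1)$call == 0L))
  path <- tempfile(fileext = ".tsv")
  write_predictions(pred, path)
  expect_equal(nrow(utils::read.delim(path)), nrow(pred))
})

test_that("training is deterministic under a fixed seed and can overfit", {
  gs <- tiny_graphs(5, seed = 11)
  cfg <- tiny_config(seed = 11, epochs = 6, patience = 6, lr = 3e-3)
  m1 <- suppressWarnings(train_model(gs[1:4], gs[5], cfg, quiet = TRUE))
  m2 <- suppressWarnings(train_model(gs[1:4], gs[5], cfg, quiet = TRUE))
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params$head$fc2$W, m2$params$head$fc2$W)

  # overfit sanity: later loss at or below the first epoch's
  h <- m1$history$train_loss
  expect_lt(h[2], h[1])
  expect_lt(min(h), h[1])
})

test_that("model selection tracks the best validation AUPRC epoch", {
  gs <- tiny_graphs(5, seed = 13)
  cfg <- tiny_config(seed = 13, epochs = 5, patience = 5, lr = 3e-3)
  m <- suppressWarnings(train_model(gs[1:4], gs[5], cfg, quiet = TRUE))
  expect_equal(m$best_epoch, which.max(m$history$val_auprc))
  gl <- glance(m)
  expect_equal(gl$best_epoch, m$best_epoch)
  expect_identical(tidy(m), m$history)
})

test_that("single-class validation labels fall back to loss selection", {
  gs <- tiny_graphs(3, seed = 17)
  gs[[3]]$labels <- rep(0L, length(gs[[3]]$labels))
  cfg <- tiny_config(seed = 17, epochs = 2, patience = 2)
  expect_warning(m <- train_model(gs[1:2], gs[3], cfg, quiet = TRUE),
                 "single-class")
  expect_true(all(is.na(m$history$val_auprc)))
  expect_gt(m$best_epoch, 0L)
})

test_that("checkpoints round-trip through the archive with manifest", {
  gs <- tiny_graphs(3, seed = 19)
  cfg <- tiny_config(seed = 19, epochs = 1, patience = 1)
  m <- suppressWarnings(train_model(gs[1:2], gs[3], cfg, quiet = TRUE))
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)
  expect_equal(m2$config$egat_layers, cfg$egat_layers)
  g <- gs[[1]]
  expect_equal(predict(m2, g), predict(m, g))
  manifest <- jsonlite::fromJSON(readRDS(path)$manifest)
  expect_equal(manifest$config$focal_alpha, 0.25)
})

test_that("cross-validated training aggregates per-fold metrics", {
  gs <- tiny_graphs(6, seed = 23)
  cfg <- tiny_config(seed = 23, epochs = 1, patience = 1)
  cv <- suppressWarnings(cv_train(gs, cfg, k = 3, quiet = TRUE))
  expect_equal(nrow(cv$metrics), 3L)
  expect_named(cv$metrics, c("fold", "acc", "precision", "recall", "f1",
                             "mcc", "auroc", "auprc"))
  expect_length(cv$models, 3L)
})

test_that("training rejects unlabelled or empty datasets", {
  g <- random_graph(n = 8, seed = 29)
  g$labels <- NULL
  expect_error(train_model(list(), list(), tiny_config()), "empty")
  expect_error(suppressWarnings(train_model(list(g), list(), tiny_config())),
               "labelled")
})
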