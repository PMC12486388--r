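# Protein-level cross-validation folds, the Adam training loop, and k-fold
# cross-validated training.

#' Protein-level cross-validation folds
#'
#' Randomly partitions proteins into `k` near-equal test subsets; for each
#' fold, the remaining proteins are split 80/20 into training and
#' validation sets (train count = `round(0.8 * m)`).  Deterministic for a
#' given seed.  The split is at the protein level: no chain ever appears in
#' two roles within one fold.
#'
#' @param protein_ids Character vector of protein identifiers.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Object of class `ppis_folds`: list of `k` lists with `fold_id`,
#'   `test`, `train`, `validation`.
#' @export
make_folds <- function(protein_ids, k = 5, seed = 42L) {
  n <- length(protein_ids)
  if (n < k) stop("need at least ", k, " proteins, got ", n)
  if (anyDuplicated(protein_ids)) stop("duplicated protein ids")
  set.seed(seed)
  shuffled <- sample(protein_ids)
  assignment <- rep(seq_len(k), length.out = n)
  folds <- lapply(seq_len(k), function(f) {
    test <- shuffled[assignment == f]
    rest <- shuffled[assignment != f]
    m <- length(rest)
    n_train <- round(0.8 * m)
    perm <- sample(m)  # continues the seeded stream; deterministic
    list(fold_id = f,
         test = test,
         train = rest[perm[seq_len(n_train)]],
         validation = rest[perm[-seq_len(n_train)]])
  })
  structure(folds, class = "ppis_folds")
}

#' @export
print.ppis_folds <- function(x, ...) {
  for (f in x) {
    cat("fold", f$fold_id, ": test", length(f$test), ", train", length(f$train),
        ", validation", length(f$validation), "\n")
  }
  invisible(x)
}

# --- Adam optimiser over nested parameter lists -----------------------------

.tree_map <- function(f, ...) {
  trees <- list(...)
  a <- trees[[1]]
  if (is.list(a)) {
    out <- lapply(seq_along(a), function(i) {
      do.call(.tree_map, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(a)
    attributes(out) <- attributes(a)
    out
  } else if (is.matrix(a)) {
    do.call(f, trees)
  } else a  # metadata (kernel widths, d_k) passes through
}

.zeros_like <- function(params) .tree_map(function(p) p * 0, params)

# Collect gradients off a wrapped (requires_grad) parameter tree.
.grads_of <- function(prm_t) {
  walk <- function(x) {
    if (inherits(x, "ag_tensor")) {
      if (is.null(x$grad)) x$value * 0 else x$grad
    } else if (is.list(x)) {
      out <- lapply(x, walk)
      attributes(out) <- attributes(x)
      out
    } else x
  }
  walk(prm_t)
}

.adam_step <- function(state, grads, lr, wd, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  walk <- function(p, m, v, g) {
    if (is.matrix(p)) {
      adam_update_inplace(p, m, v, g, lr, wd, beta1, beta2, eps, state$t)
    } else if (is.list(p)) {
      for (k in seq_along(p)) walk(p[[k]], m[[k]], v[[k]], g[[k]])
    }
    invisible(NULL)
  }
  walk(state$params, state$m, state$v, grads)
  state
}

# Gradients live on the (discarded-after-step) tape, parameters and moments
# in the optimiser state; all three are updated in place by compiled
# kernels, so one step allocates no full-size temporaries.
.walk_matrices <- function(tree, fn) {
  if (is.matrix(tree)) fn(tree) else if (is.list(tree)) lapply(tree, .walk_matrices, fn)
  invisible(NULL)
}

.clip_grads_tree <- function(grads, max_norm) {
  total <- 0
  .walk_matrices(grads, function(g) total <<- total + sumsq(g))
  gn <- sqrt(total)
  if (is.finite(gn) && gn > max_norm) {
    f <- max_norm / gn
    .walk_matrices(grads, function(g) scale_inplace(g, f))
  }
  grads
}

# --- training ---------------------------------------------------------------

.dataset_scores <- function(graphs, params, config) {
  scores <- lapply(graphs, function(g) forward(g, params, config))
  labels <- lapply(graphs, function(g) g$labels)
  list(scores = unlist(scores), labels = unlist(labels))
}

#' Train the interface-site model
#'
#' Full-model training with focal loss and Adam, one protein per gradient
#' step.  After each epoch the validation AUPRC is computed; the parameters
#' with the best validation AUPRC are kept (early stopping after
#' `config$patience` epochs without improvement).  If the validation labels
#' contain a single class (AUPRC undefined), selection falls back to the
#' validation loss with a warning.  All randomness (initialisation, epoch
#' shuffling, dropout) is driven by `config$seed`.
#'
#' @param train_graphs List of labelled `protein_graph` objects.
#' @param val_graphs List of labelled `protein_graph` objects.
#' @param config A `ppis_config`.
#' @param init Optional initial parameters (default [init_model_params()]).
#' @param quiet Suppress per-epoch progress messages.
#' @return Object of class `ppis_model`: `params`, `config`, `history`
#'   (tibble: epoch, train_loss, val_loss, val_auroc, val_auprc),
#'   `best_epoch`.
#' @export
train_model <- function(train_graphs, val_graphs, config = model_config(),
                        init = NULL, quiet = FALSE) {
  if (length(train_graphs) == 0L) stop("empty training dataset")
  for (g in c(train_graphs, val_graphs)) {
    if (is.null(g$labels)) stop("training requires labelled graphs (", g$id, ")")
  }
  # deep-copy so in-place optimiser updates never alias caller-owned matrices
  params <- .tree_map(function(m) m + 0,
                      if (is.null(init)) init_model_params(config) else init)
  set.seed(config$seed + 1L)
  state <- list(params = params, m = .zeros_like(params),
                v = .zeros_like(params), t = 0L)

  val_labels <- unlist(lapply(val_graphs, `[[`, "labels"))
  single_class_val <- length(val_graphs) == 0L || length(unique(val_labels)) < 2L
  if (single_class_val) {
    warning("validation labels are single-class; selecting on validation loss",
            call. = FALSE)
  }

  history <- list()
  best_score <- -Inf
  best_params <- params
  best_epoch <- 0L
  stall <- 0L

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(length(train_graphs))
    losses <- numeric(length(ord))
    for (s in seq_along(ord)) {
      g <- train_graphs[[ord[s]]]
      tp <- ag_tape()
      prm_t <- .wrap_model_params(state$params, tp, requires = TRUE)
      st <- .forward_t(g, prm_t, config, tp, training = TRUE)
      loss <- .focal_loss_t(st$p, g$labels, config$focal_alpha, config$focal_gamma)
      ag_backward(loss, tp)
      losses[s] <- loss$value[1]
      grads <- .clip_grads_tree(.grads_of(prm_t), config$max_grad_norm)
      state <- .adam_step(state, grads, config$lr, config$weight_decay)
    }
    train_loss <- mean(losses)
    cur_params <- state$params

    val <- if (length(val_graphs) > 0L) {
      .dataset_scores(val_graphs, cur_params, config)
    } else NULL
    val_loss <- if (is.null(val)) NA_real_ else {
      mean(focal_loss(val$scores, ifelse(val$labels > 0, 1, -1),
                      config$focal_alpha, config$focal_gamma))
    }
    val_auroc <- if (is.null(val) || single_class_val) NA_real_ else {
      auroc(val$scores, val$labels)
    }
    val_auprc <- if (is.null(val) || single_class_val) NA_real_ else {
      auprc(val$scores, val$labels)
    }
    score <- if (single_class_val) {
      if (is.na(val_loss)) -train_loss else -val_loss
    } else val_auprc

    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = train_loss, val_loss = val_loss,
      val_auroc = val_auroc, val_auprc = val_auprc)
    if (!quiet) {
      message(sprintf("epoch %3d  train loss %.5f  val AUROC %s  val AUPRC %s",
                      epoch, train_loss,
                      ifelse(is.na(val_auroc), "-", sprintf("%.3f", val_auroc)),
                      ifelse(is.na(val_auprc), "-", sprintf("%.3f", val_auprc))))
    }

    if (score > best_score + 1e-12) {
      best_score <- score
      best_params <- .tree_map(function(m) m + 0, cur_params)  # snapshot copy
      best_epoch <- epoch
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }

  structure(list(params = best_params, config = config,
                 history = dplyr::bind_rows(history), best_epoch = best_epoch),
            class = "ppis_model")
}

#' Evaluate a trained model on a set of graphs
#'
#' @param model A `ppis_model`.
#' @param graphs List of labelled `protein_graph` objects.
#' @param threshold Classification threshold (default: model config's).
#' @return A `ppis_metrics` tibble (see [compute_metrics()]).
#' @export
evaluate_model <- function(model, graphs, threshold = NULL) {
  if (is.null(threshold)) threshold <- model$config$threshold
  sc <- .dataset_scores(graphs, model$params, model$config)
  compute_metrics(sc$labels, sc$scores, threshold)
}

#' k-fold cross-validated training
#'
#' Protein-level k-fold cross-validation: for every fold, trains on the
#' fold's training proteins with early stopping on its validation proteins,
#' then scores the held-out test proteins.
#'
#' @param graphs Named list of labelled `protein_graph` objects (names =
#'   protein ids) or a list whose elements carry `$id`.
#' @param config A `ppis_config`.
#' @param k Number of folds.
#' @param folds Optional precomputed `ppis_folds`.
#' @param quiet Suppress progress messages.
#' @return List with `folds`, per-fold `models`, and `metrics` (tibble with
#'   one row per fold plus the fold id).
#' @export
cv_train <- function(graphs, config = model_config(), k = 5, folds = NULL,
                     quiet = FALSE) {
  ids <- vapply(graphs, `[[`, character(1), "id")
  names(graphs) <- ids
  if (is.null(folds)) folds <- make_folds(ids, k = k, seed = config$seed)
  models <- list()
  rows <- list()
  for (f in folds) {
    if (!quiet) message("fold ", f$fold_id, ": training on ", length(f$train),
                        " proteins")
    model <- train_model(graphs[f$train], graphs[f$validation], config,
                         quiet = quiet)
    m <- evaluate_model(model, graphs[f$test])
    rows[[f$fold_id]] <- dplyr::bind_cols(tibble::tibble(fold = f$fold_id), m)
    models[[f$fold_id]] <- model
  }
  list(folds = folds, models = models, metrics = dplyr::bind_rows(rows))
}

#' One-line summary of a trained model
#'
#' @param x A `ppis_model`.
#' @param ... Unused.
#' @return Tibble with one row: best epoch, epochs run, final train loss,
#'   best validation AUROC/AUPRC.
#' @method glance ppis_model
#' @export
glance.ppis_model <- function(x, ...) {
  h <- x$history
  best <- h[h$epoch == x$best_epoch, ]
  tibble::tibble(
    epochs_run = nrow(h),
    best_epoch = x$best_epoch,
    train_loss = h$train_loss[nrow(h)],
    val_auroc = if (nrow(best)) best$val_auroc else NA_real_,
    val_auprc = if (nrow(best)) best$val_auprc else NA_real_
  )
}

#' Training history of a fitted model
#'
#' @param x A `ppis_model`.
#' @param ... Unused.
#' @return The per-epoch history tibble.
#' @method tidy ppis_model
#' @export
tidy.ppis_model <- function(x, ...) x$history
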