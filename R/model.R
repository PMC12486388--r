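# Full model: input projections -> EGAT multiscale local view + EGNN global
# view -> concatenation -> MUSE fusion -> MLP head -> per-residue interface
# probability.

#' Model configuration
#'
#' Collects the architecture and training hyperparameters.  Defaults follow
#' the published configuration: 5 EGAT layers (width 128), 7 EGNN layers
#' (width 256), focal loss with `alpha = 0.25`, `gamma = 2`, a 14 Angstrom
#' contact cutoff and a 0.5 classification threshold.  Optimiser settings
#' (Adam, learning rate, weight decay, early-stopping patience) are package
#' choices.
#'
#' @param egat_layers,egnn_layers Layer counts (>= 1).
#' @param d_egat,d_egnn Node embedding widths (128 / 256).
#' @param focal_alpha Focal-loss class weight, in (0, 1].
#' @param focal_gamma Focal-loss focusing exponent, >= 0.
#' @param cutoff Contact cutoff in Angstroms.
#' @param threshold Classification probability threshold.
#' @param seed Integer seed controlling initialisation, shuffling, dropout.
#' @param use_egat,use_egnn If `FALSE`, substitute a plain graph-convolution
#'   stack for the corresponding pathway (ablation variants).
#' @param fusion One of `"muse"`, `"self_attention"`, `"concat"`.
#' @param egnn_coord_sum Use the sum-form EGNN coordinate update.
#' @param kernels Dynamic-convolution kernel widths (odd).
#' @param lr,weight_decay,max_grad_norm,epochs,patience Optimiser settings
#'   (gradients are clipped to a global norm of `max_grad_norm`).
#' @param dropout Dropout rate in the MLP head.
#' @param head_hidden Hidden width of the MLP head.
#' @return Object of class `ppis_config` (a named list).
#' @export
model_config <- function(egat_layers = 5, egnn_layers = 7,
                         d_egat = 128, d_egnn = 256,
                         focal_alpha = 0.25, focal_gamma = 2,
                         cutoff = 14, threshold = 0.5, seed = 42L,
                         use_egat = TRUE, use_egnn = TRUE,
                         fusion = c("muse", "self_attention", "concat"),
                         egnn_coord_sum = FALSE, kernels = c(1, 3, 5),
                         lr = 2e-4, weight_decay = 1e-5,
                         max_grad_norm = 1,
                         epochs = 100, patience = 15,
                         dropout = 0.1, head_hidden = 256) {
  fusion <- match.arg(fusion)
  stopifnot(egat_layers >= 1, egnn_layers >= 1,
            focal_alpha > 0, focal_alpha <= 1, focal_gamma >= 0,
            cutoff > 0, threshold >= 0, threshold <= 1)
  structure(list(
    egat_layers = as.integer(egat_layers), egnn_layers = as.integer(egnn_layers),
    d_egat = d_egat, d_egnn = d_egnn,
    focal_alpha = focal_alpha, focal_gamma = focal_gamma,
    cutoff = cutoff, threshold = threshold, seed = as.integer(seed),
    use_egat = use_egat, use_egnn = use_egnn, fusion = fusion,
    egnn_coord_sum = egnn_coord_sum, kernels = kernels,
    lr = lr, weight_decay = weight_decay, max_grad_norm = max_grad_norm,
    epochs = as.integer(epochs), patience = as.integer(patience),
    dropout = dropout, head_hidden = head_hidden
  ), class = "ppis_config")
}

embedding_width <- function(config) {
  config$d_egnn + config$egat_layers * config$d_egat
}

#' Initialise all model parameters
#'
#' Draws initial values for every learnable tensor of the configured model
#' (EGAT or its GCN substitute, EGNN or its GCN substitute, MUSE, and the
#' MLP head), seeded by `config$seed`.
#'
#' @param config A `ppis_config`.
#' @return Nested list of parameter matrices.
#' @export
init_model_params <- function(config = model_config()) {
  set.seed(config$seed)
  d_emb <- embedding_width(config)
  local <- if (config$use_egat) {
    init_egat_params(d_h = config$d_egat, layers = config$egat_layers)
  } else {
    list(node_in = affine_params(62, config$d_egat),
         layers = lapply(seq_len(config$egat_layers),
                         function(l) list(W = glorot(config$d_egat, config$d_egat))))
  }
  global <- if (config$use_egnn) {
    init_egnn_params(d_h = config$d_egnn, layers = config$egnn_layers)
  } else {
    list(node_in = affine_params(62, config$d_egnn),
         layers = lapply(seq_len(config$egnn_layers),
                         function(l) list(W = glorot(config$d_egnn, config$d_egnn))))
  }
  muse <- if (config$fusion == "concat") NULL else {
    init_muse_params(d = d_emb, kernels = config$kernels)
  }
  list(local = local, global = global, muse = muse,
       head = list(fc1 = affine_params(d_emb, config$head_hidden),
                   fc2 = affine_params(config$head_hidden, 1)))
}

# Tensor-level forward pass; returns probability tensor plus intermediates.
.forward_t <- function(graph, prm, config, tape, training = FALSE) {
  X <- ag_const(graph$node_features, tape)
  edges <- graph$edges
  efeat <- graph$edge_features

  # local multiscale view
  h <- .affine_t(X, prm$local$node_in)
  hs <- vector("list", config$egat_layers)
  if (config$use_egat) {
    e <- .affine_t(ag_const(efeat, tape), prm$local$edge_in)
    st <- .egat_stack_t(h, e, edges, prm$local$layers, config$egat_layers)
    hs <- st$hs
    alphas <- st$alphas
  } else {
    alphas <- NULL
    for (l in seq_len(config$egat_layers)) {
      h <- .gcn_layer_t(h, edges, prm$local$layers[[l]]$W)
      hs[[l]] <- h
    }
  }
  h_local <- if (length(hs) == 1L) hs[[1]] else do.call(ag_cbind, hs)

  # global view
  g <- .affine_t(X, prm$global$node_in)
  if (config$use_egnn) {
    g <- .egnn_stack_t(g, ag_const(graph$coords, tape), edges, efeat,
                       prm$global$layers, config$egnn_layers,
                       coord_sum = config$egnn_coord_sum)$h
  } else {
    for (l in seq_len(config$egnn_layers)) {
      g <- .gcn_layer_t(g, edges, prm$global$layers[[l]]$W)
    }
  }

  X_emb <- ag_cbind(g, h_local)

  attention <- NULL
  X_fused <- switch(config$fusion,
    muse = {
      st <- .muse_fuse_t(X_emb, prm$muse, prm$muse$d_k)
      attention <- st$attention
      st$out
    },
    self_attention = {
      st <- .self_attention_t(X_emb, prm$muse, prm$muse$d_k)
      attention <- st$attention
      ag_add(X_emb, st$out)
    },
    concat = X_emb
  )

  z <- ag_relu(.affine_t(X_fused, prm$head$fc1))
  z <- ag_dropout(z, config$dropout, training)
  p <- ag_sigmoid(.affine_t(z, prm$head$fc2))
  if (any(!is.finite(p$value))) stop("NaN in MLP head output")
  list(p = p, attention = attention, X_emb = X_emb, alphas = alphas)
}

# Wrap a parameter tree for a forward pass.  d_k (scalar metadata) and
# kernel widths ride along as constants.
.wrap_model_params <- function(params, tape, requires = FALSE) {
  wrap <- function(x) {
    if (is.list(x)) {
      out <- lapply(x, wrap)
      attributes(out) <- attributes(x)
      out
    } else if (is.numeric(x)) {
      ag_leaf(as.matrix(x), tape, requires_grad = requires)
    } else x
  }
  out <- wrap(params)
  if (!is.null(out$muse)) {
    out$muse$kernels <- params$muse$kernels
    out$muse$d_k <- params$muse$d_k
  }
  out
}

#' Forward pass: per-residue interface probabilities
#'
#' Runs the full pipeline (projections, EGAT multiscale local features,
#' EGNN global features, view concatenation, fusion, MLP head with sigmoid
#' output) on one protein graph.
#'
#' @param graph A `protein_graph` with 62-wide node features.
#' @param params Parameters from [init_model_params()] or a trained model.
#' @param config The matching `ppis_config`.
#' @return Numeric vector of probabilities in (0, 1), one per residue, with
#'   the MUSE attention matrix (if any) as attribute `"attention"`.
#' @export
forward <- function(graph, params, config = model_config()) {
  if (ncol(graph$node_features) != 62) {
    stop("graph node features must be 62 wide, got ", ncol(graph$node_features))
  }
  tp <- ag_tape()
  st <- .forward_t(graph, .wrap_model_params(params, tp), config, tp, training = FALSE)
  p <- as.numeric(st$p$value)
  if (!is.null(st$attention)) attr(p, "attention") <- st$attention$value
  p
}

#' Predict interface residues for one protein graph
#'
#' @param object A trained `ppis_model` (from [train_model()]).
#' @param graph A `protein_graph`.
#' @param threshold Classification threshold (default: the model config's).
#' @param ... Unused.
#' @return Tibble with `protein_id`, `residue_number`, `probability`,
#'   `call` (binary at `probability >= threshold`) and, when the graph is
#'   labelled, `label`.
#' @export
predict.ppis_model <- function(object, graph, threshold = NULL, ...) {
  if (is.null(threshold)) threshold <- object$config$threshold
  p <- forward(graph, object$params, object$config)
  out <- tibble::tibble(
    protein_id = graph$id,
    residue_number = graph$residue_numbers,
    probability = as.numeric(p),
    call = as.integer(p >= threshold)
  )
  if (!is.null(graph$labels)) out$label <- graph$labels
  out
}

#' Write predictions as TSV
#'
#' @param predictions Tibble from [predict.ppis_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a trained model
#'
#' The checkpoint is a single RDS archive holding a JSON manifest string
#' (configuration plus parameter shapes, for reproducibility) and the
#' parameter values.
#'
#' @param model A `ppis_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` invisibly (`save_model`); the restored `ppis_model`
#'   (`load_model`).
#' @export
save_model <- function(model, path) {
  shapes <- list()
  walk <- function(x, prefix) {
    if (is.list(x)) {
      for (nm in names(x)) walk(x[[nm]], paste0(prefix, "/", nm))
    } else if (is.matrix(x)) {
      shapes[[prefix]] <<- dim(x)
    }
  }
  walk(model$params, "")
  manifest <- jsonlite::toJSON(list(config = unclass(model$config),
                                    parameter_shapes = shapes),
                               auto_unbox = TRUE, digits = NA)
  saveRDS(list(manifest = as.character(manifest), params = model$params,
               config = model$config, history = model$history,
               best_epoch = model$best_epoch), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  structure(list(params = obj$params, config = obj$config,
                 history = obj$history, best_epoch = obj$best_epoch),
            class = "ppis_model")
}

#' @export
print.ppis_model <- function(x, ...) {
  cat("<ppis_model> fusion=", x$config$fusion,
      ", EGAT layers=", x$config$egat_layers,
      ", EGNN layers=", x$config$egnn_layers,
      ", best epoch=", x$best_epoch, "\n", sep = "")
  invisible(x)
}
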