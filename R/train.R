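#' Train/test split masks for transductive learning
#'
#' Reproducible random split of the labeled nodes: `floor(ratio * n)` train,
#' the rest test.
#'
#' @param n_labeled number of labeled nodes (>= 5).
#' @param ratio training fraction. Default 0.8.
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test` and the seed.
#' @export
make_split <- function(n_labeled, ratio = 0.8, seed = 1L) {
  stopifnot(n_labeled >= 5L, ratio > 0, ratio < 1)
  with_seed(seed, {
    tr <- sort(sample.int(n_labeled, floor(ratio * n_labeled)))
    list(train = tr, test = setdiff(seq_len(n_labeled), tr), seed = seed)
  })
}

#' Training protocol configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 1e-3 and
#' weight decay 1e-4, 200 full-batch epochs, 50 repeats.
#'
#' @param lr learning rate.
#' @param weight_decay L2 weight decay coefficient.
#' @param epochs number of full-batch epochs.
#' @param repeats number of independent repeats in [run_experiment()].
#' @param base_seed base RNG seed; repeat i uses `base_seed + i - 1`.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-3, weight_decay = 1e-4, epochs = 200L,
                         repeats = 50L, base_seed = 1L) {
  stopifnot(epochs >= 1, lr > 0, repeats >= 1)
  structure(list(lr = lr, weight_decay = weight_decay,
                 epochs = as.integer(epochs), repeats = as.integer(repeats),
                 base_seed = as.integer(base_seed)),
            class = "train_config")
}

#' Train the multi-hop gated attention model
#'
#' Full-batch transductive training: `epochs` Adam steps on the
#' cross-entropy-plus-gate-sparsity objective, computed on the training
#' mask only. Deterministic given the seed.
#'
#' @param g a labeled `dama_graph`.
#' @param ifm a `dama_influence` built on `g`.
#' @param neighborhoods a `dama_neighborhoods`.
#' @param masks a split from [make_split()].
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param features optional node feature matrix (see
#'   [build_model_inputs()]).
#' @param seed RNG seed for initialization and dropout.
#' @return a `dama_fit` with elements `params`, `loss_history` (per-epoch
#'   total loss), `inputs`, `model_cfg`, `masks`, `n_classes`.
#' @export
train_dama <- function(g, ifm, neighborhoods, masks,
                       model_cfg = model_config(), train_cfg = train_config(),
                       features = NULL, seed = 1L) {
  if (is.null(g$labels)) stop("training requires node labels")
  labels <- as.integer(factor(g$labels))
  n_classes <- max(labels)
  inputs <- build_model_inputs(g, ifm, neighborhoods, features, model_cfg)
  params <- init_params(model_cfg, inputs$n_features, n_classes, seed = seed)
  state <- list(t = 0L, m = list(), v = list())
  history <- numeric(train_cfg$epochs)
  with_seed(seed + 1L, {
    for (ep in seq_len(train_cfg$epochs)) {
      fb <- dama_forward_backward(params, inputs, model_cfg, labels,
                                  masks$train, training = TRUE)
      if (!is.finite(fb$loss)) {
        stop(sprintf("training diverged at epoch %d (loss = %g)", ep, fb$loss))
      }
      st <- adam_step(params, fb$grads, state, train_cfg$lr,
                      train_cfg$weight_decay)
      params <- st$params; state <- st$state
      history[ep] <- fb$loss
      dama_log("DEBUG", "epoch %d loss %.6f", ep, fb$loss)
    }
  })
  structure(list(params = params, loss_history = history, inputs = inputs,
                 model_cfg = model_cfg, train_cfg = train_cfg, masks = masks,
                 labels = labels, n_classes = n_classes, seed = seed),
            class = "dama_fit")
}

#' @export
print.dama_fit <- function(x, ...) {
  cat(sprintf("dama_fit: %d nodes, %d classes, %d parameters, final loss %.4f\n",
              x$inputs$n, x$n_classes, n_parameters(x$params),
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Predicted class scores or labels
#'
#' Forward pass without dropout.
#' @param object a `dama_fit`.
#' @param type `"class"` (default) for argmax labels, `"scores"` for the
#'   raw score matrix.
#' @param ... unused.
#' @export
predict.dama_fit <- function(object, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  fwd <- dama_forward(object$params, object$inputs, object$model_cfg,
                      training = FALSE)
  if (type == "scores") return(fwd$scores)
  max.col(fwd$scores, ties.method = "first")
}

#' Evaluate a trained model
#'
#' Accuracy, NMI, macro-F1 and ARI on the evaluation nodes (the test mask
#' by default), plus the modularity of the predicted partition of the whole
#' graph — modularity is a whole-graph property and is always computed on
#' all nodes.
#'
#' @param fit a `dama_fit`.
#' @param g the graph it was trained on.
#' @param masks the split used.
#' @param scope `"test"` (default) or `"all"`: which nodes the label-based
#'   metrics are computed on.
#' @return list with `accuracy`, `nmi`, `f1_macro`, `ari`, `modularity` and
#'   the predicted assignment.
#' @export
evaluate_fit <- function(fit, g, masks, scope = c("test", "all")) {
  scope <- match.arg(scope)
  pred <- predict(fit)
  idx <- if (scope == "test") masks$test else seq_len(g$n_nodes)
  truth <- fit$labels[idx]
  list(accuracy = accuracy_score(truth, pred[idx]),
       nmi = nmi_score(truth, pred[idx]),
       f1_macro = f1_score(truth, pred[idx], "macro"),
       ari = ari_score(truth, pred[idx]),
       modularity = modularity_q(g, pred),
       assignment = pred)
}

#' Repeat-and-aggregate experiment runner
#'
#' Runs split + train + evaluate `repeats` times with per-repeat seeds
#' `base_seed + i - 1` and aggregates each metric's mean and standard
#' deviation.
#'
#' @param g a labeled `dama_graph`.
#' @param ifm a `dama_influence` built on `g`.
#' @param neighborhoods a `dama_neighborhoods`.
#' @param model_cfg,train_cfg configurations.
#' @param features optional feature matrix.
#' @param repeats number of repeats (defaults to `train_cfg$repeats`).
#' @return a `dama_report`: list with `per_run` (data.frame, one row per
#'   repeat) and `summary` (mean/sd per metric).
#' @export
run_experiment <- function(g, ifm, neighborhoods,
                           model_cfg = model_config(),
                           train_cfg = train_config(),
                           features = NULL, repeats = NULL) {
  repeats <- repeats %||% train_cfg$repeats
  metrics <- c("accuracy", "nmi", "f1_macro", "ari", "modularity")
  rows <- vector("list", repeats)
  for (i in seq_len(repeats)) {
    seed_i <- train_cfg$base_seed + i - 1L
    masks <- make_split(g$n_nodes, seed = seed_i)
    fit <- train_dama(g, ifm, neighborhoods, masks, model_cfg, train_cfg,
                      features = features, seed = seed_i)
    ev <- evaluate_fit(fit, g, masks)
    rows[[i]] <- data.frame(run = i, seed = seed_i,
                            as.data.frame(ev[metrics]))
    dama_log("INFO", "run %d/%d: acc %.3f nmi %.3f mod %.3f",
             i, repeats, ev$accuracy, ev$nmi, ev$modularity)
  }
  per_run <- do.call(rbind, rows)
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_run[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(per_run[[m]]), numeric(1)))
  structure(list(per_run = per_run, summary = summary), class = "dama_report")
}

#' @export
print.dama_report <- function(x, ...) {
  cat("dama_report over", nrow(x$per_run), "run(s):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Serializes the fitted parameters together with the configurations and
#' seed (a run-time artifact; re-loading restores identical predictions).
#'
#' @param fit a `dama_fit`.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "dama_fit"))
  fit
}
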