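#' Model hyperparameters
#'
#' Defaults follow the reference training protocol: 8 attention heads of 16
#' dimensions each (128-dimensional hop embeddings), three hop levels,
#' dropout 0.6, a learnable attention decay initialized at 0.3, a
#' 128-to-128 fusion MLP and a 128-to-64-to-C classifier.
#'
#' @param n_heads number of attention heads per hop.
#' @param head_dim output dimension per head; `n_heads * head_dim` is the
#'   hop embedding dimension.
#' @param max_hops number of hop levels K.
#' @param dropout dropout rate on attention inputs and the fusion input,
#'   applied during training only.
#' @param attention_lambda initial value of the learnable decay coefficient
#'   in the attention kernel `Phi(d) = exp(-lambda d)`.
#' @param kappa coefficient of the L1 sparsity penalty on the final gate
#'   weights.
#' @param classifier_hidden hidden width of the classifier MLP.
#' @param l1_scope `"mean"` (default) averages the gate L1 term over
#'   training nodes; `"sum"` sums it.
#' @param no_msg disable the dual-gating stage: hop embeddings are averaged
#'   with fixed weight 1/K and the gating parameters are dropped (the
#'   multi-scale-gating ablation).
#' @return a `model_config` list.
#' @export
model_config <- function(n_heads = 8L, head_dim = 16L, max_hops = 3L,
                         dropout = 0.6, attention_lambda = 0.3,
                         kappa = 1e-3, classifier_hidden = 64L,
                         l1_scope = c("mean", "sum"), no_msg = FALSE) {
  stopifnot(n_heads >= 1, head_dim >= 1, max_hops >= 1,
            dropout >= 0, dropout < 1, kappa >= 0)
  structure(list(n_heads = as.integer(n_heads), head_dim = as.integer(head_dim),
                 dim = as.integer(n_heads * head_dim),
                 max_hops = as.integer(max_hops), dropout = dropout,
                 attention_lambda = attention_lambda, kappa = kappa,
                 classifier_hidden = as.integer(classifier_hidden),
                 l1_scope = match.arg(l1_scope), no_msg = isTRUE(no_msg)),
            class = "model_config")
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize model parameters
#'
#' Glorot-uniform projection and MLP weights, zero biases, per-hop separate
#' attention parameters, one shared learnable decay coefficient.
#'
#' @param cfg a [model_config()].
#' @param n_features input feature dimension.
#' @param n_classes number of communities C.
#' @param seed RNG seed.
#' @return named list of parameter arrays (class `dama_params`).
#' @export
init_params <- function(cfg, n_features, n_classes, seed = 1L) {
  D <- cfg$dim; K <- cfg$max_hops; nf <- n_features
  with_seed(seed, {
    p <- list()
    for (k in seq_len(K)) {
      p[[paste0("Wq", k)]] <- glorot(nf, D)
      p[[paste0("Wk", k)]] <- glorot(nf, D)
      p[[paste0("Wv", k)]] <- glorot(nf, D)
    }
    p$lambda <- cfg$attention_lambda
    if (!cfg$no_msg) {
      p$Wr <- glorot(K, 2L) * 0.1      # priors (degree, max intensity) are unscaled
      p$Wf <- glorot(K, nf)
    }
    p$W1 <- glorot(D, D); p$b1 <- numeric(D)
    p$W2 <- glorot(D, D); p$b2 <- numeric(D)
    p$Wc1 <- glorot(D, cfg$classifier_hidden); p$bc1 <- numeric(cfg$classifier_hidden)
    p$Wc2 <- glorot(cfg$classifier_hidden, n_classes); p$bc2 <- numeric(n_classes)
    structure(p, class = "dama_params", n_features = F, n_classes = n_classes)
  })
}

#' Number of trainable scalars in a parameter set
#' @param params a `dama_params`.
#' @return integer count.
#' @export
n_parameters <- function(params) {
  sum(vapply(params, length, integer(1)))
}

#' Assemble the fixed per-graph model inputs
#'
#' Precomputes everything the forward pass needs: the feature matrix, the
#' per-hop neighbor pair lists with true BFS distances, the gating priors
#' (degree and maximum incident influence intensity) and the batch feature
#' standard deviations.
#'
#' @param g a `dama_graph`.
#' @param ifm a `dama_influence` built on `g`.
#' @param neighborhoods a `dama_neighborhoods` from [sample_all()] or
#'   [full_neighborhoods()].
#' @param features node feature matrix; defaults to `g$features` or, when
#'   absent, [make_node_features()].
#' @param cfg a [model_config()].
#' @return a `dama_inputs` list.
#' @export
build_model_inputs <- function(g, ifm, neighborhoods, features = NULL,
                               cfg = model_config()) {
  X <- features %||% g$features %||% make_node_features(g, ifm)
  X <- as.matrix(X)
  stopifnot(nrow(X) == g$n_nodes)
  K <- cfg$max_hops
  Dm <- distance_matrix(g)
  hops <- vector("list", K)
  for (k in seq_len(K)) {
    members <- lapply(neighborhoods$nodes, function(nd)
      if (length(nd$hops) >= k) nd$hops[[k]] else integer(0))
    i_idx <- rep.int(seq_len(g$n_nodes), lengths(members))
    j_idx <- unlist(members, use.names = FALSE)
    d <- if (length(i_idx) > 0L) Dm[cbind(i_idx, j_idx)] else numeric(0)
    hops[[k]] <- list(i = as.integer(i_idx), j = as.integer(j_idx), d = d)
  }
  if (any(vapply(neighborhoods$nodes, `[[`, logical(1), "isolated"))) {
    dama_log("WARN", "%d isolated node(s): self-only (zero) embeddings",
             sum(vapply(neighborhoods$nodes, `[[`, logical(1), "isolated")))
  }
  deg <- degrees(g)
  maxm <- apply_row_max(ifm$mat)
  s <- apply(X, 2, function(col) sqrt(mean((col - mean(col))^2)))
  if (all(s < 1e-12)) {
    dama_log("WARN", "batch feature standard deviation is ~0; the feedback gate will zero all hop contributions")
  }
  structure(list(X = X, hops = hops, deg = deg, maxm = maxm,
                 prior = cbind(deg, maxm), s = s,
                 n = g$n_nodes, n_features = ncol(X), K = K),
            class = "dama_inputs")
}

elu <- function(x) {
  neg <- x < 0
  x[neg] <- exp(x[neg]) - 1
  x
}
elu_grad <- function(x) {
  g <- array(1, dim(x) %||% length(x))
  neg <- x < 0
  g[neg] <- exp(x[neg])
  g
}
relu <- function(x) pmax(x, 0)

row_softmax <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

layernorm_rows <- function(A, active = NULL, eps = 1e-5) {
  m <- rowMeans(A)
  v <- rowMeans((A - m)^2)
  sd <- sqrt(v + eps)
  Y <- (A - m) / sd
  if (!is.null(active)) Y[!active, ] <- 0
  list(Y = Y, sd = sd)
}

layernorm_backward <- function(dY, Y, sd, active = NULL) {
  dA <- (dY - rowMeans(dY) - Y * rowMeans(dY * Y)) / sd
  if (!is.null(active)) dA[!active, ] <- 0
  dA
}

# Full forward pass. Returns scores plus (when keep_cache) every
# intermediate needed for the analytic backward pass.
dama_forward <- function(params, inputs, cfg, training = FALSE,
                         keep_cache = FALSE) {
  n <- inputs$n; K <- inputs$K; D <- cfg$dim
  X <- inputs$X
  cache <- list()
  if (training && cfg$dropout > 0) {
    M1 <- matrix((stats::runif(length(X)) >= cfg$dropout) / (1 - cfg$dropout),
                 nrow(X), ncol(X))
    Xd <- X * M1
    cache$M1 <- M1
  } else Xd <- X
  H <- O <- fw <- QL <- KL <- VL <- phiL <- vector("list", K)
  lns <- vector("list", K)
  active <- vector("list", K)
  for (k in seq_len(K)) {
    hp <- inputs$hops[[k]]
    # kernels take node-major (transposed) matrices: one contiguous column
    # per node
    QL[[k]] <- t(Xd %*% params[[paste0("Wq", k)]])
    KL[[k]] <- t(Xd %*% params[[paste0("Wk", k)]])
    VL[[k]] <- t(Xd %*% params[[paste0("Wv", k)]])
    phiL[[k]] <- exp(-params$lambda * hp$d)
    fw[[k]] <- .attn_forward(QL[[k]], KL[[k]], VL[[k]], hp$i, hp$j,
                             phiL[[k]], n, cfg$n_heads)
    O[[k]] <- t(fw[[k]]$O)
    act <- rep.int(FALSE, n); act[unique(hp$i)] <- TRUE
    active[[k]] <- act
    A <- elu(O[[k]])
    ln <- layernorm_rows(A, act)
    lns[[k]] <- ln
    H[[k]] <- ln$Y
  }
  if (cfg$no_msg) {
    G <- matrix(1 / K, n, K)
    g_base <- NULL; dg <- rep(1 / K, K)
  } else {
    Blog <- inputs$prior %*% t(params$Wr)
    g_base <- row_softmax(Blog)
    dg <- as.numeric(tanh(params$Wf %*% inputs$s))
    G <- g_base * matrix(dg, n, K, byrow = TRUE)
  }
  Z <- matrix(0, n, D)
  for (k in seq_len(K)) Z <- Z + G[, k] * H[[k]]
  if (training && cfg$dropout > 0) {
    M2 <- matrix((stats::runif(length(Z)) >= cfg$dropout) / (1 - cfg$dropout), n, D)
    Zd <- Z * M2
    cache$M2 <- M2
  } else Zd <- Z
  U1p <- sweep(Zd %*% params$W1, 2, params$b1, `+`)
  U1 <- relu(U1p)
  U2 <- sweep(U1 %*% params$W2, 2, params$b2, `+`)
  C1p <- sweep(U2 %*% params$Wc1, 2, params$bc1, `+`)
  C1 <- relu(C1p)
  S <- sweep(C1 %*% params$Wc2, 2, params$bc2, `+`)
  out <- list(scores = S, gates = G, g_base = g_base, delta_g = dg, H = H)
  if (keep_cache) {
    out$cache <- c(cache, list(Xd = Xd, Q = QL, K = KL, V = VL, phi = phiL,
                               fw = fw, O = O, lns = lns, active = active,
                               Z = Z, Zd = Zd, U1p = U1p, U1 = U1,
                               U2 = U2, C1p = C1p, C1 = C1))
  }
  out
}

# Cross-entropy + gate-sparsity objective and its gradient at the scores.
ce_loss_grad <- function(S, labels, train_idx) {
  St <- S[train_idx, , drop = FALSE]
  mx <- apply(St, 1, max)
  E <- exp(St - mx)
  P <- E / rowSums(E)
  y <- labels[train_idx]
  nll <- -(log(P[cbind(seq_along(train_idx), y)]))
  dS <- matrix(0, nrow(S), ncol(S))
  Pt <- P
  Pt[cbind(seq_along(train_idx), y)] <- Pt[cbind(seq_along(train_idx), y)] - 1
  dS[train_idx, ] <- Pt / length(train_idx)
  list(ce = mean(nll), dS = dS)
}

# Forward + analytic backward over all parameters.
dama_forward_backward <- function(params, inputs, cfg, labels, train_idx,
                                  training = TRUE) {
  fwd <- dama_forward(params, inputs, cfg, training = training, keep_cache = TRUE)
  ca <- fwd$cache
  n <- inputs$n; K <- inputs$K
  G <- fwd$gates
  lg <- ce_loss_grad(fwd$scores, labels, train_idx)
  l1_norm <- sum(abs(G[train_idx, , drop = FALSE]))
  l1_den <- if (cfg$l1_scope == "mean") length(train_idx) else 1
  loss <- lg$ce + cfg$kappa * l1_norm / l1_den
  grads <- list()
  dS <- lg$dS
  grads$Wc2 <- crossprod(ca$C1, dS); grads$bc2 <- colSums(dS)
  dC1 <- tcrossprod(dS, params$Wc2) * (ca$C1p > 0)
  grads$Wc1 <- crossprod(ca$U2, dC1); grads$bc1 <- colSums(dC1)
  dU2 <- tcrossprod(dC1, params$Wc1)
  grads$W2 <- crossprod(ca$U1, dU2); grads$b2 <- colSums(dU2)
  dU1 <- tcrossprod(dU2, params$W2) * (ca$U1p > 0)
  grads$W1 <- crossprod(ca$Zd, dU1); grads$b1 <- colSums(dU1)
  dZd <- tcrossprod(dU1, params$W1)
  dZ <- if (!is.null(ca$M2)) dZd * ca$M2 else dZd
  dG <- matrix(0, n, K)
  dH <- vector("list", K)
  for (k in seq_len(K)) {
    dH[[k]] <- dZ * G[, k]
    dG[, k] <- rowSums(dZ * fwd$H[[k]])
  }
  # gate sparsity penalty
  dG[train_idx, ] <- dG[train_idx, ] +
    cfg$kappa / l1_den * sign(G[train_idx, , drop = FALSE])
  if (!cfg$no_msg) {
    dg <- fwd$delta_g
    dg_base <- dG * matrix(dg, n, K, byrow = TRUE)
    ddg <- colSums(dG * fwd$g_base)
    gb <- fwd$g_base
    dBlog <- gb * (dg_base - rowSums(dg_base * gb))
    grads$Wr <- crossprod(dBlog, inputs$prior)
    dpre <- ddg * (1 - dg^2)
    grads$Wf <- tcrossprod(dpre, inputs$s)   # K x F, matches params$Wf
  }
  grads$lambda <- 0
  dXd <- matrix(0, n, inputs$n_features)
  for (k in seq_len(K)) {
    hp <- inputs$hops[[k]]
    dY <- dH[[k]]
    dA <- layernorm_backward(dY, ca$lns[[k]]$Y, ca$lns[[k]]$sd, ca$active[[k]])
    dO <- dA * elu_grad(ca$O[[k]])
    bw <- .attn_backward(ca$Q[[k]], ca$K[[k]], ca$V[[k]], hp$i, hp$j,
                         ca$phi[[k]], hp$d, ca$fw[[k]]$alpha, ca$fw[[k]]$qdot,
                         t(dO), cfg$n_heads)
    grads[[paste0("Wq", k)]] <- tcrossprod(t(ca$Xd), bw$dQ)
    grads[[paste0("Wk", k)]] <- tcrossprod(t(ca$Xd), bw$dK)
    grads[[paste0("Wv", k)]] <- tcrossprod(t(ca$Xd), bw$dV)
    grads$lambda <- grads$lambda + bw$dlambda
  }
  list(loss = loss, ce = lg$ce, scores = fwd$scores, gates = G, grads = grads)
}

# One Adam step (in place on the params list); decoupled L2 weight decay is
# applied to every parameter except the decay coefficient lambda.
adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (nm != "lambda" && weight_decay > 0) g <- g + weight_decay * params[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Decay-aware attention weights for one node and hop (reference form)
#'
#' Straight-line evaluation of the per-hop attention row: softmax over the
#' hop members of `Phi(d_ij) * <Wq h_i, Wk h_j>` with `Phi(d) =
#' exp(-lambda d)`. This is the single-head reference used for verification;
#' the training path evaluates the same quantity in compiled code.
#'
#' @param h_i feature vector of the target node.
#' @param H_members matrix of member feature vectors (one row each).
#' @param distances hop distances of the members from the target.
#' @param Wq,Wk projection matrices (features x head dim).
#' @param lambda decay coefficient.
#' @return attention weights summing to 1.
#' @export
decay_attention <- function(h_i, H_members, distances, Wq, Wk, lambda = 0.3) {
  stopifnot(nrow(H_members) >= 1L, length(distances) == nrow(H_members))
  q <- drop(h_i %*% Wq)
  Km <- H_members %*% Wk
  logits <- exp(-lambda * distances) * drop(Km %*% q)
  w <- exp(logits - max(logits))
  w / sum(w)
}

#' Aggregate one hop's members into an embedding (reference form)
#'
#' Weighted sum of value-projected member features, optionally
#' layer-normalized.
#'
#' @param H_members matrix of member feature vectors.
#' @param alpha attention weights (normalized).
#' @param Wv value projection matrix.
#' @param normalize apply layer normalization (default `TRUE`).
#' @return the hop embedding vector.
#' @export
aggregate_hop <- function(H_members, alpha, Wv, normalize = TRUE) {
  z <- drop(crossprod(H_members %*% Wv, alpha))
  if (!normalize) return(z)
  m <- mean(z); v <- mean((z - m)^2)
  (z - m) / sqrt(v + 1e-5)
}

#' Prior (base) gate over hop levels for one node
#'
#' `softmax(Wr %*% c(deg, max_m))`: a K-simplex weight vector derived from
#' the node's degree and its maximum incident influence intensity.
#'
#' @param deg node degree.
#' @param max_m maximum influence intensity among the node's neighbors.
#' @param Wr routing matrix (K x 2).
#' @return length-K weights, positive, summing to 1.
#' @export
base_gate <- function(deg, max_m, Wr) {
  l <- drop(Wr %*% c(deg, max_m))
  w <- exp(l - max(l))
  w / sum(w)
}

#' Batch-feedback gate adjustment
#'
#' `tanh(Wf %*% Std(H_batch))` where `Std` is the per-dimension population
#' standard deviation of the batch feature matrix. One adjustment vector per
#' batch, shared by all nodes.
#'
#' @param H_batch batch feature matrix (nodes x dims).
#' @param Wf feedback projection (K x dims).
#' @return length-K vector in (-1, 1).
#' @export
feedback_gate <- function(H_batch, Wf) {
  s <- apply(H_batch, 2, function(col) sqrt(mean((col - mean(col))^2)))
  as.numeric(tanh(Wf %*% s))
}

#' Fuse gated hop embeddings and classify (reference form)
#'
#' `y_i = MLP(sum_k g_ik * h_i^(k))`: the gated sum feeds the fusion MLP
#' (two D-to-D layers, ReLU between) and then the classifier MLP
#' (D -> hidden -> C, ReLU after the first layer).
#'
#' @param hop_embeddings list of K embedding matrices (nodes x D).
#' @param gates final gate weight matrix (nodes x K).
#' @param weights list with `W1`, `b1`, `W2`, `b2`, `Wc1`, `bc1`, `Wc2`,
#'   `bc2` (as produced by [init_params()]).
#' @return per-class score matrix (nodes x C).
#' @export
fuse_and_classify <- function(hop_embeddings, gates, weights) {
  K <- length(hop_embeddings)
  Z <- Reduce(`+`, lapply(seq_len(K), function(k)
    gates[, k] * hop_embeddings[[k]]))
  U1 <- relu(sweep(Z %*% weights$W1, 2, weights$b1, `+`))
  U2 <- sweep(U1 %*% weights$W2, 2, weights$b2, `+`)
  C1 <- relu(sweep(U2 %*% weights$Wc1, 2, weights$bc1, `+`))
  sweep(C1 %*% weights$Wc2, 2, weights$bc2, `+`)
}

#' Training objective (reference form)
#'
#' Cross-entropy over the training nodes plus `kappa` times the L1 norm of
#' the final gate weights (averaged or summed over training nodes).
#'
#' @param scores per-class score matrix.
#' @param labels integer labels (1..C).
#' @param gates final gate weights (nodes x K).
#' @param kappa sparsity coefficient.
#' @param train_idx indices of training nodes.
#' @param l1_scope `"mean"` or `"sum"`.
#' @return scalar loss.
#' @export
model_loss <- function(scores, labels, gates, kappa, train_idx,
                       l1_scope = c("mean", "sum")) {
  if (length(train_idx) == 0L) stop("empty training mask")
  l1_scope <- match.arg(l1_scope)
  ce <- ce_loss_grad(scores, labels, train_idx)$ce
  l1 <- sum(abs(gates[train_idx, , drop = FALSE]))
  ce + kappa * l1 / if (l1_scope == "mean") length(train_idx) else 1
}
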