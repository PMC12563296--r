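toy_setup <- function(seed = 1, n_heads = 2, head_dim = 4, no_msg = FALSE,
                      kappa = 1e-2) {
  g <- generate_planted_partition(c(6, 6), 0.8, 0.15, seed = seed)
  cfg <- influence_config()
  ifm <- build_ifm(build_pim(g, cfg), g, cfg)
  nb <- sample_all(g, ifm, sampling_config())
  mcfg <- model_config(n_heads = n_heads, head_dim = head_dim, dropout = 0,
                       kappa = kappa, no_msg = no_msg)
  X <- make_node_features(g, ifm, n_random = 5, n_spectral = 3, seed = seed)
  inputs <- build_model_inputs(g, ifm, nb, X, mcfg)
  labels <- as.integer(factor(g$labels))
  params <- init_params(mcfg, inputs$n_features, max(labels), seed = seed)
  list(g = g, ifm = ifm, nb = nb, cfg = mcfg, inputs = inputs,
       labels = labels, params = params, train_idx = c(1:5, 7:11))
}

test_that("analytic gradients match finite differences for every parameter block", {
  ts <- toy_setup()
  fb <- dama:::dama_forward_backward(ts$params, ts$inputs, ts$cfg, ts$labels,
                                     ts$train_idx, training = FALSE)
  loss_at <- function(params) {
    dama:::dama_forward_backward(params, ts$inputs, ts$cfg, ts$labels,
                                 ts$train_idx, training = FALSE)$loss
  }
  h <- 1e-6
  for (nm in names(fb$grads)) {
    p <- ts$params
    theta <- p[[nm]]
    # probe a handful of coordinates per block
    idx <- seq_len(min(4L, length(theta)))
    for (ii in idx) {
      p[[nm]][ii] <- theta[ii] + h
      up <- loss_at(p)
      p[[nm]][ii] <- theta[ii] - h
      dn <- loss_at(p)
      p[[nm]][ii] <- theta[ii]
      fd <- (up - dn) / (2 * h)
      expect_equal(fb$grads[[nm]][ii], fd, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, ii))
    }
  }
})

test_that("gradient flows to the learnable decay on distance-heterogeneous neighborhoods", {
  ts <- toy_setup()
  fb <- dama:::dama_forward_backward(ts$params, ts$inputs, ts$cfg, ts$labels,
                                     ts$train_idx, training = FALSE)
  expect_gt(abs(fb$grads$lambda), 0)
})

test_that("attention rows are normalized and match the reference evaluation", {
  ts <- toy_setup()
  fwd <- dama:::dama_forward(ts$params, ts$inputs, ts$cfg, keep_cache = TRUE)
  for (k in seq_len(ts$inputs$K)) {
    hp <- ts$inputs$hops[[k]]
    if (length(hp$i) == 0) next
    al <- fwd$cache$fw[[k]]$alpha
    sums <- rowsum(al, hp$i)
    expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
  }
  # cross-check one node's hop-1 attention row against decay_attention()
  hp <- ts$inputs$hops[[1]]
  v <- hp$i[1]
  members <- hp$j[hp$i == v]
  dists <- hp$d[hp$i == v]
  hd <- ts$cfg$head_dim
  a_ref <- decay_attention(ts$inputs$X[v, ], ts$inputs$X[members, , drop = FALSE],
                           dists, ts$params$Wq1[, 1:hd], ts$params$Wk1[, 1:hd],
                           ts$params$lambda)
  a_got <- fwd$cache$fw[[1]]$alpha[hp$i == v, 1]
  expect_equal(unname(a_got), unname(a_ref), tolerance = 1e-10)
})

test_that("decay-aware attention closed forms hold", {
  Wq <- diag(2); Wk <- diag(2)
  # singleton membership
  expect_equal(decay_attention(c(1, 0), rbind(c(1, 0)), 1, Wq, Wk), 1)
  # zero query-key products give uniform weights regardless of distance
  a <- decay_attention(c(0, 0), rbind(c(1, 2), c(3, 4), c(5, 6)),
                       c(1, 2, 3), Wq, Wk)
  expect_equal(a, rep(1 / 3, 3))
  # two members, equal keys, unit logit: ratio exp(e^-0.3) : exp(e^-0.6),
  # i.e. 1 / (1 + exp(-(e^-0.3 - e^-0.6))) = 0.54785 on the first member
  a2 <- decay_attention(c(1, 0), rbind(c(1, 0), c(1, 0)), c(1, 2),
                        Wq, Wk, lambda = 0.3)
  want <- exp(c(exp(-0.3), exp(-0.6)))
  expect_equal(a2, want / sum(want), tolerance = 1e-12)
  expect_equal(round(a2, 5), c(0.54785, 0.45215))
})

test_that("hop aggregation is convex and layer-normalizes", {
  Wv <- matrix(c(1, 0, 0, 2), 2)
  h <- c(0.3, -0.2)
  members <- rbind(h, h, h)
  for (alpha in list(c(1, 0, 0), c(0.2, 0.5, 0.3))) {
    expect_equal(aggregate_hop(members, alpha, Wv, normalize = FALSE),
                 drop(h %*% Wv))
  }
  # hand-computed weighted sum on distinct members
  M <- rbind(c(1, 0), c(0, 1), c(1, 1))
  al <- c(0.5, 0.3, 0.2)
  expect_equal(aggregate_hop(M, al, Wv, normalize = FALSE),
               drop(al %*% (M %*% Wv)))
  z <- aggregate_hop(M, al, Wv)
  expect_equal(mean(z), 0, tolerance = 1e-9)
})

test_that("base gate lives on the simplex and matches hand softmax", {
  K <- 3
  expect_equal(base_gate(5, 2, matrix(0, K, 2)), rep(1 / K, K))
  Wr <- rbind(c(1, 0), c(0, 0), c(0, 0))
  g <- base_gate(1, 0, Wr)
  expect_equal(round(g, 5), c(0.57612, 0.21194, 0.21194))
  g2 <- base_gate(17.3, 4.2, matrix(rnorm(6), K, 2))
  expect_true(all(g2 > 0))
  expect_equal(sum(g2), 1)
})

test_that("feedback gate uses population std and zeroes out constant batches", {
  Wf <- rbind(c(1, 1), c(0.5, 0), c(0, 2))
  expect_equal(feedback_gate(rbind(c(3, 7), c(3, 7)), Wf), c(0, 0, 0))
  expect_equal(feedback_gate(rbind(c(0, 0), c(2, 2)), matrix(0, 3, 2)), c(0, 0, 0))
  # population std of {0,2} is 1 per dimension
  dg <- feedback_gate(rbind(c(0, 0), c(2, 2)), Wf)
  expect_equal(dg, c(tanh(2), tanh(0.5), tanh(2)))
  expect_equal(round(dg[1], 5), 0.96403)
  # single-row batch is defined, not an error
  expect_equal(feedback_gate(rbind(c(1, 2)), Wf), c(0, 0, 0))
})

test_that("constant features zero every final gate through the feedback path", {
  ts <- toy_setup()
  inputs <- ts$inputs
  inputs$X <- matrix(1, nrow = inputs$n, ncol = 4)
  inputs$n_features <- 4L
  inputs$s <- apply(inputs$X, 2, function(col) sqrt(mean((col - mean(col))^2)))
  params <- init_params(ts$cfg, 4L, max(ts$labels), seed = 2)
  fwd <- dama:::dama_forward(params, inputs, ts$cfg)
  expect_equal(max(abs(fwd$gates)), 0)
})

test_that("gate invariants hold on a trained forward pass", {
  ts <- toy_setup()
  fwd <- dama:::dama_forward(ts$params, ts$inputs, ts$cfg)
  expect_equal(rowSums(fwd$g_base), rep(1, ts$inputs$n), tolerance = 1e-12)
  expect_true(all(fwd$g_base >= 0))
  expect_true(all(abs(fwd$delta_g) < 1))
  expect_true(all(abs(fwd$gates) < 1))
})

test_that("fusion and classification follow the reference forward", {
  ts <- toy_setup(seed = 3)
  n <- ts$inputs$n; D <- ts$cfg$dim; K <- ts$cfg$max_hops
  set.seed(42)
  hops <- lapply(1:K, function(k) matrix(rnorm(n * D), n))
  gates <- matrix(runif(n * K), n)
  S <- fuse_and_classify(hops, gates, ts$params)
  # one-hot gate on hop 1 reduces to classifying h^(1)
  one_hot <- matrix(0, n, K); one_hot[, 1] <- 1
  S1 <- fuse_and_classify(hops, one_hot, ts$params)
  S1b <- fuse_and_classify(hops[c(1, 1, 1)], one_hot / 3 * 3, ts$params)
  expect_equal(dim(S), c(n, max(ts$labels)))
  expect_equal(S1, S1b)
  # zero gates leave only the bias pathway, identical for all nodes
  S0 <- fuse_and_classify(hops, matrix(0, n, K), ts$params)
  expect_equal(S0, matrix(S0[1, ], n, ncol(S0), byrow = TRUE))
  # hand-computed two-node straight-line forward
  p <- ts$params
  z <- gates[1, 1] * hops[[1]][1, ] + gates[1, 2] * hops[[2]][1, ] +
    gates[1, 3] * hops[[3]][1, ]
  u1 <- pmax(drop(z %*% p$W1) + p$b1, 0)
  u2 <- drop(u1 %*% p$W2) + p$b2
  c1 <- pmax(drop(u2 %*% p$Wc1) + p$bc1, 0)
  expect_equal(S[1, ], drop(c1 %*% p$Wc2) + p$bc2, tolerance = 1e-12)
})

test_that("loss reduces to cross-entropy at kappa zero and ln C for uniform scores", {
  n <- 10; C <- 4
  labels <- rep(1:2, 5)
  gates <- matrix(0.5, n, 3)
  uniform <- matrix(0, n, C)
  expect_equal(model_loss(uniform, labels, gates, kappa = 0, train_idx = 1:8),
               log(C))
  perfect <- matrix(-1e4, n, C)
  perfect[cbind(1:n, labels)] <- 1e4
  expect_lt(model_loss(perfect, labels, gates, kappa = 0, train_idx = 1:8), 1e-8)
  # kappa scales the node-averaged gate L1
  l0 <- model_loss(uniform, labels, gates, 0, 1:8)
  l1 <- model_loss(uniform, labels, gates, 0.1, 1:8)
  expect_equal(l1 - l0, 0.1 * 1.5)
  expect_error(model_loss(uniform, labels, gates, 0, integer(0)), "empty")
})

test_that("ablation switches change parameter counts or outputs", {
  ts_full <- toy_setup(seed = 5)
  ts_nomsg <- toy_setup(seed = 5, no_msg = TRUE)
  # gating parameters disappear under the no-gating ablation
  expect_gt(n_parameters(ts_full$params), n_parameters(ts_nomsg$params))
  expect_null(ts_nomsg$params$Wr)

  # gates become the fixed 1/K average
  fwd <- dama:::dama_forward(ts_nomsg$params, ts_nomsg$inputs, ts_nomsg$cfg)
  expect_true(all(fwd$gates == 1 / ts_nomsg$cfg$max_hops))

  # adjacency-only influence changes the sampled neighborhoods or intensities
  g <- ts_full$g
  icfg_abl <- influence_config(beta = 0, gamma = 1)
  ifm_abl <- build_ifm(build_pim(g, icfg_abl), g, icfg_abl)
  expect_false(isTRUE(all.equal(as.matrix(ifm_abl$mat),
                                as.matrix(ts_full$ifm$mat))))

  # full k-hop neighborhoods differ from adaptively sampled ones
  nb_full <- full_neighborhoods(g, 3)
  sizes_s <- vapply(ts_full$nb$nodes, function(nd) length(nd$union), numeric(1))
  sizes_f <- vapply(nb_full$nodes, function(nd) length(nd$union), numeric(1))
  expect_true(any(sizes_f != sizes_s))
})

test_that("stronger sparsity pressure shrinks the final gates on a fixed toy", {
  means <- vapply(c(0, 1e-2, 1), function(kap) {
    ts <- toy_setup(seed = 7, kappa = kap)
    masks <- list(train = ts$train_idx, test = setdiff(1:12, ts$train_idx))
    fit <- train_dama(ts$g, ts$ifm, ts$nb, masks,
                      model_config(n_heads = 2, head_dim = 4, dropout = 0,
                                   kappa = kap),
                      train_config(epochs = 120),
                      features = ts$inputs$X, seed = 7)
    fwd <- dama:::dama_forward(fit$params, fit$inputs, fit$model_cfg)
    mean(abs(fwd$gates))
  }, numeric(1))
  expect_true(all(diff(means) <= 1e-8))
})
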