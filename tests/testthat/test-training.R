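fit_toy <- function(seed = 1, epochs = 200, ...) {
  g <- generate_planted_partition(c(10, 10), 1, 0, seed = seed)  # two 10-cliques
  cfg <- influence_config()
  ifm <- build_ifm(build_pim(g, cfg), g, cfg)
  nb <- sample_all(g, ifm, sampling_config())
  masks <- make_split(g$n_nodes, seed = seed)
  fit <- train_dama(g, ifm, nb, masks,
                    model_config(n_heads = 2, head_dim = 8, ...),
                    train_config(epochs = epochs), seed = seed)
  list(g = g, ifm = ifm, nb = nb, masks = masks, fit = fit)
}

test_that("split masks have the contracted sizes and are seed-reproducible", {
  s <- make_split(10, 0.8, seed = 3)
  expect_length(s$train, 8)
  expect_length(s$test, 2)
  expect_setequal(c(s$train, s$test), 1:10)
  expect_identical(make_split(10, 0.8, seed = 3), s)
  expect_false(identical(make_split(10, 0.8, seed = 4)$train, s$train))
  expect_error(make_split(4), "n_labeled")

  # long-run train frequency of each node stays near the split ratio
  n <- 100; draws <- 1000
  counts <- integer(n)
  for (d in seq_len(draws)) {
    tr <- make_split(n, 0.8, seed = d)$train
    counts[tr] <- counts[tr] + 1L
  }
  bounds <- qbinom(c(0.005, 0.995), draws, 0.8)
  expect_true(all(counts >= bounds[1] & counts <= bounds[2]))
})

test_that("two disjoint cliques are learned perfectly with decreasing loss", {
  r <- fit_toy(seed = 1)
  expect_lt(tail(r$fit$loss_history, 1), r$fit$loss_history[1])
  ev <- evaluate_fit(r$fit, r$g, r$masks)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$nmi, 1)
  expect_equal(ev$ari, 1)
})

test_that("initial loss is near ln C under near-uniform initial scores", {
  r <- fit_toy(seed = 2, epochs = 1)
  expect_lt(abs(r$fit$loss_history[1] - log(2)), 0.3)
})

test_that("the sparsity coefficient changes the optimization trajectory", {
  g <- generate_planted_partition(c(8, 8), 0.9, 0.05, seed = 5)
  cfg <- influence_config()
  ifm <- build_ifm(build_pim(g, cfg), g, cfg)
  nb <- sample_all(g, ifm, sampling_config())
  masks <- make_split(g$n_nodes, seed = 5)
  hist <- lapply(c(0, 1e-3, 1e-1), function(kap) {
    train_dama(g, ifm, nb, masks,
               model_config(n_heads = 2, head_dim = 4, kappa = kap),
               train_config(epochs = 30), seed = 5)$loss_history
  })
  expect_false(identical(hist[[1]], hist[[2]]))
  expect_false(identical(hist[[2]], hist[[3]]))
})

test_that("training is deterministic given the seed", {
  r1 <- fit_toy(seed = 9, epochs = 25)
  r2 <- fit_toy(seed = 9, epochs = 25)
  expect_identical(r1$fit$loss_history, r2$fit$loss_history)
  expect_identical(r1$fit$params, r2$fit$params)
})

test_that("test-node labels never leak into training", {
  g <- generate_planted_partition(c(10, 10), 0.8, 0.05, seed = 11)
  cfg <- influence_config()
  ifm <- build_ifm(build_pim(g, cfg), g, cfg)
  nb <- sample_all(g, ifm, sampling_config())
  masks <- make_split(g$n_nodes, seed = 11)
  g_scrambled <- g
  g_scrambled$labels[masks$test] <- sample(1:2, length(masks$test), replace = TRUE)
  f1 <- train_dama(g, ifm, nb, masks, model_config(n_heads = 2, head_dim = 4),
                   train_config(epochs = 20), seed = 11)
  f2 <- train_dama(g_scrambled, ifm, nb, masks,
                   model_config(n_heads = 2, head_dim = 4),
                   train_config(epochs = 20), seed = 11)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$params, f2$params)
})

test_that("agreement metrics match an independent confusion-matrix implementation", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    truth <- sample(1:4, n, replace = TRUE)
    pred <- sample(1:5, n, replace = TRUE)
    ref <- oracle_scores(truth, pred)
    expect_equal(accuracy_score(truth, pred), ref$accuracy, tolerance = 1e-9)
    expect_equal(nmi_score(truth, pred), ref$nmi, tolerance = 1e-9)
    expect_equal(ari_score(truth, pred), ref$ari, tolerance = 1e-9)
    expect_equal(f1_score(truth, pred), ref$f1_macro, tolerance = 1e-9)
  }
})

test_that("metrics behave correctly on degenerate and permuted predictions", {
  truth <- rep(1:2, each = 10)
  expect_equal(accuracy_score(truth, truth), 1)
  expect_equal(nmi_score(truth, truth), 1)
  expect_equal(ari_score(truth, truth), 1)
  expect_equal(f1_score(truth, truth), 1)
  # class-permuted predictions: partition metrics stay 1, accuracy drops
  perm <- 3 - truth
  expect_equal(nmi_score(truth, perm), 1)
  expect_equal(ari_score(truth, perm), 1)
  expect_equal(accuracy_score(truth, perm), 0)
  # constant predictor on a balanced 2-class set
  ones <- rep(1, 20)
  expect_equal(accuracy_score(truth, ones), 0.5)
  expect_equal(ari_score(truth, ones), 0)
})

test_that("run_experiment aggregates reproducibly and a single repeat equals train+evaluate", {
  g <- generate_planted_partition(c(8, 8), 0.9, 0.05, seed = 21)
  cfg <- influence_config()
  ifm <- build_ifm(build_pim(g, cfg), g, cfg)
  nb <- sample_all(g, ifm, sampling_config())
  tcfg <- train_config(epochs = 15, base_seed = 21)
  mcfg <- model_config(n_heads = 2, head_dim = 4)
  rep1 <- run_experiment(g, ifm, nb, mcfg, tcfg, repeats = 1)
  masks <- make_split(g$n_nodes, seed = 21)
  fit <- train_dama(g, ifm, nb, masks, mcfg, tcfg, seed = 21)
  ev <- evaluate_fit(fit, g, masks)
  expect_equal(rep1$per_run$accuracy, ev$accuracy)
  expect_equal(rep1$per_run$modularity, ev$modularity)

  rep3 <- run_experiment(g, ifm, nb, mcfg, tcfg, repeats = 3)
  rep3b <- run_experiment(g, ifm, nb, mcfg, tcfg, repeats = 3)
  expect_identical(rep3$summary, rep3b$summary)
  expect_true(all(rep3$summary$sd >= 0))
})

test_that("checkpoints restore identical predictions", {
  r <- fit_toy(seed = 13, epochs = 20)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(r$fit, f)
  back <- load_checkpoint(f)
  expect_identical(predict(back), predict(r$fit))
})
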