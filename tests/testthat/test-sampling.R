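test_that("dynamic threshold equals mu times the mean incident intensity", {
  g <- triangle()
  ifm <- make_ifm(g, beta = 0, gamma = 1)   # all incident entries equal 1
  for (mu in c(0, 0.5, 1, 2)) {
    expect_equal(dynamic_threshold(ifm, 1L, g, mu), mu * 1)
  }

  # 6-node graph with heterogeneous intensities vs exhaustive enumeration
  g6 <- dama_graph(6, rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4), c(4, 5),
                            c(4, 6), c(5, 6)))
  ifm6 <- make_ifm(g6)
  A <- dense_adj(g6)
  M <- as.matrix(ifm6$mat)
  frontier <- c(2L, 4L)
  acc <- c()
  for (j in frontier) for (h in which(A[j, ] == 1)) acc <- c(acc, M[j, h])
  expect_equal(dynamic_threshold(ifm6, frontier, g6, 0.7), 0.7 * mean(acc))

  # isolated frontier signals termination
  giso <- dama_graph(3, rbind(c(1, 2)))
  expect_true(is.na(dynamic_threshold(make_ifm(giso), 3L, giso, 1)))
})

test_that("zero threshold with no early stop retains the exact k-hop ball minus the node", {
  for (seed in 1:3) {
    g <- random_graph(10, 0.3, seed)
    ifm <- make_ifm(g)
    D <- oracle_distances(g)
    nb <- sample_all(g, ifm, sampling_config(mu = 0, epsilon = 0, max_hops = 2))
    for (v in seq_len(g$n_nodes)) {
      ball <- setdiff(which(D[v, ] <= 2 & is.finite(D[v, ])), v)
      expect_equal(nb$nodes[[v]]$union, sort(ball))
    }
  }
})

test_that("isolated nodes yield empty, flagged neighborhoods", {
  g <- dama_graph(4, rbind(c(1, 2), c(2, 3)))
  nd <- sample_node(g, make_ifm(g), 4, sampling_config())
  expect_true(nd$isolated)
  expect_equal(nd$union, integer(0))
})


test_that("sampling matches the literal brute-force recursion on all small connected graphs", {
  # exhaustive over all connected labeled graphs with 4 and 5 nodes
  for (n in 4:5) {
    graphs <- all_connected_graphs(n)
    bad <- sum(!vapply(graphs, check_against_oracle, logical(1),
                       check_hops = TRUE))
    expect_equal(bad, 0L)
  }
})

test_that("sampling matches the brute-force recursion on random 6-8 node graphs", {
  cases <- expand.grid(n = 6:8, seed = 1:8)
  for (r in seq_len(nrow(cases))) {
    g <- random_graph(cases$n[r], 0.4, cases$seed[r] + 100 * cases$n[r])
    if (!igraph::is_connected(as_igraph(g))) next
    expect_true(check_against_oracle(g))
  }
})

test_that("signed early-stop variant is exposed and stops no later than absolute", {
  g <- random_graph(10, 0.35, seed = 5)
  ifm <- make_ifm(g)
  for (v in seq_len(g$n_nodes)) {
    ka <- sample_node(g, ifm, v, sampling_config(stop_rule = "absolute"))$k_stop
    ks <- sample_node(g, ifm, v, sampling_config(stop_rule = "signed"))$k_stop
    expect_lte(ks, ka)
  }
})

test_that("retained sets shrink monotonically in mu (before early stop)", {
  g <- generate_planted_partition(c(20, 20), 0.4, 0.05, seed = 3)
  ifm <- make_ifm(g)
  cfg0 <- sampling_config(epsilon = 1e-12)   # effectively no early stop
  sizes <- sapply(c(0, 0.5, 1, 2), function(mu) {
    cfg <- sampling_config(mu = mu, epsilon = 1e-12)
    nb <- sample_all(g, ifm, cfg)
    mean(vapply(nb$nodes, function(nd) length(nd$union), numeric(1)))
  })
  expect_true(all(diff(sizes) <= 1e-12))

  # per-hop subset relation at hop 1 (threshold rule is per hop)
  nb1 <- sample_all(g, ifm, sampling_config(mu = 0.5, epsilon = 1e-12))
  nb2 <- sample_all(g, ifm, sampling_config(mu = 1.5, epsilon = 1e-12))
  for (v in seq_len(g$n_nodes)) {
    h1 <- nb1$nodes[[v]]$hops
    h2 <- nb2$nodes[[v]]$hops
    if (length(h1) >= 1 && length(h2) >= 1) {
      expect_true(all(h2[[1]] %in% h1[[1]]))
    }
  }
})

test_that("hop layers stay inside the BFS ball and unions are consistent", {
  g <- random_graph(12, 0.3, seed = 8)
  ifm <- make_ifm(g)
  D <- oracle_distances(g)
  nb <- sample_all(g, ifm, sampling_config())
  for (v in seq_len(g$n_nodes)) {
    nd <- nb$nodes[[v]]
    for (k in seq_along(nd$hops)) {
      if (length(nd$hops[[k]]) > 0) {
        expect_true(all(D[v, nd$hops[[k]]] <= k))
      }
    }
    expect_equal(nd$union, sort(unique(unlist(nd$hops))))
  }
})

test_that("sample_all is deterministic and covers the triangle case", {
  g <- triangle()
  ifm <- make_ifm(g, beta = 0, gamma = 1)
  nb <- sample_all(g, ifm, sampling_config(mu = 0))
  expect_equal(nb$nodes[[1]]$union, c(2L, 3L))
  expect_equal(nb$nodes[[2]]$union, c(1L, 3L))
  nb2 <- sample_all(g, ifm, sampling_config(mu = 0))
  expect_identical(nb, nb2)
})

test_that("cross-block contamination is lower in sampled sets than k-hop balls", {
  g <- generate_planted_partition(c(30, 30), 0.35, 0.1, seed = 4)
  ifm <- make_ifm(g)
  nb_s <- sample_all(g, ifm, sampling_config(mu = 1))
  nb_f <- full_neighborhoods(g, 3)
  frac_cross <- function(nb) {
    num <- den <- 0
    for (v in seq_len(g$n_nodes)) {
      u <- nb$nodes[[v]]$union
      num <- num + sum(g$labels[u] != g$labels[v])
      den <- den + length(u)
    }
    num / den
  }
  expect_lt(frac_cross(nb_s), frac_cross(nb_f))
})

test_that("neighborhood audit export writes one line per node and hop", {
  g <- path3()
  nb <- sample_all(g, make_ifm(g), sampling_config(mu = 0, epsilon = 0))
  f <- withr::local_tempfile()
  write_neighborhoods(nb, f)
  lines <- readLines(f)
  expect_true(any(grepl("^1 1: 2$", lines)))
  expect_true(any(grepl("^1 2: 3$", lines)))
})
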