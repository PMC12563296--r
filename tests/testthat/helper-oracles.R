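# Independent reference implementations used as oracles. These deliberately
# use different algorithms / data layouts than the package code.

# dense adjacency matrix straight from the edge list
dense_adj <- function(g) {
  A <- matrix(0, g$n_nodes, g$n_nodes)
  for (r in seq_len(nrow(g$edges))) {
    i <- g$edges[r, 1]; j <- g$edges[r, 2]
    A[i, j] <- A[j, i] <- 1
  }
  A
}

# all-pairs shortest paths by Floyd-Warshall
oracle_distances <- function(g) {
  n <- g$n_nodes
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  A <- dense_adj(g)
  D[A == 1] <- 1
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# modularity as the literal double sum over ordered node pairs
oracle_modularity <- function(g, comm) {
  A <- dense_adj(g)
  k <- rowSums(A)
  m <- sum(A) / 2
  tot <- 0
  n <- g$n_nodes
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (comm[i] == comm[j]) tot <- tot + A[i, j] - k[i] * k[j] / (2 * m)
    }
  }
  tot / (2 * m)
}

# naive graph statistics via triangle counting and Floyd-Warshall
oracle_statistics <- function(g) {
  A <- dense_adj(g)
  n <- g$n_nodes
  deg <- rowSums(A)
  local_c <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1)
    if (length(nb) < 2) return(0)
    links <- sum(A[nb, nb]) / 2
    links / choose(length(nb), 2)
  }, numeric(1))
  D <- oracle_distances(g)
  finite <- is.finite(D) & D > 0
  list(avg_degree = sum(deg) / n,
       avg_clustering = mean(local_c),
       diameter = max(D[is.finite(D)]),
       avg_path_length = mean(D[finite]))
}

# literal step-by-step evaluation of the adaptive sampling recursion,
# written against the equations rather than the package's data structures
oracle_sample_node <- function(g, M, v, mu, eps, K, min_keep = 1,
                               rule = "absolute") {
  A <- dense_adj(g)
  nbrs <- function(u) which(A[u, ] == 1)
  if (length(nbrs(v)) == 0) {
    return(list(hops = list(), union = integer(0)))
  }
  retained <- v
  frontier <- v
  qprev <- mean(M[v, nbrs(v)])
  hops <- list()
  for (k in seq_len(K)) {
    pairs <- do.call(rbind, lapply(frontier, function(j) {
      hs <- nbrs(j)
      if (length(hs) == 0) return(NULL)
      cbind(j = j, h = hs, a = M[j, hs])
    }))
    if (is.null(pairs)) break
    r_k <- mu * mean(pairs[, "a"])
    cand <- pairs[!(pairs[, "h"] %in% retained), , drop = FALSE]
    layer <- sort(unique(cand[cand[, "a"] >= r_k, "h"]))
    if (length(layer) == 0 && nrow(cand) > 0 && min_keep > 0) {
      strongest <- tapply(cand[, "a"], cand[, "h"], max)
      ord <- order(-strongest, as.integer(names(strongest)))
      layer <- as.integer(names(strongest))[ord][seq_len(min(min_keep, length(ord)))]
    }
    if (length(layer) == 0) break
    hops[[k]] <- as.integer(layer)
    retained <- c(retained, layer)
    spairs <- do.call(rbind, lapply(layer, function(j) {
      hs <- nbrs(j)
      if (length(hs) == 0) return(NULL)
      cbind(a = M[j, hs])
    }))
    qk <- if (is.null(spairs)) 0 else mean(spairs[, "a"])
    dq <- if (rule == "absolute") abs(qk - qprev) else qk - qprev
    if (dq < eps) break
    qprev <- qk
    frontier <- layer
  }
  list(hops = hops, union = sort(setdiff(unlist(hops), v)))
}

# confusion-matrix based agreement scores
oracle_scores <- function(truth, pred) {
  ct <- table(truth, pred)
  n <- sum(ct)
  # NMI (sum normalization 2I/(H1+H2))
  pij <- ct / n
  pi_ <- rowSums(pij); p_j <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, p_j)[nz]))
  h1 <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  h2 <- -sum(p_j[p_j > 0] * log(p_j[p_j > 0]))
  nmi <- if (h1 + h2 == 0) 1 else 2 * mi / (h1 + h2)
  # ARI from pair counts
  sij <- sum(choose(ct, 2))
  si <- sum(choose(rowSums(ct), 2)); sj <- sum(choose(colSums(ct), 2))
  expected <- si * sj / choose(n, 2)
  ari <- if (max(si, sj) == 0) 0 else
    (sij - expected) / ((si + sj) / 2 - expected)
  # macro F1 over true classes
  classes <- rownames(ct)
  f1s <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  list(nmi = nmi, ari = ari, f1_macro = mean(f1s),
       accuracy = mean(truth == pred))
}

# Erdos-Renyi sample as a dama_graph
random_graph <- function(n, p, seed) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  dama_graph(n, pairs[keep, , drop = FALSE])
}

# all connected labeled graphs on n nodes (as edge matrices)
all_connected_graphs <- function(n) {
  pairs <- t(combn(n, 2))
  np <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^np - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(np) - 1)))
    g <- dama_graph(n, pairs[sel, , drop = FALSE])
    if (igraph::is_connected(as_igraph(g))) out[[length(out) + 1]] <- g
  }
  out
}

# small deterministic fixture graphs
path3 <- function() dama_graph(3, rbind(c(1, 2), c(2, 3)))
triangle <- function() dama_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
star4 <- function() dama_graph(4, rbind(c(1, 2), c(1, 3), c(1, 4)))
two_triangles <- function() {
  dama_graph(6, rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)),
             labels = c(1, 1, 1, 2, 2, 2))
}

make_ifm <- function(g, beta = 0.5, gamma = 0.5) {
  cfg <- influence_config(beta = beta, gamma = gamma)
  build_ifm(build_pim(g, cfg), g, cfg)
}

# package-vs-oracle agreement over a mu sweep (used by several files)
check_against_oracle <- function(g, mus = c(0, 0.5, 1), check_hops = FALSE) {
  ifm <- make_ifm(g)
  M <- as.matrix(ifm$mat)
  ok <- TRUE
  for (mu in mus) {
    cfg <- sampling_config(mu = mu, epsilon = 1e-3, max_hops = 3)
    nb <- sample_all(g, ifm, cfg)
    for (v in seq_len(g$n_nodes)) {
      ref <- oracle_sample_node(g, M, v, mu, 1e-3, 3)
      ok <- ok && identical(nb$nodes[[v]]$union, ref$union)
      if (check_hops) {
        ok <- ok && identical(lapply(nb$nodes[[v]]$hops, as.integer), ref$hops)
      }
    }
  }
  ok
}
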