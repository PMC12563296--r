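#' Construct an undirected graph object
#'
#' The basic container used throughout the package: a simple undirected graph
#' with optional node features and optional integer community labels. Edges
#' are stored once per unordered pair with the smaller endpoint first;
#' self-loops are rejected. Node ids are 1-based internally (the R
#' convention); file readers and writers translate from/to 0-based ids.
#'
#' @param n_nodes number of nodes (nodes are `1..n_nodes`).
#' @param edges two-column integer matrix of endpoints (1-based). Duplicate
#'   and reversed duplicate rows are collapsed; self-loops are an error here
#'   (readers drop them with a warning instead).
#' @param features optional numeric matrix with `n_nodes` rows.
#' @param labels optional integer vector of length `n_nodes` (community ids).
#' @return an object of class `dama_graph` with elements `n_nodes`, `edges`,
#'   `features`, `labels`.
#' @export
dama_graph <- function(n_nodes, edges, features = NULL, labels = NULL) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(length(n_nodes) == 1L, n_nodes >= 1L)
  edges <- canonicalize_edges(edges, n_nodes, drop_self_loops = FALSE)
  if (!is.null(features)) {
    features <- as.matrix(features)
    stopifnot(nrow(features) == n_nodes)
  }
  if (!is.null(labels)) {
    stopifnot(length(labels) == n_nodes, !anyNA(labels))
    labels <- as.integer(labels)
  }
  structure(list(n_nodes = n_nodes, edges = edges,
                 features = features, labels = labels),
            class = "dama_graph")
}

# Canonical edge form: integer matrix, min endpoint first, sorted, unique.
canonicalize_edges <- function(edges, n_nodes, drop_self_loops = TRUE) {
  if (is.null(edges) || length(edges) == 0L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j"))))
  }
  edges <- matrix(as.integer(as.matrix(edges)[, 1:2]), ncol = 2L)
  if (anyNA(edges)) stop("edge endpoints must be integers")
  if (any(edges < 1L) || any(edges > n_nodes)) {
    stop("edge endpoint outside [1, n_nodes]")
  }
  self <- edges[, 1L] == edges[, 2L]
  if (any(self)) {
    if (!drop_self_loops) stop("self-loops are not allowed")
    warning(sprintf("dropped %d self-loop(s)", sum(self)))
    edges <- edges[!self, , drop = FALSE]
  }
  e <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  e <- unique(e)
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  dimnames(e) <- list(NULL, c("i", "j"))
  e
}

#' @export
print.dama_graph <- function(x, ...) {
  cat(sprintf("dama_graph: %d nodes, %d edges%s%s\n",
              x$n_nodes, nrow(x$edges),
              if (!is.null(x$features))
                sprintf(", %d features", ncol(x$features)) else "",
              if (!is.null(x$labels))
                sprintf(", %d communities", length(unique(x$labels))) else ""))
  invisible(x)
}

#' Number of edges
#' @param g a `dama_graph`.
#' @return integer edge count.
#' @export
n_edges <- function(g) nrow(g$edges)

#' Node degrees
#' @param g a `dama_graph`.
#' @return integer vector of length `n_nodes`.
#' @export
degrees <- function(g) {
  tabulate(c(g$edges[, 1L], g$edges[, 2L]), nbins = g$n_nodes)
}

#' Adjacency list
#'
#' @param g a `dama_graph`.
#' @return list of length `n_nodes`; element `i` holds the sorted neighbor
#'   ids of node `i`.
#' @export
adjacency_list <- function(g) {
  adj <- split(c(g$edges[, 2L], g$edges[, 1L]),
               factor(c(g$edges[, 1L], g$edges[, 2L]), levels = seq_len(g$n_nodes)))
  lapply(adj, function(v) sort(as.integer(v)))
}

#' Sparse adjacency matrix
#' @param g a `dama_graph`.
#' @return symmetric sparse 0/1 matrix (`Matrix::dgCMatrix`).
#' @export
adjacency_matrix <- function(g) {
  n <- g$n_nodes
  if (n_edges(g) == 0L) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                                    x = numeric(0), dims = c(n, n)))
  Matrix::sparseMatrix(i = c(g$edges[, 1L], g$edges[, 2L]),
                       j = c(g$edges[, 2L], g$edges[, 1L]),
                       x = 1, dims = c(n, n))
}

#' Convert to an igraph object
#' @param g a `dama_graph`.
#' @return an `igraph` graph; labels (if any) are attached as the vertex
#'   attribute `community`.
#' @export
as_igraph <- function(g) {
  ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, g$n_nodes - igraph::vcount(ig)))
  if (!is.null(g$labels)) igraph::V(ig)$community <- g$labels
  ig
}

#' Read an undirected graph from an edge-list file
#'
#' Accepts whitespace- or comma-separated integer pairs, one edge per line.
#' Lines starting with `#` are comments; an optional header line of the form
#' `% n m` declares the node and edge counts (only `n` is used). Duplicate
#' edges (in either orientation) collapse to one; self-loops are dropped with
#' a warning.
#'
#' @param path file path, or a character vector of lines (for tests).
#' @param zero_based if `TRUE` (default) ids in the file are 0-based and are
#'   shifted to the internal 1-based convention; if `FALSE` they are taken as
#'   1-based.
#' @param n_nodes optional node count override (otherwise max id + 1, or the
#'   `%` header when present).
#' @return a `dama_graph`.
#' @export
read_edge_list <- function(path, zero_based = TRUE, n_nodes = NULL) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- trimws(lines)
  header_n <- NULL
  keep <- !(lines == "" | startsWith(lines, "#"))
  hdr <- startsWith(lines, "%")
  if (any(hdr)) {
    toks <- strsplit(sub("^%\\s*", "", lines[which(hdr)[1L]]), "[,[:space:]]+")[[1]]
    header_n <- suppressWarnings(as.integer(toks[1]))
    keep <- keep & !hdr
  }
  idx <- which(keep)
  if (length(idx) == 0L && is.null(header_n) && is.null(n_nodes)) {
    stop("no edges found and no node count declared")
  }
  pairs <- matrix(integer(0), ncol = 2L)
  if (length(idx) > 0L) {
    toks <- strsplit(lines[idx], "[,[:space:]]+")
    bad <- vapply(toks, function(t) length(t) < 2L ||
                    anyNA(suppressWarnings(as.integer(t[1:2]))), logical(1))
    if (any(bad)) {
      stop(sprintf("cannot parse edge on line %d: '%s'",
                   idx[which(bad)[1L]], lines[idx[which(bad)[1L]]]))
    }
    pairs <- t(vapply(toks, function(t) as.integer(t[1:2]), integer(2)))
    if (zero_based) pairs <- pairs + 1L
  }
  n <- n_nodes %||% header_n %||% max(pairs)
  if (length(pairs) > 0L && max(pairs) > n) {
    stop("edge endpoint exceeds declared node count")
  }
  edges <- canonicalize_edges(pairs, n, drop_self_loops = TRUE)
  dama_graph(n, edges)
}

#' Write a graph as an edge list
#' @param g a `dama_graph`.
#' @param path output file path.
#' @param zero_based write 0-based ids (default `TRUE`).
#' @param header write a `% n m` header (default `TRUE`).
#' @export
write_edge_list <- function(g, path, zero_based = TRUE, header = TRUE) {
  off <- if (zero_based) 1L else 0L
  lines <- sprintf("%d %d", g$edges[, 1L] - off, g$edges[, 2L] - off)
  if (header) lines <- c(sprintf("%% %d %d", g$n_nodes, n_edges(g)), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Write a graph in GML format (for visualization tools)
#' @param g a `dama_graph`.
#' @param path output file path.
#' @export
write_gml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "gml")
  invisible(path)
}

#' Read a citation-network bundle (Cora/CiteSeer style)
#'
#' Reads the Planetoid-style plain-text layout: a `.content` file with one
#' line per node (`<id> <feature tokens...> <label>`) and a `.cites` file
#' with one directed citation pair per line. Directed pairs are
#' canonicalized to undirected edges, duplicates collapse, and self-citations
#' are dropped, which is what yields the published undirected edge counts
#' for these benchmarks.
#'
#' @param content_path path to the node file (`id feat... label`).
#' @param cites_path path to the citation pair file.
#' @return a `dama_graph` with binary features and integer labels (labels are
#'   the sorted unique label strings, coded 1..C).
#' @export
read_citation_bundle <- function(content_path, cites_path) {
  content <- strsplit(trimws(readLines(content_path)), "[\t[:space:]]+")
  content <- content[lengths(content) >= 2L]
  ids <- vapply(content, `[`, character(1), 1L)
  lab <- vapply(content, function(t) t[length(t)], character(1))
  nf <- lengths(content) - 2L
  if (length(unique(nf)) != 1L) stop("inconsistent feature counts in content file")
  feats <- NULL
  if (nf[1] > 0L) {
    feats <- t(vapply(content, function(t)
      as.numeric(t[2:(length(t) - 1L)]), numeric(nf[1])))
  }
  id_map <- stats::setNames(seq_along(ids), ids)
  cl <- strsplit(trimws(readLines(cites_path)), "[\t[:space:]]+")
  cl <- cl[lengths(cl) >= 2L]
  a <- vapply(cl, `[`, character(1), 1L)
  b <- vapply(cl, `[`, character(1), 2L)
  known <- a %in% ids & b %in% ids
  if (any(!known)) {
    warning(sprintf("dropped %d citation(s) to unknown node ids", sum(!known)))
  }
  pairs <- cbind(id_map[a[known]], id_map[b[known]])
  self <- pairs[, 1L] == pairs[, 2L]
  if (any(self)) pairs <- pairs[!self, , drop = FALSE]
  edges <- canonicalize_edges(pairs, length(ids), drop_self_loops = TRUE)
  dama_graph(length(ids), edges, features = feats,
             labels = as.integer(factor(lab, levels = sort(unique(lab)))))
}

#' Hop distances from one source node (BFS)
#'
#' @param g a `dama_graph`.
#' @param source node id.
#' @param cutoff maximum depth; nodes farther than `cutoff` (or unreachable)
#'   are absent from the result. Default `Inf`.
#' @return named integer vector, names = reached node ids, values = hop
#'   distances (0 for the source).
#' @export
bfs_distances <- function(g, source, cutoff = Inf) {
  source <- as.integer(source)
  if (length(source) != 1L || is.na(source) || source < 1L || source > g$n_nodes) {
    stop("invalid source node id")
  }
  adj <- adjacency_list(g)
  dist <- rep.int(NA_integer_, g$n_nodes)
  dist[source] <- 0L
  frontier <- source
  d <- 0L
  while (length(frontier) > 0L && d < cutoff) {
    d <- d + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    if (length(nxt) == 0L) break
    dist[nxt] <- d
    frontier <- nxt
  }
  reached <- which(!is.na(dist))
  stats::setNames(dist[reached], reached)
}

#' All-pairs hop distance matrix
#'
#' Convenience wrapper around [igraph::distances()] (unweighted BFS).
#' Unreachable pairs are `Inf`.
#' @param g a `dama_graph`.
#' @return `n x n` numeric matrix of shortest-path lengths.
#' @export
distance_matrix <- function(g) {
  igraph::distances(as_igraph(g), algorithm = "unweighted")
}

#' Number of common neighbors of two distinct nodes
#' @param g a `dama_graph`.
#' @param i,j distinct node ids.
#' @return integer count `|Gamma(i) intersect Gamma(j)|`.
#' @export
common_neighbor_count <- function(g, i, j) {
  i <- as.integer(i); j <- as.integer(j)
  stopifnot(i >= 1L, i <= g$n_nodes, j >= 1L, j <= g$n_nodes)
  if (i == j) stop("common_neighbor_count is defined for distinct nodes")
  adj <- adjacency_list(g)
  length(intersect(adj[[i]], adj[[j]]))
}

#' Summary statistics of a graph
#'
#' Average degree (`2|E|/n`), diameter, average shortest-path length and
#' average local clustering coefficient. Nodes with degree below 2 contribute
#' a local clustering of 0 to the average. On a disconnected graph the
#' diameter and average path length are computed on the largest connected
#' component (with a message).
#'
#' @param g a non-empty `dama_graph`.
#' @return list with `n_nodes`, `n_edges`, `avg_degree`, `diameter`,
#'   `avg_path_length`, `avg_clustering`.
#' @export
graph_statistics <- function(g) {
  if (g$n_nodes == 0L) stop("empty graph")
  ig <- as_igraph(g)
  comp <- igraph::components(ig)
  if (comp$no > 1L) {
    message(sprintf(
      "graph has %d components; diameter/path length computed on the largest (%d nodes)",
      comp$no, max(comp$csize)))
    ig_lcc <- igraph::induced_subgraph(ig, which(comp$membership == which.max(comp$csize)))
  } else {
    ig_lcc <- ig
  }
  lc <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
  lc[is.na(lc)] <- 0
  list(
    n_nodes = g$n_nodes,
    n_edges = n_edges(g),
    avg_degree = 2 * n_edges(g) / g$n_nodes,
    diameter = igraph::diameter(ig_lcc, unconnected = FALSE),
    avg_path_length = igraph::mean_distance(ig_lcc),
    avg_clustering = mean(lc)
  )
}

#' Newman modularity of a partition
#'
#' Evaluates `Q = 1/(2m) * sum_ij (A_ij - k_i k_j / (2m)) delta(c_i, c_j)`
#' over ordered node pairs, the standard quality score comparing
#' within-community edge density to a degree-preserving random baseline.
#'
#' @param g a `dama_graph` with at least one edge.
#' @param assignment integer community id per node (ids need not be
#'   contiguous), or a `dama_partition`.
#' @return modularity in `[-0.5, 1]`.
#' @export
modularity_q <- function(g, assignment) {
  if (inherits(assignment, "dama_partition")) assignment <- assignment$assignment
  m <- n_edges(g)
  if (m == 0L) stop("modularity is undefined on an edgeless graph")
  stopifnot(length(assignment) == g$n_nodes, !anyNA(assignment))
  same <- assignment[g$edges[, 1L]] == assignment[g$edges[, 2L]]
  e_in <- sum(same)                      # edges inside communities
  k <- degrees(g)
  ksum <- vapply(split(k, assignment), sum, numeric(1))
  e_in / m - sum((ksum / (2 * m))^2)
}

#' A partition of the node set
#' @param assignment integer community id per node.
#' @return object of class `dama_partition`.
#' @export
dama_partition <- function(assignment) {
  stopifnot(!anyNA(assignment))
  structure(list(assignment = as.integer(assignment)), class = "dama_partition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
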