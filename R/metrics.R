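# Coerce a binary_graph / 0-1 matrix to the integer adjacency the C++ core
# expects.
as_adjacency <- function(g) {
  a <- if (inherits(g, "binary_graph")) g$adjacency else as.matrix(g)
  if (nrow(a) != ncol(a)) stop("adjacency must be square", call. = FALSE)
  storage.mode(a) <- "integer"
  a
}

#' Shortest path lengths
#'
#' Breadth-first-search hop distances between all node pairs; unreachable
#' pairs are `Inf`, the diagonal 0.
#'
#' @param g a [binary_graph()] or 0/1 adjacency matrix.
#' @return numeric matrix of hop counts.
#' @export
shortest_path_lengths <- function(g) {
  a <- as_adjacency(g)
  d <- cpp_bfs_distances(a)
  dimnames(d) <- dimnames(a)
  d
}

#' Characteristic path length
#'
#' Mean hop distance over reachable ordered pairs; disconnected pairs are
#' excluded and their count attached as attribute `n_unreachable_pairs`.
#'
#' @param g a [binary_graph()] or adjacency matrix.
#' @return scalar `L >= 1` (for any graph with an edge).
#' @export
characteristic_path_length <- function(g) {
  d <- shortest_path_lengths(g)
  off <- d[row(d) != col(d)]
  reach <- is.finite(off)
  if (!any(reach)) stop("no reachable node pairs", call. = FALSE)
  structure(mean(off[reach]), n_unreachable_pairs = sum(!reach) / 2)
}

#' Nodal path length
#'
#' Per node, the mean hop distance to its reachable partners; isolated
#' nodes (no reachable partner) get `Inf`.
#'
#' @inheritParams characteristic_path_length
#' @return numeric vector, one value per node.
#' @export
nodal_path_length <- function(g) {
  d <- shortest_path_lengths(g)
  diag(d) <- NA
  apply(d, 1, function(r) {
    r <- r[!is.na(r) & is.finite(r)]
    if (!length(r)) Inf else mean(r)
  })
}

#' Global efficiency
#'
#' Mean inverse shortest path length over ordered pairs, with `1/Inf = 0`
#' for unreachable pairs — well defined on disconnected graphs.
#'
#' @inheritParams characteristic_path_length
#' @return scalar in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  d <- shortest_path_lengths(g)
  inv <- 1 / d
  diag(inv) <- 0
  n <- nrow(d)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  sum(inv) / (n * (n - 1))
}

#' @rdname global_efficiency
#' @return `nodal_global_efficiency`: per-node mean of `1/d` to all partners.
#' @export
nodal_global_efficiency <- function(g) {
  d <- shortest_path_lengths(g)
  inv <- 1 / d
  diag(inv) <- 0
  rowSums(inv) / (nrow(d) - 1)
}

#' Clustering coefficient
#'
#' Per node, the fraction of neighbour pairs that are themselves connected
#' (`2 t / (k (k - 1))`); nodes of degree < 2 get 0. The graph value is the
#' mean over all nodes.
#'
#' @inheritParams characteristic_path_length
#' @return `nodal_clustering`: numeric vector; `clustering_coefficient`:
#'   scalar mean.
#' @export
nodal_clustering <- function(g) {
  a <- as_adjacency(g)
  an <- a * 1.0
  k <- rowSums(an)
  tri <- diag(an %*% an %*% an)
  cp <- ifelse(k < 2, 0, tri / (k * (k - 1)))
  names(cp) <- rownames(a)
  cp
}

#' @rdname nodal_clustering
#' @export
clustering_coefficient <- function(g) mean(nodal_clustering(g))

#' Local efficiency
#'
#' Per node, the global efficiency of the subgraph induced by its
#' neighbours (the node itself excluded); degree < 2 gives 0. The graph
#' value is the mean over nodes.
#'
#' @inheritParams characteristic_path_length
#' @return `nodal_local_efficiency`: numeric vector; `local_efficiency`:
#'   scalar mean.
#' @export
nodal_local_efficiency <- function(g) {
  a <- as_adjacency(g)
  e <- cpp_local_efficiency(a)
  names(e) <- rownames(a)
  e
}

#' @rdname nodal_local_efficiency
#' @export
local_efficiency <- function(g) mean(nodal_local_efficiency(g))

#' Betweenness centrality
#'
#' Exact shortest-path betweenness (Brandes' algorithm),
#' `sum over s != v != t of sigma_st(v) / sigma_st`, unnormalized by
#' default; `normalized = TRUE` divides by `(N-1)(N-2)/2`. The hub rule
#' (BC above mean + SD) is invariant to this choice.
#'
#' @inheritParams characteristic_path_length
#' @param normalized divide by the number of possible intermediary pairs.
#' @return numeric vector of centralities, `>= 0`.
#' @export
betweenness_centrality <- function(g, normalized = FALSE) {
  a <- as_adjacency(g)
  bc <- cpp_betweenness(a)
  if (normalized) {
    n <- nrow(a)
    if (n > 2) bc <- bc * 2 / ((n - 1) * (n - 2))
  }
  names(bc) <- rownames(a)
  bc
}

#' Global graph parameters
#'
#' @inheritParams characteristic_path_length
#' @return named vector `c(L, C, GlobE, LocE)`.
#' @export
global_metrics <- function(g) {
  c(L = as.numeric(characteristic_path_length(g)),
    C = clustering_coefficient(g),
    GlobE = global_efficiency(g),
    LocE = local_efficiency(g))
}

#' Nodal graph parameters
#'
#' @inheritParams characteristic_path_length
#' @return data frame with columns `region`, `Lp`, `Cp`, `Eglob`, `Eloc`,
#'   `BC`.
#' @export
nodal_metrics <- function(g) {
  a <- as_adjacency(g)
  data.frame(region = if (is.null(rownames(a)))
               sprintf("region%03d", seq_len(nrow(a))) else rownames(a),
             Lp = unname(nodal_path_length(a)),
             Cp = unname(nodal_clustering(a)),
             Eglob = unname(nodal_global_efficiency(a)),
             Eloc = unname(nodal_local_efficiency(a)),
             BC = unname(betweenness_centrality(a)),
             stringsAsFactors = FALSE)
}

# Registry used by sweeps and permutation tests.
global_metric_fun <- function(metric) {
  switch(metric,
         L = function(a) as.numeric(characteristic_path_length(a)),
         C = clustering_coefficient,
         GlobE = global_efficiency,
         LocE = local_efficiency,
         stop("unknown global metric '", metric, "'", call. = FALSE))
}

nodal_metric_fun <- function(metric) {
  switch(metric,
         Lp = nodal_path_length,
         Cp = nodal_clustering,
         Eglob = nodal_global_efficiency,
         Eloc = nodal_local_efficiency,
         BC = betweenness_centrality,
         stop("unknown nodal metric '", metric, "'", call. = FALSE))
}
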