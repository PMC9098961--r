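# Brute-force graph oracles, independent of the package's compiled code.
# All operate on plain 0/1 adjacency matrices and are only meant for tiny
# graphs (exhaustive enumeration).

# Hop distances by successive adjacency powers: d(i,j) is the smallest k
# with (A^k)[i,j] > 0.
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reach <- diag(n) > 0
  p <- diag(n)
  for (k in seq_len(n)) {
    p <- (p %*% a) > 0
    new <- p & !reach
    d[new] <- k
    reach <- reach | p
  }
  d
}

oracle_char_path <- function(a) {
  d <- oracle_distances(a)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

oracle_global_eff <- function(a) {
  d <- oracle_distances(a)
  inv <- 1 / d
  diag(inv) <- 0
  n <- nrow(a)
  sum(inv) / (n * (n - 1))
}

# Clustering by triple loop over neighbour pairs.
oracle_clustering <- function(a) {
  n <- nrow(a)
  cp <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    t <- 0
    for (u in seq_len(k - 1)) for (v in (u + 1):k)
      t <- t + a[nb[u], nb[v]]
    cp[i] <- 2 * t / (k * (k - 1))
  }
  cp
}

oracle_local_eff <- function(a) {
  n <- nrow(a)
  e <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2) next
    e[i] <- oracle_global_eff(a[nb, nb, drop = FALSE])
  }
  e
}

# Betweenness by exhaustive enumeration of all shortest paths: DFS from s
# restricted to edges that advance along shortest paths towards t.
oracle_betweenness <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  bc <- numeric(n)
  paths_through <- function(s, t) {
    found <- list()
    walk <- function(v, path) {
      if (v == t) {
        found[[length(found) + 1]] <<- path
        return(invisible())
      }
      for (w in which(a[v, ] == 1))
        if (is.finite(d[w, t]) && d[s, w] == d[s, v] + 1 &&
            d[s, w] + d[w, t] == d[s, t])
          walk(w, c(path, w))
    }
    walk(s, s)
    found
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t]) || d[s, t] < 2) next
    ps <- paths_through(s, t)
    for (p in ps) {
      interior <- p[-c(1, length(p))]
      bc[interior] <- bc[interior] + 1 / length(ps)
    }
  }
  bc
}

# Small named graphs used across tests.
adj_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- 1L
    a[e[2], e[1]] <- 1L
  }
  a
}
complete_graph <- function(n) {
  a <- matrix(1L, n, n)
  diag(a) <- 0L
  a
}
path_graph <- function(n) adj_from_edges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
ring_graph <- function(n) {
  a <- path_graph(n)
  a[1, n] <- a[n, 1] <- 1L
  a
}
star_graph <- function(n_leaves) adj_from_edges(n_leaves + 1,
                                                lapply(seq_len(n_leaves) + 1, function(i) c(1, i)))

# Symmetric random 0/1 adjacency.
random_adjacency <- function(n, p = 0.4) {
  a <- matrix(rbinom(n * n, 1, p), n, n)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  diag(a) <- 0L
  storage.mode(a) <- "integer"
  a
}

# Small two-group dataset used by several suites.
small_dataset <- function(n_regions = 20, n_per_group = 8, seed = 3,
                          n_modules = 4, ...) {
  simulate_dataset(synth_spec(
    n_regions = n_regions, n_per_group = n_per_group,
    base_network = planted_modular_network(n_regions, n_modules),
    seed = seed, ...))
}
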