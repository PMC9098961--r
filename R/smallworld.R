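#' Degree-preserving random null graphs
#'
#' Maslov–Sneppen double-edge-swap rewiring: each null keeps the exact
#' degree sequence of the input while randomizing its topology; self-loops
#' and multi-edges are never created. If too few swaps can be realized
#' (e.g. a star graph has no swappable pair), a warning is emitted and the
#' realized swap count is recorded on each null.
#'
#' @param g a [binary_graph()] or 0/1 adjacency matrix.
#' @param n_null number of null graphs.
#' @param n_rewires_per_edge swap attempts per edge (default 10).
#' @param seed optional RNG seed.
#' @return list of [binary_graph()]s, each with attribute `n_swaps`.
#' @export
random_null_graphs <- function(g, n_null = 100, n_rewires_per_edge = 10,
                               seed = NULL) {
  a <- as_adjacency(g)
  if (!is.null(seed)) set.seed(seed)
  if (n_null == 0) return(list())
  n_edges <- sum(a) / 2
  attempts <- max(1L, as.integer(round(n_rewires_per_edge * n_edges)))
  regions <- if (inherits(g, "binary_graph")) g$regions else rownames(a)
  out <- vector("list", n_null)
  few <- FALSE
  for (i in seq_len(n_null)) {
    rw <- cpp_rewire(a, attempts)
    if (rw$n_swaps < n_edges) few <- TRUE
    bg <- binary_graph(rw$adjacency, regions = regions,
                       threshold = list(type = "rewired_null"))
    attr(bg, "n_swaps") <- rw$n_swaps
    out[[i]] <- bg
  }
  if (few)
    warning("fewer effective swaps than edges in at least one null; ",
            "graph admits limited rewiring", call. = FALSE)
  out
}

#' Small-world indices
#'
#' gamma = C / mean C of degree-preserving nulls, lambda = L / mean null L,
#' sigma = gamma / lambda. A small-world graph shows gamma >> 1, lambda
#' close to 1, hence sigma > 1.
#'
#' @inheritParams random_null_graphs
#' @param warn warn when the largest connected component covers < 90% of
#'   nodes.
#' @return object of class `small_world` with fields `gamma`, `lambda`,
#'   `sigma`, `C`, `L`, `C_rand`, `L_rand`, `n_null`.
#' @export
small_world <- function(g, n_null = 100, n_rewires_per_edge = 10,
                        seed = NULL, warn = TRUE) {
  a <- as_adjacency(g)
  d <- cpp_bfs_distances(a)
  comp_frac <- max(rowSums(is.finite(d))) / nrow(a)
  if (warn && comp_frac < 0.9)
    warning(sprintf("largest component covers only %.0f%% of nodes",
                    100 * comp_frac), call. = FALSE)
  c_obs <- clustering_coefficient(a)
  l_obs <- as.numeric(characteristic_path_length(a))
  nulls <- random_null_graphs(a, n_null = n_null,
                              n_rewires_per_edge = n_rewires_per_edge,
                              seed = seed)
  c_rand <- vapply(nulls, function(x) clustering_coefficient(x$adjacency), 0)
  l_rand <- vapply(nulls, function(x)
    as.numeric(characteristic_path_length(x$adjacency)), 0)
  if (mean(c_rand) == 0 || mean(l_rand) == 0)
    stop("null graphs have zero mean clustering or path length", call. = FALSE)
  gamma <- c_obs / mean(c_rand)
  lambda <- l_obs / mean(l_rand)
  structure(list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
                 C = c_obs, L = l_obs,
                 C_rand = mean(c_rand), L_rand = mean(l_rand),
                 n_null = n_null),
            class = "small_world")
}

#' @export
print.small_world <- function(x, ...) {
  cat(sprintf("Small-world indices (%d nulls): gamma = %.3f, lambda = %.3f, sigma = %.3f\n",
              x$n_null, x$gamma, x$lambda, x$sigma))
  cat(sprintf("  C = %.3f (null %.3f), L = %.3f (null %.3f)\n",
              x$C, x$C_rand, x$L, x$L_rand))
  invisible(x)
}

#' Small-world sweep over the sparsity grid
#'
#' gamma, lambda and sigma at every sparsity, each against its own set of
#' degree-preserving nulls, plus grid means — the per-group small-world
#' profile of the covariance network.
#'
#' @param net a [covariance_network()] or weight matrix.
#' @param grid a [sparsity_grid()].
#' @param n_null nulls per sparsity point.
#' @param n_rewires_per_edge swap attempts per edge.
#' @param seed RNG seed for the whole sweep.
#' @param negative negative-correlation handling.
#' @return object of class `small_world_sweep`: `values` (data frame with
#'   sparsity, gamma, lambda, sigma) and `mean_sigma`, `mean_gamma`,
#'   `mean_lambda`.
#' @export
small_world_sweep <- function(net, grid = sparsity_grid(), n_null = 100,
                              n_rewires_per_edge = 10, seed = NULL,
                              negative = c("zero", "absolute")) {
  negative <- match.arg(negative)
  if (!is.null(seed)) set.seed(seed)
  w <- if (inherits(net, "covariance_network")) net$r else net
  res <- sweep_apply(w, grid, function(a) {
    sw <- small_world(a, n_null = n_null,
                      n_rewires_per_edge = n_rewires_per_edge,
                      seed = NULL, warn = FALSE)
    c(gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma)
  }, negative)
  m <- do.call(rbind, res)
  values <- data.frame(sparsity = as.numeric(grid), m)
  structure(list(values = values,
                 mean_gamma = mean(m[, "gamma"]),
                 mean_lambda = mean(m[, "lambda"]),
                 mean_sigma = mean(m[, "sigma"]),
                 n_null = n_null,
                 group = if (inherits(net, "covariance_network")) net$group),
            class = "small_world_sweep")
}

#' @export
print.small_world_sweep <- function(x, ...) {
  cat("Small-world sweep", if (!is.null(x$group)) paste0(" [", x$group, "]"),
      ": ", nrow(x$values), " sparsity points, ", x$n_null,
      " nulls each\n", sep = "")
  cat(sprintf("  grid means: gamma = %.3f, lambda = %.3f, sigma = %.3f\n",
              x$mean_gamma, x$mean_lambda, x$mean_sigma))
  invisible(x)
}
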