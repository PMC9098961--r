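#' Trapezoidal area under a curve
#'
#' @param x strictly increasing abscissae (sparsity values).
#' @param y metric values at `x`.
#' @return trapezoidal integral of `y` over `x`.
#' @export
auc_trapezoid <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2, all(diff(x) > 0))
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Evaluate `fun(adjacency)` at every sparsity of `grid`, growing the graph
# incrementally along the shared edge ranking (nested thresholds). Used by
# every sweep and inside permutation loops.
sweep_apply <- function(w, grid, fun, negative = "zero") {
  w <- edge_weights(w, negative)
  n <- ncol(w)
  n_possible <- n * (n - 1) / 2
  ut <- which(upper.tri(w), arr.ind = TRUE)
  ord <- order(-w[upper.tri(w)], ut[, 1], ut[, 2])
  counts <- floor(grid * n_possible)
  if (counts[1] < 1)
    stop("lowest sparsity yields zero edges on ", n, " nodes", call. = FALSE)
  a <- matrix(0L, n, n)
  prev <- 0L
  out <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    e <- counts[i]
    if (e > prev) {
      pick <- ut[ord[(prev + 1L):e], , drop = FALSE]
      a[pick] <- 1L
      a[pick[, 2:1, drop = FALSE]] <- 1L
      prev <- e
    }
    out[[i]] <- fun(a)
  }
  out
}

#' Metric sweep over a sparsity grid
#'
#' Evaluates global graph parameters on the binarized network at every
#' sparsity of the grid and summarizes each metric by its trapezoidal AUC
#' over the sparsity axis — the threshold-independent quantity used for
#' group comparison.
#'
#' @param net a [covariance_network()] or weight matrix.
#' @param grid a [sparsity_grid()].
#' @param metrics subset of `c("L", "C", "GlobE", "LocE")`.
#' @param negative negative-correlation handling (see
#'   [threshold_by_sparsity()]).
#' @return object of class `metric_sweep`: `values` (long data frame:
#'   `sparsity`, `metric`, `value`), `auc` (named vector), `group`.
#' @examples
#' ds <- simulate_dataset(synth_spec(n_regions = 20, n_per_group = 8,
#'   base_network = planted_modular_network(20, 4), seed = 3))
#' sw <- metric_sweep(covariance_network(ds$table, "g1"),
#'                    sparsity_grid(0.1, 0.5, 0.1))
#' sw$auc
#' @export
metric_sweep <- function(net, grid = sparsity_grid(),
                         metrics = c("L", "C", "GlobE", "LocE"),
                         negative = c("zero", "absolute")) {
  negative <- match.arg(negative)
  funs <- lapply(metrics, global_metric_fun)
  res <- sweep_apply(if (inherits(net, "covariance_network")) net$r else net,
                     grid, function(a) vapply(funs, function(f) f(a), 0),
                     negative)
  m <- do.call(rbind, res)
  colnames(m) <- metrics
  values <- data.frame(sparsity = rep(as.numeric(grid), length(metrics)),
                       metric = rep(metrics, each = length(grid)),
                       value = as.vector(m), stringsAsFactors = FALSE)
  auc <- vapply(metrics, function(k) auc_trapezoid(as.numeric(grid), m[, k]), 0)
  structure(list(values = values, auc = auc, grid = as.numeric(grid),
                 group = if (inherits(net, "covariance_network")) net$group),
            class = "metric_sweep")
}

#' @export
print.metric_sweep <- function(x, ...) {
  cat("Metric sweep", if (!is.null(x$group)) paste0(" [", x$group, "]"),
      ": ", length(x$grid), " sparsity points in [",
      min(x$grid), ", ", max(x$grid), "]\n", sep = "")
  cat("AUC:\n")
  print(round(x$auc, 4))
  invisible(x)
}

#' @export
plot.metric_sweep <- function(x, ...) {
  mets <- unique(x$values$metric)
  op <- graphics::par(mfrow = c(1, length(mets)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (m in mets) {
    v <- x$values[x$values$metric == m, ]
    plot(v$sparsity, v$value, type = "l", xlab = "sparsity", ylab = m,
         main = sprintf("%s (AUC %.3f)", m, x$auc[[m]]), ...)
  }
  invisible(x)
}

#' Nodal metric sweep
#'
#' One nodal metric evaluated across the sparsity grid, with a per-region
#' AUC — the per-region summary compared between groups and the basis of
#' hub detection (for `BC`).
#'
#' @inheritParams metric_sweep
#' @param metric one of `"Lp"`, `"Cp"`, `"Eglob"`, `"Eloc"`, `"BC"`.
#' @return list with `values` (sparsity x region matrix) and `auc` (named
#'   per-region vector).
#' @export
nodal_metric_sweep <- function(net, grid = sparsity_grid(), metric = "BC",
                               negative = c("zero", "absolute")) {
  negative <- match.arg(negative)
  fun <- nodal_metric_fun(metric)
  w <- if (inherits(net, "covariance_network")) net$r else net
  res <- sweep_apply(w, grid, fun, negative)
  m <- do.call(rbind, res)
  colnames(m) <- net_regions(net)
  rownames(m) <- as.numeric(grid)
  auc <- apply(m, 2, function(y) auc_trapezoid(as.numeric(grid), y))
  list(values = m, auc = auc, metric = metric, grid = as.numeric(grid))
}
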