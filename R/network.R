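#' Pearson correlation coefficient
#'
#' Direct implementation of the product-moment formula
#' \deqn{r = \frac{\sum_i (x_i - \bar x)(y_i - \bar y)}{
#'   \sqrt{\sum_i (x_i - \bar x)^2 \sum_i (y_i - \bar y)^2}}}
#' the edge weight of the metabolic covariance network (x and y are one
#' region's intensities across the subjects of a group).
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  dx <- x - mean(x)
  dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) stop("correlation undefined: zero variance input", call. = FALSE)
  r <- sum(dx * dy) / den
  min(1, max(-1, r))
}

#' Group-level metabolic covariance network
#'
#' Correlates every pair of regions across the subjects of one group,
#' producing the symmetric inter-regional correlation matrix that defines
#' the group's metabolic network. Self-connections are excluded (diagonal
#' forced to 0).
#'
#' @param table an [intensity_table()], or a plain subjects x regions matrix.
#' @param group group label to subset to (required for a multi-group table).
#' @return object of class `covariance_network` with fields `r` (the
#'   correlation matrix, zero diagonal), `regions`, `n_subjects`, `group`.
#' @examples
#' ds <- simulate_dataset(synth_spec(n_regions = 20, n_per_group = 8,
#'   base_network = planted_modular_network(20, 4), seed = 3))
#' net <- covariance_network(ds$table, "g1")
#' net
#' @export
covariance_network <- function(table, group = NULL) {
  if (inherits(table, "intensity_table")) {
    if (is.null(group) && length(unique(table$group)) > 1)
      stop("table holds several groups; specify `group`", call. = FALSE)
    m <- intensity_matrix(table, group = group)
  } else {
    m <- as.matrix(table)
    if (is.null(colnames(m))) colnames(m) <- sprintf("region%03d", seq_len(ncol(m)))
  }
  if (nrow(m) < 3)
    stop("need at least 3 subjects to correlate (got ", nrow(m), ")", call. = FALSE)
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    stop("zero variance in region(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  r <- cor(m)
  diag(r) <- 0
  structure(list(r = r, regions = colnames(m), n_subjects = nrow(m),
                 group = group),
            class = "covariance_network")
}

#' @export
print.covariance_network <- function(x, ...) {
  cat("Metabolic covariance network", if (!is.null(x$group)) paste0(" [", x$group, "]"),
      ": ", length(x$regions), " regions, n = ", x$n_subjects, " subjects\n", sep = "")
  ut <- x$r[upper.tri(x$r)]
  cat(sprintf("  r: median %.3f, range [%.3f, %.3f], %d pairs with r > 0.5\n",
              median(ut), min(ut), max(ut), sum(ut > 0.5)))
  invisible(x)
}

#' @export
summary.covariance_network <- function(object, ...) {
  ut <- object$r[upper.tri(object$r)]
  out <- list(n_regions = length(object$regions), n_subjects = object$n_subjects,
              group = object$group, r_quantiles = quantile(ut),
              prop_negative = mean(ut < 0))
  class(out) <- "summary.covariance_network"
  out
}

#' @export
print.summary.covariance_network <- function(x, ...) {
  cat("Covariance network: ", x$n_regions, " regions, n = ", x$n_subjects, "\n", sep = "")
  print(round(x$r_quantiles, 3))
  cat(sprintf("Negative correlations: %.1f%% of pairs\n", 100 * x$prop_negative))
  invisible(x)
}

#' @export
plot.covariance_network <- function(x, ...) {
  n <- length(x$regions)
  image(1:n, 1:n, t(x$r[n:1, ]), axes = FALSE, xlab = "", ylab = "",
        zlim = c(-1, 1), main = paste("Covariance network", x$group), ...)
  invisible(x)
}

# Weight matrix used for edge ranking; negative correlations are either
# zeroed (default convention) or folded in by absolute value.
edge_weights <- function(net, negative = c("zero", "absolute")) {
  negative <- match.arg(negative)
  w <- if (inherits(net, "covariance_network")) net$r else as.matrix(net)
  diag(w) <- 0
  if (negative == "zero") pmax(w, 0) else abs(w)
}

net_regions <- function(net) {
  if (inherits(net, c("covariance_network", "binary_graph"))) net$regions
  else if (!is.null(colnames(net))) colnames(net)
  else sprintf("region%03d", seq_len(ncol(net)))
}

#' Binary graph
#'
#' Adjacency matrix produced by thresholding a covariance network, together
#' with its threshold descriptor.
#'
#' @param adjacency symmetric 0/1 matrix, zero diagonal.
#' @param regions region names.
#' @param threshold list describing how the graph was obtained.
#' @return object of class `binary_graph`.
#' @export
binary_graph <- function(adjacency, regions = colnames(adjacency),
                         threshold = list(type = "manual")) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "integer"
  if (!identical(adjacency, t(adjacency)) || any(diag(adjacency) != 0) ||
      !all(adjacency %in% c(0L, 1L)))
    stop("adjacency must be symmetric 0/1 with zero diagonal", call. = FALSE)
  if (is.null(regions)) regions <- sprintf("region%03d", seq_len(ncol(adjacency)))
  dimnames(adjacency) <- list(regions, regions)
  structure(list(adjacency = adjacency, regions = regions,
                 threshold = threshold, n_edges = sum(adjacency) / 2L),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  n <- length(x$regions)
  cat("Binary graph: ", n, " nodes, ", x$n_edges, " edges (density ",
      sprintf("%.3f", x$n_edges / (n * (n - 1) / 2)), ")\n", sep = "")
  thr <- x$threshold
  cat("  threshold: ", thr$type,
      if (!is.null(thr$value)) sprintf(" = %g", thr$value), "\n", sep = "")
  invisible(x)
}

#' Sparsity thresholding
#'
#' Keeps the `floor(sparsity * N(N-1)/2)` strongest edges of the network's
#' ranked weights, giving graphs of identical edge count across groups.
#' Ties at the cut are broken deterministically in lexicographic (row,
#' column) order. Negative correlations are zeroed before ranking by
#' default (`negative = "zero"`); `"absolute"` ranks by `|r|`.
#'
#' @param net a [covariance_network()] or weight matrix.
#' @param sparsity proportion of possible edges to retain, in (0, 1).
#' @param negative handling of negative correlations.
#' @return a [binary_graph()] with exactly the implied edge count.
#' @export
threshold_by_sparsity <- function(net, sparsity, negative = c("zero", "absolute")) {
  if (sparsity <= 0 || sparsity >= 1) stop("sparsity must be in (0, 1)", call. = FALSE)
  w <- edge_weights(net, negative)
  n <- ncol(w)
  n_possible <- n * (n - 1) / 2
  n_edges <- floor(sparsity * n_possible)
  if (n_edges < 1)
    stop("sparsity ", sparsity, " yields zero edges on ", n, " nodes", call. = FALSE)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  ord <- order(-w[upper.tri(w)], ut[, 1], ut[, 2])
  pick <- ut[ord[seq_len(n_edges)], , drop = FALSE]
  a <- matrix(0L, n, n)
  a[pick] <- 1L
  a <- a + t(a)
  binary_graph(a, regions = net_regions(net),
               threshold = list(type = "sparsity", value = sparsity,
                                negative = match.arg(negative)))
}

#' Absolute correlation thresholding
#'
#' Edge present iff the correlation strictly exceeds `r_min` —
#' the convention used for the hemispheric
#' connectivity maps (`r_min = 0.5`).
#'
#' @param net a [covariance_network()] or weight matrix.
#' @param r_min correlation cutoff in `[0, 1)`.
#' @return a [binary_graph()].
#' @export
threshold_by_r <- function(net, r_min = 0.5) {
  if (r_min < 0 || r_min >= 1) stop("r_min must be in [0, 1)", call. = FALSE)
  w <- if (inherits(net, "covariance_network")) net$r else as.matrix(net)
  diag(w) <- 0
  a <- (w > r_min) * 1L
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  binary_graph(a, regions = net_regions(net),
               threshold = list(type = "r", value = r_min))
}

#' Sparsity grid
#'
#' The default sweep covers 5% to 50% of possible edges in 1% steps.
#'
#' @param from,to,by grid limits and step, proportions in (0, 1).
#' @return strictly increasing numeric vector of class `sparsity_grid`.
#' @export
sparsity_grid <- function(from = 0.05, to = 0.50, by = 0.01) {
  g <- seq(from, to, by = by)
  if (any(g <= 0) || any(g >= 1) || any(diff(g) <= 0))
    stop("sparsity grid must be strictly increasing within (0, 1)", call. = FALSE)
  structure(g, class = c("sparsity_grid", "numeric"))
}

#' Write a network or graph as a square CSV matrix
#'
#' @param x a [covariance_network()] or [binary_graph()].
#' @param path output CSV.
#' @export
write_network_csv <- function(x, path) {
  m <- if (inherits(x, "covariance_network")) x$r else x$adjacency
  df <- data.frame(region = net_regions(x), m, check.names = FALSE)
  colnames(df) <- c("region", net_regions(x))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a square network CSV back
#'
#' @param path CSV written by [write_network_csv()].
#' @return matrix with region dimnames.
#' @export
read_network_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$region
  m
}

#' Write an edge list TSV (region_a, region_b, r)
#'
#' @param net a [covariance_network()] (weights) or [binary_graph()] (edges).
#' @param path output TSV.
#' @export
write_edge_list <- function(net, path) {
  if (inherits(net, "binary_graph")) {
    m <- net$adjacency
    idx <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
    df <- data.frame(region_a = net$regions[idx[, 1]],
                     region_b = net$regions[idx[, 2]], r = 1)
  } else {
    m <- net$r
    idx <- which(upper.tri(m), arr.ind = TRUE)
    df <- data.frame(region_a = net$regions[idx[, 1]],
                     region_b = net$regions[idx[, 2]],
                     r = m[idx])
  }
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
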