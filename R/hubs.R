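#' Hub detection by the mean + SD betweenness rule
#'
#' A region is a hub when its betweenness centrality strictly exceeds the
#' group mean plus one (sample) standard deviation of the centrality
#' values. A constant centrality vector yields zero hubs (SD = 0, strict
#' inequality) with a warning. The rule is invariant to any positive
#' rescaling of BC, so normalized and raw centralities give the same hubs.
#'
#' @param bc numeric vector of betweenness centralities (named by region,
#'   or supply `regions`).
#' @param regions region names.
#' @param group optional group label carried through to the result.
#' @return data frame of class `hub_set`: `region`, `bc`, `threshold`,
#'   `is_hub`; attributes `group` and `threshold`.
#' @export
detect_hubs <- function(bc, regions = names(bc), group = NULL) {
  bc <- as.numeric(bc)
  if (length(bc) < 2 || any(!is.finite(bc)))
    stop("need >= 2 finite centrality values", call. = FALSE)
  if (is.null(regions)) regions <- sprintf("region%03d", seq_along(bc))
  thr <- mean(bc) + sd(bc)
  if (sd(bc) == 0)
    warning("constant centrality vector: no hubs detectable", call. = FALSE)
  out <- data.frame(region = regions, bc = bc, threshold = thr,
                    is_hub = bc > thr, stringsAsFactors = FALSE)
  if (!is.null(group)) out$group <- group
  attr(out, "group") <- group
  attr(out, "threshold") <- thr
  class(out) <- c("hub_set", "data.frame")
  out
}

#' @export
print.hub_set <- function(x, ...) {
  cat("Hub set", if (!is.null(attr(x, "group"))) paste0(" [", attr(x, "group"), "]"),
      ": ", sum(x$is_hub), " hubs of ", nrow(x),
      sprintf(" regions (BC > %.3f)\n", attr(x, "threshold")), sep = "")
  if (any(x$is_hub)) {
    h <- x[x$is_hub, ]
    h <- h[order(-h$bc), ]
    cat(paste(sprintf("  %s (BC = %.2f)", h$region, h$bc), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Group hub analysis over the sparsity sweep
#'
#' Betweenness centrality is integrated (trapezoidal AUC) over the
#' sparsity grid per region, giving a single threshold-independent
#' centrality per region, and hubs are flagged by the mean + SD rule.
#'
#' @param net a [covariance_network()].
#' @param grid a [sparsity_grid()].
#' @param negative negative-correlation handling.
#' @return a [detect_hubs()] result based on the BC AUC.
#' @export
hub_analysis <- function(net, grid = sparsity_grid(),
                         negative = c("zero", "absolute")) {
  sw <- nodal_metric_sweep(net, grid, metric = "BC",
                           negative = match.arg(negative))
  detect_hubs(sw$auc, regions = net_regions(net),
              group = if (inherits(net, "covariance_network")) net$group)
}

#' Hemisphere assignment from region names
#'
#' @param regions region names with `.L`/`.R` (or `_L`/`_R`) suffixes.
#' @param mode `"suffix"` or `"parity"` (odd position = L).
#' @return character vector of `"L"`/`"R"`.
#' @export
hemisphere_of <- function(regions, mode = c("suffix", "parity")) {
  mode <- match.arg(mode)
  if (mode == "suffix") {
    h <- hemisphere_from_name(regions)
    if (anyNA(h))
      stop("region(s) without L/R assignment: ",
           paste(regions[is.na(h)], collapse = ", "), call. = FALSE)
    h
  } else {
    ifelse(seq_along(regions) %% 2 == 1, "L", "R")
  }
}

#' Split a covariance network into hemispheres
#'
#' Restricts the correlation matrix to intra-hemispheric entries, yielding
#' one network per hemisphere (45 nodes each for the default 90-region
#' atlas); inter-hemispheric entries are discarded.
#'
#' @param net a [covariance_network()].
#' @param hemispheres optional `"L"`/`"R"` vector per region; default
#'   derived from the region-name suffixes.
#' @return list with elements `L` and `R`, each a `covariance_network`.
#' @export
split_hemispheres <- function(net, hemispheres = NULL) {
  stopifnot(inherits(net, "covariance_network"))
  if (is.null(hemispheres)) hemispheres <- hemisphere_of(net$regions)
  stopifnot(length(hemispheres) == length(net$regions))
  out <- lapply(c(L = "L", R = "R"), function(h) {
    keep <- hemispheres == h
    structure(list(r = net$r[keep, keep, drop = FALSE],
                   regions = net$regions[keep],
                   n_subjects = net$n_subjects,
                   group = net$group),
              class = "covariance_network")
  })
  out
}

#' Hemispheric connectivity at an absolute correlation threshold
#'
#' Binarizes each intra-hemispheric network at the strict rule r > r_min
#' (default 0.5, the conventional effective-connection cutoff) and reports
#' edge counts, optionally tallied by lobe.
#'
#' @param net a [covariance_network()] over both hemispheres.
#' @param r_min correlation cutoff (strict).
#' @param lobes optional named character vector (region -> lobe) for the
#'   lobe-grouped edge tallies; see [read_lobe_table()].
#' @param hemispheres optional hemisphere assignment per region.
#' @return object of class `hemisphere_report`: `graphs` (list `L`, `R` of
#'   [binary_graph()]), `edge_counts`, optional `lobe_edges` tables.
#' @export
hemisphere_connectivity <- function(net, r_min = 0.5, lobes = NULL,
                                    hemispheres = NULL) {
  halves <- split_hemispheres(net, hemispheres)
  graphs <- lapply(halves, threshold_by_r, r_min = r_min)
  counts <- vapply(graphs, function(g) g$n_edges, 0)
  lobe_edges <- NULL
  if (!is.null(lobes)) {
    lobe_edges <- lapply(graphs, function(g) {
      m <- g$adjacency
      idx <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
      la <- lobes[g$regions[idx[, 1]]]
      lb <- lobes[g$regions[idx[, 2]]]
      pair <- apply(cbind(la, lb), 1, function(z) paste(sort(z), collapse = "-"))
      table(pair)
    })
  }
  structure(list(graphs = graphs, edge_counts = counts, r_min = r_min,
                 lobe_edges = lobe_edges,
                 group = net$group),
            class = "hemisphere_report")
}

#' @export
print.hemisphere_report <- function(x, ...) {
  cat("Hemispheric connectivity at r > ", x$r_min,
      if (!is.null(x$group)) paste0(" [", x$group, "]"), "\n", sep = "")
  cat(sprintf("  left: %d edges on %d nodes; right: %d edges on %d nodes\n",
              x$edge_counts[["L"]], length(x$graphs$L$regions),
              x$edge_counts[["R"]], length(x$graphs$R$regions)))
  invisible(x)
}

#' Read a region -> lobe metadata table
#'
#' Editable TSV with columns `region` and `lobe` used to group hemispheric
#' edges by lobe. A template for the synthetic 90-region parcellation ships
#' in `inst/extdata/toy_region_lobes.tsv`.
#'
#' @param path TSV path; default the packaged template.
#' @return named character vector (region -> lobe).
#' @export
read_lobe_table <- function(path = system.file("extdata", "toy_region_lobes.tsv",
                                               package = "mcnet")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(df$lobe, df$region)
}

#' Left-right asymmetry of hemispheric network parameters
#'
#' For one group, the observed left-minus-right difference in the AUC of
#' each global metric over the sparsity grid, computed on the
#' intra-hemispheric networks. Because both hemispheres come from the same
#' subjects, inference uses a subject bootstrap: subjects are resampled
#' with replacement, both hemispheric networks rebuilt per resample, and a
#' two-sided add-one p-value is taken from the sign distribution of the
#' bootstrap differences.
#'
#' @param table an [intensity_table()].
#' @param group group label to analyse.
#' @param grid a [sparsity_grid()].
#' @param metrics global metrics to compare.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @param hemispheres optional hemisphere assignment per region.
#' @param negative negative-correlation handling.
#' @return data frame of class `hemisphere_test`: `metric`,
#'   `auc_left`, `auc_right`, `observed_diff`, `p`.
#' @export
compare_hemispheres <- function(table, group = NULL, grid = sparsity_grid(),
                                metrics = c("C", "GlobE", "LocE", "L"),
                                n_boot = 1000, seed = NULL,
                                hemispheres = NULL,
                                negative = c("zero", "absolute")) {
  negative <- match.arg(negative)
  x <- intensity_matrix(table, group = group)
  if (is.null(hemispheres)) hemispheres <- hemisphere_of(colnames(x))
  iL <- hemispheres == "L"
  iR <- hemispheres == "R"
  funs <- lapply(metrics, global_metric_fun)
  hemi_aucs <- function(xx) {
    if (any(apply(xx, 2, sd) == 0)) return(NULL)
    r <- cor(xx)
    diag(r) <- 0
    sapply(list(r[iL, iL], r[iR, iR]), function(rr)
      vapply(seq_along(funs), function(k)
        auc_trapezoid(as.numeric(grid),
                      unlist(sweep_apply(rr, grid, funs[[k]], negative))), 0))
  }
  obs <- hemi_aucs(x)
  if (is.null(obs)) stop("zero-variance region in the input", call. = FALSE)
  observed <- obs[, 1] - obs[, 2]
  if (!is.null(seed)) set.seed(seed)
  boot <- matrix(0, n_boot, length(metrics))
  b <- 1L
  n_degenerate <- 0L
  while (b <= n_boot) {
    res <- hemi_aucs(x[sample.int(nrow(x), replace = TRUE), , drop = FALSE])
    if (is.null(res)) {
      n_degenerate <- n_degenerate + 1L
      if (n_degenerate > 100 * n_boot)
        stop("too many degenerate resamples", call. = FALSE)
      next
    }
    boot[b, ] <- res[, 1] - res[, 2]
    b <- b + 1L
  }
  pvals <- vapply(seq_along(metrics), function(k) {
    lo <- (sum(boot[, k] <= 0) + 1) / (n_boot + 1)
    hi <- (sum(boot[, k] >= 0) + 1) / (n_boot + 1)
    min(1, 2 * min(lo, hi))
  }, 0)
  out <- data.frame(metric = metrics, auc_left = obs[, 1],
                    auc_right = obs[, 2], observed_diff = observed,
                    p = pvals, stringsAsFactors = FALSE)
  attr(out, "n_boot") <- n_boot
  attr(out, "group") <- group
  class(out) <- c("hemisphere_test", "data.frame")
  out
}

#' @export
print.hemisphere_test <- function(x, ...) {
  cat("Hemispheric asymmetry (subject bootstrap, n = ", attr(x, "n_boot"),
      ")", if (!is.null(attr(x, "group"))) paste0(" [", attr(x, "group"), "]"),
      "\n", sep = "")
  df <- as.data.frame(x)
  df$auc_left <- round(df$auc_left, 4)
  df$auc_right <- round(df$auc_right, 4)
  df$observed_diff <- round(df$observed_diff, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
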