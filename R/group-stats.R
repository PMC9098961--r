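#' Permute group labels
#'
#' Randomly reassigns subjects to the two groups, preserving the original
#' group sizes — the exchangeability move of the permutation test.
#'
#' @param table an [intensity_table()] with exactly two groups.
#' @param seed optional RNG seed.
#' @return the table with a permuted `group` column.
#' @export
permute_group_labels <- function(table, seed = NULL) {
  if (length(unique(table$group)) != 2)
    stop("permutation requires exactly two groups", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  out <- table
  out$group <- sample(table$group)
  out
}

# AUC of one global metric's sparsity sweep for a subjects-x-regions
# submatrix; NA signals a degenerate draw (a zero-variance region).
stat_global_auc <- function(x, grid, fun, negative) {
  if (any(apply(x, 2, sd) == 0)) return(NA_real_)
  r <- cor(x)
  diag(r) <- 0
  vals <- unlist(sweep_apply(r, grid, fun, negative))
  auc_trapezoid(as.numeric(grid), vals)
}

stat_nodal_auc <- function(x, grid, fun, negative) {
  if (any(apply(x, 2, sd) == 0)) return(NULL)
  r <- cor(x)
  diag(r) <- 0
  m <- do.call(rbind, sweep_apply(r, grid, fun, negative))
  apply(m, 2, function(y) auc_trapezoid(as.numeric(grid), y))
}

# Two-sided add-one permutation p-value (always > 0).
perm_pvalue <- function(observed, null) {
  (sum(abs(null) >= abs(observed)) + 1) / (length(null) + 1)
}

#' Permutation comparison of a global network parameter
#'
#' The group difference in the AUC of a global metric over the sparsity
#' grid is compared against its label-permutation null: every permutation
#' reassigns subjects to groups, rebuilds both covariance networks from
#' scratch, re-sweeps and re-integrates. Permutations producing a
#' zero-variance region are redrawn (their count is recorded). The
#' two-sided p-value uses the add-one estimator
#' `p = (#\{|null| >= |observed|\} + 1) / (n_perm + 1)`.
#'
#' @param table an [intensity_table()] with exactly two groups (each
#'   `n >= 3`).
#' @param grid a [sparsity_grid()].
#' @param metric one of `"L"`, `"C"`, `"GlobE"`, `"LocE"`.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param negative negative-correlation handling for thresholding.
#' @return object of class `perm_test` with `observed` (group1 - group2),
#'   `null`, `p`, `auc` per group, `n_degenerate`.
#' @export
compare_global <- function(table, grid = sparsity_grid(), metric = "GlobE",
                           n_perm = 1000, seed = NULL,
                           negative = c("zero", "absolute")) {
  negative <- match.arg(negative)
  groups <- unique(table$group)
  if (length(groups) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(table$group) < 3)) stop("each group needs >= 3 subjects", call. = FALSE)
  fun <- global_metric_fun(metric)
  x <- intensity_matrix(table)
  grp <- table$group
  i1 <- which(grp == groups[1])
  i2 <- which(grp == groups[2])
  a1 <- stat_global_auc(x[i1, , drop = FALSE], grid, fun, negative)
  a2 <- stat_global_auc(x[i2, , drop = FALSE], grid, fun, negative)
  if (is.na(a1) || is.na(a2))
    stop("zero-variance region in the observed groups", call. = FALSE)
  observed <- a1 - a2
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  n1 <- length(i1)
  null <- numeric(n_perm)
  n_degenerate <- 0L
  for (b in seq_len(n_perm)) {
    repeat {
      p <- sample.int(n)
      d <- stat_global_auc(x[p[seq_len(n1)], , drop = FALSE], grid, fun, negative) -
        stat_global_auc(x[p[(n1 + 1):n], , drop = FALSE], grid, fun, negative)
      if (!is.na(d)) break
      n_degenerate <- n_degenerate + 1L
      if (n_degenerate > 100 * n_perm)
        stop("too many degenerate permutations", call. = FALSE)
    }
    null[b] <- d
  }
  structure(list(metric = metric, scope = "global",
                 groups = groups, observed = observed,
                 auc = setNames(c(a1, a2), groups),
                 null = null, p = perm_pvalue(observed, null),
                 n_perm = n_perm, n_degenerate = n_degenerate),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test (", x$scope, "): ", x$metric, " AUC, ",
      x$groups[1], " - ", x$groups[2], "\n", sep = "")
  cat(sprintf("  observed difference = %.4f, p = %.4f (%d permutations)\n",
              x$observed, x$p, x$n_perm))
  if (x$n_degenerate > 0)
    cat("  degenerate permutations redrawn:", x$n_degenerate, "\n")
  invisible(x)
}

#' Benjamini-Hochberg FDR decisions
#'
#' Step-up rule at level `q`: flags hypotheses whose BH-adjusted p-value is
#' at most `q`.
#'
#' @param p vector of p-values.
#' @param q FDR level (default 0.05).
#' @return logical vector of rejections.
#' @export
fdr_significant <- function(p, q = 0.05) p.adjust(p, method = "BH") <= q

#' Permutation comparison of nodal parameters across regions
#'
#' Per region, the group difference in the AUC of a nodal metric over the
#' sparsity grid, with the same rebuild-everything permutation scheme as
#' [compare_global()] and Benjamini-Hochberg correction across regions.
#'
#' @inheritParams compare_global
#' @param metric one of `"Lp"`, `"Cp"`, `"Eglob"`, `"Eloc"`, `"BC"`.
#' @param q FDR level for the region-wise decisions.
#' @return data frame of class `nodal_perm_test`: `region`,
#'   `observed_diff`, `p`, `p_fdr`, `significant`.
#' @export
compare_nodal <- function(table, grid = sparsity_grid(), metric = "Eglob",
                          n_perm = 1000, seed = NULL, q = 0.05,
                          negative = c("zero", "absolute")) {
  negative <- match.arg(negative)
  groups <- unique(table$group)
  if (length(groups) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(table$group) < 3)) stop("each group needs >= 3 subjects", call. = FALSE)
  fun <- nodal_metric_fun(metric)
  x <- intensity_matrix(table)
  grp <- table$group
  i1 <- which(grp == groups[1])
  i2 <- which(grp == groups[2])
  s1 <- stat_nodal_auc(x[i1, , drop = FALSE], grid, fun, negative)
  s2 <- stat_nodal_auc(x[i2, , drop = FALSE], grid, fun, negative)
  if (is.null(s1) || is.null(s2))
    stop("zero-variance region in the observed groups", call. = FALSE)
  observed <- s1 - s2
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  n1 <- length(i1)
  null <- matrix(0, n_perm, ncol(x))
  n_degenerate <- 0L
  for (b in seq_len(n_perm)) {
    repeat {
      p <- sample.int(n)
      d1 <- stat_nodal_auc(x[p[seq_len(n1)], , drop = FALSE], grid, fun, negative)
      d2 <- stat_nodal_auc(x[p[(n1 + 1):n], , drop = FALSE], grid, fun, negative)
      if (!is.null(d1) && !is.null(d2)) break
      n_degenerate <- n_degenerate + 1L
      if (n_degenerate > 100 * n_perm)
        stop("too many degenerate permutations", call. = FALSE)
    }
    null[b, ] <- d1 - d2
  }
  pvals <- vapply(seq_along(observed),
                  function(j) perm_pvalue(observed[j], null[, j]), 0)
  out <- data.frame(region = colnames(x), metric = metric,
                    observed_diff = unname(observed), p = pvals,
                    p_fdr = p.adjust(pvals, method = "BH"),
                    significant = fdr_significant(pvals, q),
                    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm
  attr(out, "n_degenerate") <- n_degenerate
  attr(out, "q") <- q
  class(out) <- c("nodal_perm_test", "data.frame")
  out
}

#' @export
print.nodal_perm_test <- function(x, ...) {
  cat("Nodal permutation test: ", x$metric[1], " AUC, ",
      attr(x, "n_perm"), " permutations, BH FDR q = ", attr(x, "q"),
      "\n", sep = "")
  sig <- x$region[x$significant]
  cat("  significant regions: ", length(sig),
      if (length(sig)) paste0(" (", paste(head(sig, 8), collapse = ", "),
                              if (length(sig) > 8) ", ...", ")"),
      "\n", sep = "")
  invisible(x)
}
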