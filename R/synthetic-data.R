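#' Default region names
#'
#' For an even region count, names come in left/right pairs with `.L`/`.R`
#' suffixes interleaved in atlas-label order (odd labels left, even right),
#' mirroring the 90-region, 45-per-hemisphere whole-brain parcellation the
#' pipeline defaults to. Odd counts get plain names without hemisphere.
#'
#' @param n_regions number of regions.
#' @return character vector of length `n_regions`.
#' @export
default_region_names <- function(n_regions) {
  if (n_regions %% 2 == 0) {
    base <- sprintf("roi%03d", rep(seq_len(n_regions / 2), each = 2))
    paste0(base, c(".L", ".R"))
  } else {
    sprintf("roi%03d", seq_len(n_regions))
  }
}

#' Planted hub network
#'
#' Random simple graph with an exact degree sequence: nodes in `hubs` get
#' `hub_degree`, all others `background_degree`. Used as the edge skeleton of
#' a synthetic covariance structure with known hubs.
#'
#' @param n_regions node count.
#' @param hubs integer indices (1-based) of planted hub nodes; may be empty.
#' @param hub_degree degree of each hub; must exceed `background_degree`.
#' @param background_degree degree of every non-hub node.
#' @param seed optional RNG seed.
#' @return symmetric 0/1 matrix with zero diagonal and attribute `hubs`.
#' @export
planted_network <- function(n_regions, hubs = integer(0), hub_degree = NULL,
                            background_degree = 2, seed = NULL) {
  hubs <- as.integer(hubs)
  if (length(hubs) && (any(hubs < 1) || any(hubs > n_regions)))
    stop("hub indices out of range 1..", n_regions, call. = FALSE)
  deg <- rep(as.integer(background_degree), n_regions)
  if (length(hubs)) {
    if (is.null(hub_degree)) stop("hub_degree required when hubs are given", call. = FALSE)
    if (hub_degree <= background_degree)
      stop("hub_degree must exceed background_degree", call. = FALSE)
    deg[hubs] <- as.integer(hub_degree)
  }
  if (any(deg >= n_regions) || any(deg < 0) || sum(deg) %% 2 != 0 ||
      !igraph::is_graphical(deg))
    stop("infeasible degree sequence for a simple graph on ", n_regions,
         " nodes", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  g <- tryCatch(
    suppressWarnings(igraph::sample_degseq(deg, method = "vl")),
    error = function(e) igraph::sample_degseq(deg, method = "fast.heur.simple"))
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  a <- (a != 0) * 1L
  dimnames(a) <- NULL
  attr(a, "hubs") <- hubs
  a
}

#' Planted modular network
#'
#' Nodes are split into `n_modules` contiguous blocks; every within-module
#' pair is an edge, cross-module pairs are not. The resulting covariance
#' target (strong within-module, weak background correlation) is the default
#' generating structure for whole-brain simulations.
#'
#' @param n_regions node count.
#' @param n_modules number of modules (blocks as equal as possible).
#' @return symmetric 0/1 matrix with zero diagonal and attribute `modules`.
#' @export
planted_modular_network <- function(n_regions = 90, n_modules = 6) {
  mod <- sort(rep_len(seq_len(n_modules), n_regions))
  a <- outer(mod, mod, "==") * 1L
  diag(a) <- 0L
  attr(a, "modules") <- mod
  a
}

#' Modular network with bridging hubs
#'
#' The modular skeleton of [planted_modular_network()] with selected nodes
#' additionally connected to every other node. Such hubs carry the
#' cross-module shortest paths of the thresholded covariance network, which
#' is what makes a region a betweenness hub; a plain high-degree node cannot
#' play this role in a correlation matrix because positive semi-definiteness
#' shrinks the edge correlations of any node with many mutually uncorrelated
#' partners.
#'
#' @param n_regions node count.
#' @param n_modules module count for the background.
#' @param hubs integer node indices to plant as bridging hubs.
#' @return symmetric 0/1 matrix with zero diagonal, attributes `hubs` and
#'   `modules`.
#' @export
planted_hub_modular_network <- function(n_regions = 90, n_modules = 6,
                                        hubs = integer(0)) {
  a <- planted_modular_network(n_regions, n_modules)
  mod <- attr(a, "modules")
  hubs <- as.integer(hubs)
  if (length(hubs) && (any(hubs < 1) || any(hubs > n_regions)))
    stop("hub indices out of range 1..", n_regions, call. = FALSE)
  a[hubs, ] <- 1L
  a[, hubs] <- 1L
  diag(a) <- 0L
  attr(a, "hubs") <- hubs
  attr(a, "modules") <- mod
  a
}

#' Nearest positive semi-definite correlation repair
#'
#' Eigenvalue clipping at a small floor followed by rescaling to unit
#' diagonal, iterated until the smallest eigenvalue is non-negative (up to
#' the floor). Edge-wise target matrices (r_connected on edges, r_background
#' elsewhere) are often indefinite; this repairs them minimally.
#'
#' @param m symmetric matrix with unit diagonal.
#' @param eig_floor smallest admitted eigenvalue.
#' @param max_iter iteration cap.
#' @return PSD correlation matrix with unit diagonal.
#' @export
nearest_psd <- function(m, eig_floor = 1e-8, max_iter = 100) {
  for (i in seq_len(max_iter)) {
    e <- eigen(m, symmetric = TRUE)
    if (min(e$values) >= eig_floor) return(m)
    v <- pmax(e$values, eig_floor)
    m <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(diag(m))
    m <- m / tcrossprod(d)
    m <- (m + t(m)) / 2
    diag(m) <- 1
  }
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < 0)
    stop("target correlation matrix could not be repaired to PSD", call. = FALSE)
  m
}

#' Ground-truth specification for synthetic datasets
#'
#' Describes the generating model for two-group regional metabolism data:
#' subjects are multivariate-normal draws whose correlation matrix is the
#' PSD-repaired edge-wise target built from `base_network` (`r_connected` on
#' planted edges, `r_background` elsewhere). Regional intensity is
#' `region_mean + region_sd * signal + noise`, with independent additive
#' noise of SD `noise_sd` attenuating the planted correlations slightly.
#' Group 2 may differ through `group_effect`.
#'
#' @param n_regions regions per subject (default 90).
#' @param n_per_group subjects per group (default 17).
#' @param base_network symmetric 0/1 planted-edge matrix, zero diagonal;
#'   default [planted_modular_network()] on `n_regions`.
#' @param r_connected target correlation on planted edges, in (0, 1).
#' @param r_background target correlation off edges; `>= 0`, `< r_connected`.
#' @param region_mean mean intensity per region (scalar or length-n vector,
#'   arbitrary uptake units).
#' @param region_sd between-subject SD of the correlated signal component.
#' @param noise_sd SD of independent additive noise per region.
#' @param group_effect list with any of `mean_shift` (scalar or vector added
#'   to group 2 means), `r_connected`, `r_background`, `base_network`
#'   (overrides for group 2's covariance target).
#' @param region_names region names; default [default_region_names()].
#' @param seed base RNG seed; group g draws use `seed + g`.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_regions = 90, n_per_group = 17,
                       base_network = planted_modular_network(n_regions),
                       r_connected = 0.6, r_background = 0.1,
                       region_mean = 100, region_sd = 10, noise_sd = 1,
                       group_effect = list(), region_names = NULL,
                       seed = 1L) {
  base_network <- as.matrix(base_network)
  if (!isTRUE(all.equal(base_network, t(base_network))) ||
      any(diag(base_network) != 0) || !all(base_network %in% c(0, 1)))
    stop("base_network must be a symmetric 0/1 matrix with zero diagonal",
         call. = FALSE)
  if (nrow(base_network) != n_regions)
    stop("base_network dimension disagrees with n_regions", call. = FALSE)
  if (!(r_connected > r_background && r_background >= 0 && r_connected < 1))
    stop("need r_connected > r_background >= 0 and r_connected < 1", call. = FALSE)
  if (n_per_group < 3) stop("n_per_group must be >= 3", call. = FALSE)
  if (is.null(region_names)) region_names <- default_region_names(n_regions)
  known <- c("mean_shift", "r_connected", "r_background", "base_network")
  if (length(setdiff(names(group_effect), known)))
    stop("unknown group_effect fields: ",
         paste(setdiff(names(group_effect), known), collapse = ", "), call. = FALSE)
  spec <- list(n_regions = n_regions, n_per_group = n_per_group,
               base_network = base_network, r_connected = r_connected,
               r_background = r_background,
               region_mean = rep_len(region_mean, n_regions),
               region_sd = region_sd, noise_sd = noise_sd,
               group_effect = group_effect, region_names = region_names,
               planted_hubs = attr(base_network, "hubs"),
               seed = as.integer(seed))
  class(spec) <- "synth_spec"
  spec
}

#' @export
print.synth_spec <- function(x, ...) {
  cat("Synthetic ground-truth spec: ", x$n_regions, " regions, 2 x ",
      x$n_per_group, " subjects\n", sep = "")
  cat("  planted edges: ", sum(x$base_network) / 2,
      " (r = ", x$r_connected, "), background r = ", x$r_background, "\n", sep = "")
  cat("  region_sd = ", x$region_sd, ", noise_sd = ", x$noise_sd,
      ", seed = ", x$seed, "\n", sep = "")
  if (length(x$planted_hubs))
    cat("  planted hubs: ", paste(x$planted_hubs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Target correlation matrix of a spec
#'
#' Edge-wise target (r_connected on planted edges, r_background elsewhere)
#' after PSD repair, for group 1 or 2 (group 2 honours `group_effect`
#' overrides).
#'
#' @param spec a `synth_spec`.
#' @param group 1 or 2.
#' @return PSD correlation matrix, unit diagonal.
#' @export
target_correlation <- function(spec, group = 1) {
  stopifnot(inherits(spec, "synth_spec"), group %in% c(1, 2))
  net <- spec$base_network
  rc <- spec$r_connected
  rb <- spec$r_background
  if (group == 2) {
    ge <- spec$group_effect
    if (!is.null(ge$base_network)) net <- as.matrix(ge$base_network)
    if (!is.null(ge$r_connected)) rc <- ge$r_connected
    if (!is.null(ge$r_background)) rb <- ge$r_background
  }
  tgt <- ifelse(net != 0, rc, rb)
  diag(tgt) <- 1
  nearest_psd(tgt)
}

#' Sample one group's intensity table
#'
#' Draws `n_per_group` subjects from the spec's multivariate-normal model
#' for the requested group (group 2 receives the `group_effect`).
#'
#' @param spec a `synth_spec`.
#' @param group 1 or 2.
#' @param seed RNG seed; default `spec$seed + group` so the two groups use
#'   distinct, reproducible streams.
#' @return numeric matrix `n_per_group` x `n_regions` with region column names.
#' @export
sample_group_intensities <- function(spec, group, seed = NULL) {
  stopifnot(inherits(spec, "synth_spec"), group %in% c(1, 2))
  if (is.null(seed)) seed <- spec$seed + group
  tgt <- target_correlation(spec, group)
  sigma <- spec$region_sd^2 * tgt + diag(spec$noise_sd^2, spec$n_regions)
  mu <- spec$region_mean
  if (group == 2 && !is.null(spec$group_effect$mean_shift))
    mu <- mu + rep_len(spec$group_effect$mean_shift, spec$n_regions)
  set.seed(seed)
  m <- MASS::mvrnorm(spec$n_per_group, mu = mu, Sigma = sigma)
  m <- matrix(m, nrow = spec$n_per_group)
  colnames(m) <- spec$region_names
  m
}

#' Simulate a full two-group dataset
#'
#' @param spec a `synth_spec`.
#' @param group_labels labels for the two groups.
#' @return list of class `synth_dataset` with elements `table` (an
#'   [intensity_table()]), `spec`, and `planted_hubs`.
#' @examples
#' sp <- synth_spec(n_regions = 20, n_per_group = 5,
#'                  base_network = planted_modular_network(20, 4), seed = 7)
#' ds <- simulate_dataset(sp)
#' ds$table
#' @export
simulate_dataset <- function(spec, group_labels = c("g1", "g2")) {
  stopifnot(inherits(spec, "synth_spec"), length(group_labels) == 2)
  m1 <- sample_group_intensities(spec, 1)
  m2 <- sample_group_intensities(spec, 2)
  tab <- intensity_table(
    rbind(m1, m2),
    group = rep(group_labels, each = spec$n_per_group),
    subject_id = c(sprintf("%s_s%02d", group_labels[1], seq_len(spec$n_per_group)),
                   sprintf("%s_s%02d", group_labels[2], seq_len(spec$n_per_group))))
  out <- list(table = tab, spec = spec, planted_hubs = spec$planted_hubs)
  class(out) <- "synth_dataset"
  out
}

#' Toy labelled volumes for the extraction stage
#'
#' Builds a rectangular block parcellation of `grid_shape` with one block per
#' region (remaining blocks are background 0), then one volume per subject
#' whose voxels equal that subject's regional intensity plus Gaussian voxel
#' noise. Anatomical realism is a non-goal; the volumes exist to exercise
#' smoothing and regional-mean extraction against known values.
#'
#' @param table an [intensity_table()] (or plain matrix with region columns).
#' @param grid_shape integer length-3 volume dimensions.
#' @param voxel_noise_sd SD of independent voxel noise.
#' @param seed RNG seed for the voxel noise.
#' @return list with `atlas` (an [atlas_volume()]) and `volumes` (named list
#'   of 3D arrays, one per subject).
#' @export
make_toy_volumes <- function(table, grid_shape = c(30, 36, 30),
                             voxel_noise_sd = 0, seed = 1L) {
  if (inherits(table, "intensity_table")) {
    m <- intensity_matrix(table)
  } else {
    m <- as.matrix(table)
    if (is.null(rownames(m))) rownames(m) <- sprintf("s%03d", seq_len(nrow(m)))
  }
  n_regions <- ncol(m)
  stopifnot(length(grid_shape) == 3)
  k <- blocks_for(n_regions, grid_shape)
  if (any(k > grid_shape))
    stop("grid too small: would create empty parcels for ", n_regions,
         " regions", call. = FALSE)
  cuts <- lapply(1:3, function(a) ceiling(seq_len(grid_shape[a]) / (grid_shape[a] / k[a])))
  block <- array(0L, grid_shape)
  block[] <- (cuts[[1]] - 1L) +
    k[1] * (rep(cuts[[2]] - 1L, each = grid_shape[1])) +
    k[1] * k[2] * (rep(cuts[[3]] - 1L, each = grid_shape[1] * grid_shape[2]))
  labels <- block + 1L
  labels[labels > n_regions] <- 0L
  present <- sort(unique(labels[labels > 0]))
  if (length(present) != n_regions)
    stop("grid too small: empty parcels for ",
         paste(setdiff(seq_len(n_regions), present), collapse = ", "), call. = FALSE)
  atlas <- atlas_volume(labels, data.frame(label = seq_len(n_regions),
                                           name = colnames(m),
                                           stringsAsFactors = FALSE))
  set.seed(seed)
  vox_of <- labels[labels > 0]
  vols <- lapply(seq_len(nrow(m)), function(s) {
    v <- array(0, grid_shape)
    v[labels > 0] <- m[s, vox_of]
    if (voxel_noise_sd > 0)
      v[labels > 0] <- v[labels > 0] + rnorm(sum(labels > 0), 0, voxel_noise_sd)
    v
  })
  names(vols) <- rownames(m)
  list(atlas = atlas, volumes = vols)
}

# Smallest block grid (kx, ky, kz) whose product reaches n, axes split as
# evenly as the grid proportions allow.
blocks_for <- function(n, grid_shape) {
  best <- NULL
  lim <- ceiling(n^(1 / 2)) + 1
  for (kx in 1:lim) for (ky in 1:lim) {
    kz <- ceiling(n / (kx * ky))
    k <- c(kx, ky, kz)
    if (prod(k) >= n && (is.null(best) || prod(k) < prod(best) ||
                         (prod(k) == prod(best) && max(k) < max(best))))
      best <- k
  }
  best
}

#' Serialize a ground-truth spec to YAML
#'
#' @param spec a `synth_spec`.
#' @param path output file.
#' @export
save_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synth_spec"))
  x <- unclass(spec)
  x$base_network <- apply(x$base_network, 1, as.integer, simplify = FALSE)
  x$group_effect <- lapply(x$group_effect, function(v)
    if (is.matrix(v)) apply(v, 1, as.integer, simplify = FALSE) else v)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @param path YAML file written by [save_spec()].
#' @rdname save_spec
#' @export
load_spec <- function(path) {
  x <- yaml::read_yaml(path)
  bn <- do.call(rbind, x$base_network)
  ge <- x$group_effect
  if (!is.null(ge$base_network)) ge$base_network <- do.call(rbind, ge$base_network)
  if (is.null(ge)) ge <- list()
  sp <- synth_spec(n_regions = x$n_regions, n_per_group = x$n_per_group,
                   base_network = bn, r_connected = x$r_connected,
                   r_background = x$r_background, region_mean = x$region_mean,
                   region_sd = x$region_sd, noise_sd = x$noise_sd,
                   group_effect = ge, region_names = x$region_names,
                   seed = x$seed)
  sp$planted_hubs <- x$planted_hubs
  sp
}
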