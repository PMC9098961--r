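#' Atlas volume
#'
#' An integer-labelled parcellation grid (0 = background) plus a region
#' table mapping each label to a region name and hemisphere. Hemisphere is
#' read from the name suffix (`.L`/`_L`, `.R`/`_R`); an odd/even-label
#' fallback is available for atlases whose names carry no suffix.
#'
#' @param labels 3D integer array, 0 for background.
#' @param region_table data frame with columns `label`, `name` (and
#'   optionally `hemisphere`).
#' @param hemisphere_from `"suffix"` (default) or `"parity"` (odd label = L,
#'   even = R).
#' @return object of class `atlas_volume`.
#' @export
atlas_volume <- function(labels, region_table,
                         hemisphere_from = c("suffix", "parity")) {
  hemisphere_from <- match.arg(hemisphere_from)
  labels <- as.array(labels)
  if (length(dim(labels)) != 3) stop("labels must be a 3D array", call. = FALSE)
  rt <- as.data.frame(region_table, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "name") %in% names(rt)))
  rt <- rt[order(rt$label), , drop = FALSE]
  present <- sort(unique(as.vector(labels)))
  present <- present[present > 0]
  missing <- setdiff(present, rt$label)
  if (length(missing))
    stop("grid labels absent from region table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"hemisphere" %in% names(rt)) {
    if (hemisphere_from == "suffix") {
      rt$hemisphere <- hemisphere_from_name(rt$name)
    } else {
      rt$hemisphere <- ifelse(rt$label %% 2 == 1, "L", "R")
    }
  }
  structure(list(labels = labels, regions = rt), class = "atlas_volume")
}

hemisphere_from_name <- function(names) {
  h <- rep(NA_character_, length(names))
  h[grepl("[._]L$", names)] <- "L"
  h[grepl("[._]R$", names)] <- "R"
  h
}

#' @export
print.atlas_volume <- function(x, ...) {
  cat("Atlas volume ", paste(dim(x$labels), collapse = " x "), ": ",
      nrow(x$regions), " regions", sep = "")
  h <- table(factor(x$regions$hemisphere, levels = c("L", "R")))
  cat(" (", h[["L"]], " L / ", h[["R"]], " R)\n", sep = "")
  invisible(x)
}

#' Isotropic Gaussian smoothing of a volume
#'
#' Separable convolution with a Gaussian of
#' `sigma = fwhm_mm / (2 sqrt(2 log 2))` per axis, converted to voxel units
#' by the voxel size. Boundary handling is renormalized: at each voxel the
#' kernel weights falling inside the grid are rescaled to sum to one, so a
#' constant field is exactly preserved and interior mass is conserved.
#'
#' @param volume 3D numeric array.
#' @param fwhm_mm full width at half maximum in mm (default 8, the standard
#'   PET preprocessing width).
#' @param voxel_size_mm voxel edge lengths in mm (scalar or length 3).
#' @return smoothed array of the same dimensions.
#' @export
gaussian_smooth <- function(volume, fwhm_mm = 8, voxel_size_mm = 2) {
  volume <- as.array(volume)
  if (length(dim(volume)) != 3) stop("volume must be 3D", call. = FALSE)
  if (fwhm_mm <= 0) stop("fwhm_mm must be positive", call. = FALSE)
  voxel_size_mm <- rep_len(voxel_size_mm, 3)
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive", call. = FALSE)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  out <- volume
  for (ax in 1:3) {
    w <- smoothing_matrix(dim(volume)[ax], sigma_vox[ax])
    out <- apply_along(out, ax, w)
  }
  out
}

# Row-renormalized 1D Gaussian smoothing matrix (d x d), kernel truncated
# at 4 sigma.
smoothing_matrix <- function(d, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- matrix(0, d, d)
  for (i in seq_len(d)) {
    j <- pmax(1L, i - r):pmin(d, i + r)
    kk <- k[j - i + r + 1L]
    w[i, j] <- kk / sum(kk)
  }
  w
}

apply_along <- function(vol, axis, w) {
  d <- dim(vol)
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  m <- matrix(v, nrow = d[axis])
  m <- w %*% m
  v <- array(m, dim = d[perm])
  aperm(v, order(perm))
}

#' Extract regional mean intensities
#'
#' Arithmetic mean of voxel intensities under each atlas label, in atlas
#' region order; background (label 0) excluded.
#'
#' @param volume 3D numeric array, same shape as the atlas grid.
#' @param atlas an [atlas_volume()].
#' @return named numeric vector, one mean per region.
#' @export
extract_regional_means <- function(volume, atlas) {
  stopifnot(inherits(atlas, "atlas_volume"))
  volume <- as.array(volume)
  if (!identical(dim(volume), dim(atlas$labels)))
    stop("volume shape ", paste(dim(volume), collapse = "x"),
         " does not match atlas grid ",
         paste(dim(atlas$labels), collapse = "x"), call. = FALSE)
  lab <- as.vector(atlas$labels)
  keep <- lab > 0
  sums <- tapply(as.vector(volume)[keep], lab[keep], mean)
  got <- as.integer(names(sums))
  empty <- setdiff(atlas$regions$label, got)
  if (length(empty))
    stop("atlas label(s) with zero voxels: ", paste(empty, collapse = ", "),
         call. = FALSE)
  out <- as.numeric(sums[as.character(atlas$regions$label)])
  names(out) <- atlas$regions$name
  out
}

#' Build an intensity table from subject volumes
#'
#' Optionally smooths each volume, then extracts regional means under the
#' atlas, assembling the subjects x regions table used by all downstream
#' network stages.
#'
#' @param volumes named list of 3D arrays (names = subject ids).
#' @param atlas an [atlas_volume()].
#' @param group group label per subject.
#' @param fwhm_mm smoothing width in mm, or `NULL` to skip smoothing.
#' @param voxel_size_mm voxel size for the FWHM conversion.
#' @return an [intensity_table()].
#' @export
extract_intensity_table <- function(volumes, atlas, group, fwhm_mm = NULL,
                                    voxel_size_mm = 2) {
  stopifnot(length(group) == length(volumes))
  rows <- vapply(volumes, function(v) {
    if (!is.null(fwhm_mm)) v <- gaussian_smooth(v, fwhm_mm, voxel_size_mm)
    extract_regional_means(v, atlas)
  }, numeric(nrow(atlas$regions)))
  m <- t(rows)
  ids <- names(volumes)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_along(volumes))
  intensity_table(m, group = group, subject_id = ids)
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers around RNifti; `read_volume` returns the array with a
#' `voxel_size_mm` attribute taken from the header.
#'
#' @param path NIfTI file path.
#' @return `read_volume`: numeric array with attribute `voxel_size_mm`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "voxel_size_mm") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(arr))))]
  arr
}

#' @param volume numeric array to write.
#' @param voxel_size_mm voxel edge lengths recorded in the header.
#' @rdname read_volume
#' @export
write_volume <- function(volume, path, voxel_size_mm = 2) {
  img <- RNifti::asNifti(as.array(volume))
  RNifti::pixdim(img) <- rep_len(voxel_size_mm, length(dim(as.array(volume))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an atlas from NIfTI labels plus a region TSV
#'
#' The region table is a two-column tab-separated file (`label`, `name`),
#' names carrying `.L`/`.R` (or `_L`/`_R`) hemisphere suffixes.
#'
#' @param labels_path NIfTI file with the integer label grid.
#' @param regions_path TSV with columns `label` and `name`.
#' @inheritParams atlas_volume
#' @return an [atlas_volume()].
#' @export
read_atlas <- function(labels_path, regions_path,
                       hemisphere_from = c("suffix", "parity")) {
  labels <- round(as.array(read_volume(labels_path)))
  storage.mode(labels) <- "integer"
  rt <- read.delim(regions_path, stringsAsFactors = FALSE)
  atlas_volume(labels, rt, hemisphere_from = match.arg(hemisphere_from))
}

#' Write an atlas region table as TSV
#'
#' @param atlas an [atlas_volume()].
#' @param path output TSV path.
#' @export
write_region_table <- function(atlas, path) {
  write.table(atlas$regions, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
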