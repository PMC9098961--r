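test_that("smoothing preserves constant fields and interior mass", {
  v <- array(3.5, c(10, 10, 10))
  expect_equal(gaussian_smooth(v, fwhm_mm = 8, voxel_size_mm = 2), v)
  imp <- array(0, c(31, 31, 31))
  imp[16, 16, 16] <- 1
  sm <- gaussian_smooth(imp, fwhm_mm = 8, voxel_size_mm = 2)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_error(gaussian_smooth(matrix(1, 4, 4)), "3D")
})

test_that("the impulse response is the Gaussian at sigma = fwhm / 2.3548 / voxel", {
  sigma <- 8 / (2 * sqrt(2 * log(2))) / 2   # ~1.699 voxels
  imp <- array(0, c(31, 31, 31))
  imp[16, 16, 16] <- 1
  sm <- gaussian_smooth(imp, fwhm_mm = 8, voxel_size_mm = 2)
  x <- -15:15
  r <- ceiling(4 * sigma)
  k <- exp(-x^2 / (2 * sigma^2))
  k[abs(x) > r] <- 0          # kernel truncated at 4 sigma
  k <- k / sum(k)
  # separable response: the profile through the centre, renormalized, is the
  # 1D kernel itself
  profile <- sm[, 16, 16] / sum(sm[, 16, 16])
  expect_equal(profile, k, tolerance = 1e-10)
})

test_that("regional means are exact on hand-built volumes", {
  labs <- array(0L, c(3, 1, 1))
  labs[1:2] <- 1L
  labs[3] <- 2L
  atlas <- atlas_volume(labs, data.frame(label = 1:2, name = c("a_L", "b_R")))
  vol <- array(c(2, 4, 10), c(3, 1, 1))
  expect_equal(unname(extract_regional_means(vol, atlas)), c(3, 10))
  const <- array(5, c(3, 1, 1))
  expect_equal(unname(extract_regional_means(const, atlas)), c(5, 5))
  expect_error(extract_regional_means(array(1, c(2, 2, 2)), atlas),
               "does not match")
  atlas_bad <- atlas_volume(labs, data.frame(label = 1:3,
                                             name = c("a_L", "b_R", "c_L")))
  expect_error(extract_regional_means(vol, atlas_bad), "3")
})

test_that("extraction is equivariant under label permutation", {
  set.seed(8)
  labs <- array(sample(0:4, 60, replace = TRUE), c(5, 4, 3))
  vol <- array(rnorm(60, 10), c(5, 4, 3))
  atlas <- atlas_volume(labs, data.frame(label = 1:4,
                                         name = paste0("r", 1:4, ".L")))
  means <- extract_regional_means(vol, atlas)
  # swap labels 1 and 3 in both grid and table
  labs2 <- labs
  labs2[labs == 1] <- 3L
  labs2[labs == 3] <- 1L
  atlas2 <- atlas_volume(labs2, data.frame(label = 1:4,
                                           name = paste0("r", c(3, 2, 1, 4), ".L")))
  means2 <- extract_regional_means(vol, atlas2)
  expect_equal(unname(means2), unname(means[c(3, 2, 1, 4)]))
})

test_that("smoothing a constant volume does not change regional means", {
  ds <- small_dataset(n_regions = 6, n_per_group = 3)
  tv <- make_toy_volumes(ds$table, grid_shape = c(10, 10, 6), seed = 1)
  const <- array(7, dim(tv$atlas$labels))
  expect_equal(extract_regional_means(gaussian_smooth(const, 8, 2), tv$atlas),
               extract_regional_means(const, tv$atlas))
})

test_that("the noiseless volume pipeline recovers the generating table", {
  ds <- small_dataset(n_regions = 10, n_per_group = 4)
  tv <- make_toy_volumes(ds$table, grid_shape = c(12, 10, 8),
                         voxel_noise_sd = 0, seed = 5)
  tab <- extract_intensity_table(tv$volumes, tv$atlas, group = ds$table$group)
  expect_equal(intensity_matrix(tab), intensity_matrix(ds$table),
               ignore_attr = TRUE)
})

test_that("proportional normalization rescales rows to grand mean 100", {
  tab <- intensity_table(rbind(c(50, 100, 150), c(1, 2, 3)),
                         group = c("a", "b"))
  norm <- normalize_global(tab, "proportional")
  m <- intensity_matrix(norm)
  expect_equal(unname(m[1, ]), c(50, 100, 150))
  expect_equal(unname(m[2, ]), c(50, 100, 150))
  expect_identical(normalize_global(tab, "none"), tab)
  zero <- intensity_table(rbind(c(0, 0, 0)), group = "a")
  expect_error(normalize_global(zero, "proportional"), "grand mean")
})

test_that("intensity tables survive a CSV round trip and report schema errors", {
  ds <- simulate_dataset(synth_spec(n_per_group = 17, seed = 2))
  f <- tempfile(fileext = ".csv")
  write_intensity_table(ds$table, f)
  back <- read_intensity_table(f)
  expect_equal(dim(intensity_matrix(back)), c(34, 90))
  expect_equal(intensity_matrix(back), intensity_matrix(ds$table),
               tolerance = 1e-12)
  df <- read.csv(f, check.names = FALSE)
  df$group <- NULL
  f2 <- tempfile(fileext = ".csv")
  write.csv(df, f2, row.names = FALSE)
  expect_error(read_intensity_table(f2), "group")
  df2 <- read.csv(f, check.names = FALSE)
  df2$subject_id[2] <- df2$subject_id[1]
  write.csv(df2, f2, row.names = FALSE)
  expect_error(as_intensity_table(df2), "duplicated subject_id")
})

test_that("volumes and atlases survive a NIfTI round trip", {
  ds <- small_dataset(n_regions = 8, n_per_group = 3)
  tv <- make_toy_volumes(ds$table, grid_shape = c(8, 8, 8), seed = 3)
  fv <- tempfile(fileext = ".nii.gz")
  write_volume(tv$volumes[[1]], fv, voxel_size_mm = 2)
  back <- read_volume(fv)
  expect_equal(as.vector(back), as.vector(tv$volumes[[1]]), tolerance = 1e-6)
  expect_equal(unname(attr(back, "voxel_size_mm")), c(2, 2, 2))
  fl <- tempfile(fileext = ".nii.gz")
  ft <- tempfile(fileext = ".tsv")
  write_volume(tv$atlas$labels, fl)
  write_region_table(tv$atlas, ft)
  atlas2 <- read_atlas(fl, ft)
  expect_equal(atlas2$labels, tv$atlas$labels, ignore_attr = TRUE)
  expect_equal(atlas2$regions$name, tv$atlas$regions$name)
  expect_equal(atlas2$regions$hemisphere, tv$atlas$regions$hemisphere)
})

test_that("default atlas configuration has 45 regions per hemisphere", {
  sp <- synth_spec(n_per_group = 3, seed = 1)
  tv <- make_toy_volumes(simulate_dataset(sp)$table)
  h <- table(tv$atlas$regions$hemisphere)
  expect_equal(unname(h[c("L", "R")]), c(45L, 45L), ignore_attr = TRUE)
})
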