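test_that("planted degree-sequence networks realize forced structures", {
  # forced star: one node of degree 5, five leaves of degree 1
  a <- planted_network(6, hubs = 1, hub_degree = 5, background_degree = 1,
                       seed = 1)
  expect_equal(a[1, ], c(0L, 1L, 1L, 1L, 1L, 1L))
  expect_equal(rowSums(a), c(5, 1, 1, 1, 1, 1))
  # forced complete graph
  k4 <- planted_network(4, background_degree = 3, seed = 1)
  expect_equal(unname(k4), complete_graph(4), ignore_attr = TRUE)
})

test_that("planted hubs get exactly the requested degree", {
  a <- planted_network(20, hubs = c(4, 8), hub_degree = 10,
                       background_degree = 3, seed = 7)
  expect_true(isSymmetric(a))
  expect_equal(diag(a), rep(0L, 20))
  expect_equal(unname(rowSums(a)[c(4, 8)]), c(10, 10))
  expect_equal(unname(rowSums(a)[-c(4, 8)]), rep(3, 18))
})

test_that("infeasible degree sequences are rejected", {
  # odd degree sum
  expect_error(planted_network(90, hubs = c(1, 2, 3), hub_degree = 25,
                               background_degree = 6),
               "infeasible")
  # degree >= n
  expect_error(planted_network(5, background_degree = 5), "infeasible")
})

test_that("bridging hubs dominate the degree sequence", {
  a <- planted_hub_modular_network(30, 3, hubs = c(2, 17))
  deg <- rowSums(a)
  expect_true(all(deg[c(2, 17)] > max(deg[-c(2, 17)])))
  expect_true(isSymmetric(a))
})

test_that("PSD repair returns a unit-diagonal PSD matrix", {
  set.seed(5)
  for (i in 1:5) {
    bn <- planted_network(30, hubs = 3, hub_degree = 12,
                          background_degree = 4, seed = i)
    tgt <- target_correlation(synth_spec(
      n_regions = 30, base_network = bn, r_connected = 0.7,
      r_background = 0.05, seed = i))
    expect_equal(diag(tgt), rep(1, 30))
    ev <- eigen(tgt, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
})

test_that("large-n sample correlations converge to the planted target", {
  # the modular block target is PSD as-is, so planted values survive repair
  sp <- synth_spec(n_regions = 20, n_per_group = 5000,
                   base_network = planted_modular_network(20, 4),
                   r_connected = 0.6, r_background = 0.1,
                   noise_sd = 0, seed = 42)
  x <- sample_group_intensities(sp, 1)
  r <- cor(x)
  edge1 <- which(sp$base_network == 1 & upper.tri(r), arr.ind = TRUE)[1, ]
  expect_lt(abs(r[edge1[1], edge1[2]] - 0.6), 0.03)
  edges <- sp$base_network == 1
  expect_lt(mean(abs(r[edges] - 0.6)), 0.02)
  off <- sp$base_network == 0 & row(r) != col(r)
  expect_lt(mean(abs(r[off] - 0.1)), 0.02)
})

test_that("an edgeless network with zero background gives independent regions", {
  sp <- synth_spec(n_regions = 15, n_per_group = 8000,
                   base_network = matrix(0, 15, 15),
                   r_connected = 0.5, r_background = 0,
                   noise_sd = 0, seed = 9)
  r <- cor(sample_group_intensities(sp, 1))
  expect_lt(max(abs(r[row(r) != col(r)])), 0.05)
})

test_that("sample correlation converges in Frobenius norm as n grows", {
  frob <- vapply(c(50, 500, 5000), function(n) {
    sp <- synth_spec(n_regions = 12, n_per_group = n,
                     base_network = planted_modular_network(12, 3),
                     noise_sd = 0, seed = 31)
    tgt <- target_correlation(sp, 1)
    norm(cor(sample_group_intensities(sp, 1)) - tgt, "F")
  }, 0)
  expect_true(all(diff(frob) < 0))
})

test_that("fixed seed reproduces datasets bit-identically", {
  sp <- synth_spec(n_regions = 10, n_per_group = 5,
                   base_network = planted_modular_network(10, 2), seed = 77)
  expect_identical(simulate_dataset(sp), simulate_dataset(sp))
})

test_that("group 2 receives the group effect", {
  sp <- synth_spec(n_regions = 10, n_per_group = 4000,
                   base_network = planted_modular_network(10, 2),
                   group_effect = list(mean_shift = 25), seed = 3)
  m1 <- sample_group_intensities(sp, 1)
  m2 <- sample_group_intensities(sp, 2)
  expect_equal(mean(colMeans(m2) - colMeans(m1)), 25, tolerance = 0.05)
})

test_that("planted hubs stay the top-degree nodes after matched-sparsity thresholding", {
  hubs <- c(3, 21)
  bn <- planted_hub_modular_network(30, 3, hubs = hubs)
  sp <- synth_spec(n_regions = 30, n_per_group = 1000, base_network = bn,
                   r_connected = 0.6, r_background = 0.05, seed = 13)
  net <- covariance_network(sample_group_intensities(sp, 1))
  match_sparsity <- sum(bn) / (30 * 29)
  g <- threshold_by_sparsity(net, match_sparsity)
  deg <- rowSums(g$adjacency)
  expect_true(all(deg[hubs] > max(deg[-hubs])))
})

test_that("toy volumes round-trip intensities and label every parcel", {
  ds <- small_dataset(n_regions = 12, n_per_group = 4)
  tv <- make_toy_volumes(ds$table, grid_shape = c(12, 12, 9),
                         voxel_noise_sd = 0, seed = 2)
  labs <- sort(unique(as.vector(tv$atlas$labels)))
  expect_equal(setdiff(labs, 0), 1:12)
  m <- intensity_matrix(ds$table)
  for (s in c(1, 5)) {
    got <- extract_regional_means(tv$volumes[[s]], tv$atlas)
    expect_equal(unname(got), unname(m[s, ]))
  }
})

test_that("the default 90-region table fits a 30x36x30 grid", {
  sp <- synth_spec(n_per_group = 3, seed = 1)
  tv <- make_toy_volumes(simulate_dataset(sp)$table)
  expect_equal(sort(setdiff(unique(as.vector(tv$atlas$labels)), 0)), 1:90)
  expect_error(make_toy_volumes(simulate_dataset(sp)$table,
                                grid_shape = c(4, 4, 4)),
               "empty parcel|grid too small")
})

test_that("noisy voxels average out within the standard-error bound", {
  ds <- small_dataset(n_regions = 8, n_per_group = 3)
  tv <- make_toy_volumes(ds$table, grid_shape = c(20, 20, 10),
                         voxel_noise_sd = 1, seed = 6)
  sizes <- table(tv$atlas$labels[tv$atlas$labels > 0])
  expect_true(all(sizes >= 200))
  m <- intensity_matrix(ds$table)
  got <- extract_regional_means(tv$volumes[[2]], tv$atlas)
  expect_lt(max(abs(got - m[2, ])), 0.25)
})

test_that("specs survive a YAML round trip", {
  bn <- planted_network(12, hubs = 2, hub_degree = 6, background_degree = 2,
                        seed = 4)
  sp <- synth_spec(n_regions = 12, n_per_group = 5, base_network = bn,
                   r_connected = 0.55, r_background = 0.02,
                   group_effect = list(mean_shift = 3), seed = 11)
  f <- tempfile(fileext = ".yaml")
  save_spec(sp, f)
  sp2 <- load_spec(f)
  expect_equal(sp2$base_network, unname(sp$base_network), ignore_attr = TRUE)
  expect_equal(sp2$planted_hubs, sp$planted_hubs)
  expect_identical(simulate_dataset(sp)$table, simulate_dataset(sp2)$table)
})
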