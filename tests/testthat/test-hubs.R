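test_that("the mean + SD rule flags exactly the outlying region", {
  # mean 2.5, sample SD 5 -> threshold 7.5 -> only the fourth value
  hs <- detect_hubs(c(0, 0, 0, 10), regions = paste0("r", 1:4))
  expect_equal(attr(hs, "threshold"), 7.5)
  expect_equal(hs$is_hub, c(FALSE, FALSE, FALSE, TRUE))
  expect_warning(flat <- detect_hubs(c(2, 2, 2, 2)), "constant")
  expect_false(any(flat$is_hub))
})

test_that("hub detection is invariant to positive rescaling", {
  set.seed(6)
  bc <- rexp(30, 0.1)
  h1 <- detect_hubs(bc)
  h2 <- detect_hubs(bc * 37.5)
  expect_equal(h1$is_hub, h2$is_hub)
})

test_that("planted bridging hubs are recovered from sampled data", {
  hubs <- c(3, 21)
  bn <- planted_hub_modular_network(30, 3, hubs = hubs)
  sp <- synth_spec(n_regions = 30, n_per_group = 17, base_network = bn,
                   r_connected = 0.6, r_background = 0.05, seed = 4)
  ds <- simulate_dataset(sp)
  hs <- hub_analysis(covariance_network(ds$table, "g1"),
                     sparsity_grid(0.1, 0.5, 0.05))
  expect_true(all(hubs %in% which(hs$is_hub)))
})

test_that("hemisphere splitting yields two disjoint 45-region networks", {
  ds <- simulate_dataset(synth_spec(n_per_group = 17, seed = 6))
  net <- covariance_network(ds$table, "g1")
  halves <- split_hemispheres(net)
  expect_equal(length(halves$L$regions), 45)
  expect_equal(length(halves$R$regions), 45)
  expect_length(intersect(halves$L$regions, halves$R$regions), 0)
  expect_setequal(c(halves$L$regions, halves$R$regions), net$regions)
  # submatrices are the intra-hemispheric blocks of the full network
  expect_equal(halves$L$r, net$r[halves$L$regions, halves$L$regions])
})

test_that("swapping hemisphere labels swaps the outputs", {
  ds <- small_dataset(n_regions = 10, n_per_group = 6)
  net <- covariance_network(ds$table, "g1")
  h <- hemisphere_of(net$regions)
  a <- split_hemispheres(net, h)
  swapped <- ifelse(h == "L", "R", "L")
  b <- split_hemispheres(net, swapped)
  expect_equal(a$L, b$R)
  expect_equal(a$R, b$L)
  expect_error(split_hemispheres(covariance_network(
    matrix(rnorm(30), 6, 5, dimnames = list(NULL, paste0("x", 1:5))))),
    "without L/R")
})

test_that("hemispheric connectivity applies the strict r > 0.5 rule", {
  nm <- default_region_names(6)
  h <- hemisphere_of(nm)
  w <- matrix(0, 6, 6, dimnames = list(nm, nm))
  w[h == "L", h == "L"] <- 0.6
  w[h == "R", h == "R"] <- 0.4
  diag(w) <- 0
  net <- structure(list(r = w, regions = nm, n_subjects = 10, group = "g"),
                   class = "covariance_network")
  rep <- hemisphere_connectivity(net, r_min = 0.5)
  expect_equal(unname(rep$edge_counts["L"]), 3)  # complete on 3 left nodes
  expect_equal(unname(rep$edge_counts["R"]), 0)
  # boundary: r exactly 0.5 is excluded
  w[h == "R", h == "R"] <- 0.5
  diag(w) <- 0
  net$r <- w
  expect_equal(unname(hemisphere_connectivity(net, 0.5)$edge_counts["R"]), 0)
})

test_that("hemispheric graphs nest across thresholds and tally lobes", {
  ds <- simulate_dataset(synth_spec(n_per_group = 17, seed = 8))
  net <- covariance_network(ds$table, "g2")
  r5 <- hemisphere_connectivity(net, 0.5)
  r4 <- hemisphere_connectivity(net, 0.4)
  for (side in c("L", "R")) {
    a5 <- r5$graphs[[side]]$adjacency
    a4 <- r4$graphs[[side]]$adjacency
    expect_true(all(a4[a5 == 1] == 1))
  }
  lobes <- read_lobe_table()
  rl <- hemisphere_connectivity(net, 0.5, lobes = lobes)
  expect_equal(sum(rl$lobe_edges$L), unname(rl$edge_counts["L"]))
})

test_that("a generative asymmetry shows up as an edge-count asymmetry", {
  # only right-hemisphere modules carry strong planted correlations
  nm <- default_region_names(30)
  h <- hemisphere_of(nm)
  bn <- matrix(0L, 30, 30)
  right <- which(h == "R")
  bn[right, right] <- planted_modular_network(15, 3)
  sp <- synth_spec(n_regions = 30, n_per_group = 17, base_network = bn,
                   r_connected = 0.7, r_background = 0.05, seed = 5)
  ds <- simulate_dataset(sp)
  rep <- hemisphere_connectivity(covariance_network(ds$table, "g1"), 0.5)
  expect_gt(rep$edge_counts[["R"]], rep$edge_counts[["L"]])
})

test_that("identical left and right intensities give exactly zero asymmetry", {
  set.seed(7)
  half <- matrix(rnorm(10 * 8, 100, 10), 10, 8)
  m <- matrix(0, 10, 16)
  m[, seq(1, 15, 2)] <- half   # .L columns
  m[, seq(2, 16, 2)] <- half   # .R columns mirror them exactly
  colnames(m) <- default_region_names(16)
  tab <- intensity_table(m, group = rep("g1", 10))
  res <- compare_hemispheres(tab, group = "g1",
                             grid = sparsity_grid(0.1, 0.5, 0.1),
                             n_boot = 30, seed = 2)
  expect_equal(res$observed_diff, rep(0, 4))
  expect_equal(res$auc_left, res$auc_right)
})

test_that("a strong hemispheric asymmetry is detected by the bootstrap", {
  nm <- default_region_names(30)
  h <- hemisphere_of(nm)
  bn <- matrix(0L, 30, 30)
  right <- which(h == "R")
  bn[right, right] <- planted_modular_network(15, 3)
  sp <- synth_spec(n_regions = 30, n_per_group = 17, base_network = bn,
                   r_connected = 0.8, r_background = 0.02, noise_sd = 0.5,
                   seed = 11)
  ds <- simulate_dataset(sp)
  res <- compare_hemispheres(ds$table, group = "g1",
                             grid = sparsity_grid(0.1, 0.5, 0.1),
                             n_boot = 200, seed = 3)
  expect_lt(res$p[res$metric == "C"], 0.05)
  expect_lt(res$p[res$metric == "LocE"], 0.05)
  # clustering is higher in the modular (right) hemisphere
  expect_lt(res$observed_diff[res$metric == "C"], 0)
})
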