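test_that("log-scale profile is the mean of log1p counts", {
  counts <- cbind(c(2, 0), c(4, 2))
  rownames(counts) <- c("g1", "g2"); colnames(counts) <- c("c1", "c2")
  prof <- estimate_type_profiles(counts, c("A", "A"))
  expect_equal(unname(prof$log_mean[1, ]),
               c((log(3) + log(5)) / 2, (log(1) + log(3)) / 2))
  # relative-expression convention: cells normalised to sum 1, then averaged
  expect_equal(unname(prof$count_mean[1, ]), c((1 + 2 / 3) / 2, (0 + 1 / 3) / 2))
})

test_that("a one-cell type equals that cell's transformed values; empty types error", {
  counts <- cbind(c(3, 1), c(5, 0))
  rownames(counts) <- c("g1", "g2"); colnames(counts) <- c("c1", "c2")
  prof <- estimate_type_profiles(counts, c("A", "B"))
  expect_equal(unname(prof$log_mean["B", ]), log1p(c(5, 0)))
  expect_equal(unname(prof$count_mean["B", ]), c(1, 0))
  expect_error(estimate_type_profiles(counts, factor(c("A", "A"), levels = c("A", "B"))),
               "empty")
})

test_that("profile estimation is permutation invariant and symmetric", {
  set.seed(2)
  counts <- matrix(rpois(60, 5), 6, 10,
                   dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
  labels <- rep(c("A", "B"), 5)
  p1 <- estimate_type_profiles(counts, labels)
  perm <- sample(10)
  p2 <- estimate_type_profiles(counts[, perm], labels[perm])
  expect_equal(p1$count_mean, p2$count_mean)
  expect_equal(p1$log_mean, p2$log_mean)
  # identical cells across types give identical rows
  same <- counts[, rep(1, 4)]
  colnames(same) <- paste0("s", 1:4)
  p3 <- estimate_type_profiles(same, c("A", "B", "A", "B"))
  expect_equal(unname(p3$count_mean[1, ]), unname(p3$count_mean[2, ]))
})

test_that("an exact mixture of profile rows yields gamma = 0", {
  # every cell of a type is identical, spots are single cells: the pseudo-bulk
  # is exactly a nonnegative mixture of the profile rows
  cA <- c(10L, 5L, 1L, 4L); cB <- c(1L, 2L, 8L, 9L)
  counts <- cbind(matrix(cA, 4, 3), matrix(cB, 4, 3))
  rownames(counts) <- paste0("g", 1:4); colnames(counts) <- paste0("c", 1:6)
  prof <- estimate_type_profiles(counts, rep(c("A", "B"), each = 3))
  y <- t(counts[, c(1, 4, 2)])
  rownames(y) <- paste0("spot", 1:3)
  spots <- spot_dataset(y, data.frame(spot_id = rownames(y), x = 1:3, y = 0),
                        cell_counts = rep(1L, 3))
  eff <- estimate_platform_effects(spots, prof)
  expect_lt(max(abs(eff$gamma)), 1e-6)
})

test_that("a designated gene's platform effect is recovered", {
  spec <- sim_spec(n_types = 3, n_genes = 200, cells_per_type = 600,
                   type_means = default_type_means(3, 200, mean_depth = 500, seed = 21),
                   grid_shape = c(20, 25), cells_per_spot = c(1, 1),
                   label_coherence = 0, seed = 21)
  sim <- simulate_spots(simulate_reference(spec), spec)
  gamma_true <- c(log(2), rep(0, 199))
  y <- round(sweep(sim$truth$pre_counts, 2, exp(gamma_true), "*"))
  storage.mode(y) <- "integer"
  dimnames(y) <- dimnames(sim$spots$counts)
  spots <- spot_dataset(y, sim$spots$coords, sim$spots$cell_counts)
  prof <- estimate_type_profiles(simulate_reference(spec)$counts,
                                 simulate_reference(spec)$labels)
  eff <- estimate_platform_effects(spots, prof)
  expect_lt(abs(eff$gamma[1] - log(2)), 0.15)
  expect_lt(max(abs(eff$gamma[-1])), 0.15)
})

test_that("gamma is near zero when simulated without platform effects", {
  spec <- sim_spec(n_types = 3, n_genes = 200, cells_per_type = 600,
                   type_means = default_type_means(3, 200, mean_depth = 500, seed = 22),
                   grid_shape = c(20, 25), cells_per_spot = c(1, 1),
                   gamma_sd = 0, seed = 22)
  ref <- simulate_reference(spec)
  sim <- simulate_spots(ref, spec)
  prof <- estimate_type_profiles(ref$counts, ref$labels)
  eff <- estimate_platform_effects(sim$spots, prof)
  expect_lt(max(abs(eff$gamma)), 0.1)
})

test_that("spot correction follows the two-step formula", {
  G <- 5
  eff <- mk_effects(G, gamma = c(log(2), rep(0, G - 1)))
  y <- c(10, 20, 30, 25, 15)
  out <- correct_spot_expression(y, eff, target_depth = sum(c(5, 20, 30, 25, 15)))
  expect_equal(out, c(5, 20, 30, 25, 15))
  # normalisation contract: any input sums to target_depth
  out2 <- correct_spot_expression(y, eff, target_depth = 777)
  expect_equal(sum(out2), 777)
  # identity when gamma = 0 and the total already matches
  eff0 <- mk_effects(G)
  expect_equal(correct_spot_expression(y, eff0, target_depth = sum(y)), y)
  expect_error(correct_spot_expression(rep(0, G), eff0, 100), "all-zero")
})

test_that("correcting with the true gamma recovers pre-effect proportions", {
  spec <- sim_spec(n_types = 3, n_genes = 50, cells_per_type = 300,
                   grid_shape = c(5, 5), cells_per_spot = c(1, 2),
                   gamma_sd = 0.5, depth_sd = 0.3, seed = 13)
  sim <- simulate_spots(simulate_reference(spec), spec)
  eff_true <- mk_effects(50, gamma = sim$truth$gamma)
  yc <- correct_spot_expression(sim$spots$counts + 0, eff_true,
                                target_depth = rowSums(sim$truth$pre_counts))
  cs <- cosine_rows(yc, sim$truth$pre_counts)
  expect_true(all(cs >= 0.99))
})

test_that("select_genes returns a valid panel containing type markers", {
  spec <- fix_e2e_spec()
  ref <- simulate_reference(spec)
  idx <- select_genes(ref$counts, ref$labels, n_hvg = 20, n_markers = 5)
  expect_true(all(idx >= 1 & idx <= 64))
  expect_false(anyDuplicated(idx) > 0)
  expect_gte(length(idx), 20)
})
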