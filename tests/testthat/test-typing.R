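mk_spots <- function(coords, M, G = 4L, N = 20L, seed = 1L) {
  set.seed(seed)
  y <- matrix(rpois(nrow(coords) * G, N / G), nrow(coords), G)
  storage.mode(y) <- "integer"
  rownames(y) <- coords$spot_id
  spot_dataset(y, coords, M)
}

test_that("neighbour graph follows the spot geometry", {
  # one spot, 3 cells: the within-spot triangle
  co <- data.frame(spot_id = "s1", x = 0, y = 0)
  g <- build_neighbor_graph(mk_spots(co, 3L), radius = 1)
  expect_equal(nrow(g$edges), 3L)
  # two distant spots, one cell each: no edges
  co2 <- data.frame(spot_id = c("s1", "s2"), x = c(0, 5), y = 0)
  g2 <- build_neighbor_graph(mk_spots(co2, c(1L, 1L)), radius = 1)
  expect_equal(nrow(g2$edges), 0L)
  # 2x2 unit grid, radius 1.01: the 4 sides, no diagonals
  co3 <- data.frame(spot_id = paste0("s", 1:4),
                    x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  g3 <- build_neighbor_graph(mk_spots(co3, rep(1L, 4)), radius = 1.01)
  expect_equal(nrow(g3$edges), 4L)
  expect_false(any(g3$edges[, 1] == 1 & g3$edges[, 2] == 4))
  # duplicate coordinates within a slice are rejected
  co4 <- data.frame(spot_id = c("a", "b"), x = 0, y = 0)
  expect_error(mk_spots(co4, c(1L, 1L)), "duplicate")
})

test_that("cross-slice links connect nearest aligned spots only", {
  co <- data.frame(spot_id = paste0("s", 1:4), x = c(0, 3, 0.1, 3.1),
                   y = 0, slice = c(1, 1, 2, 2))
  spots <- mk_spots(co, rep(1L, 4))
  g_no <- build_neighbor_graph(spots, radius = 1.01, z_link = FALSE)
  expect_equal(nrow(g_no$edges), 0L)
  g <- build_neighbor_graph(spots, radius = 1.01, z_link = TRUE)
  expect_equal(nrow(g$edges), 2L)  # s1-s3 and s2-s4
  expect_true(all(apply(g$edges, 1, function(e) abs(e[1] - e[2]) == 2)))
})

test_that("Potts energy counts discordant unordered pairs", {
  co <- data.frame(spot_id = "s1", x = 0, y = 0)
  g <- build_neighbor_graph(mk_spots(co, 3L), radius = 1)
  expect_equal(potts_energy(c(1, 1, 1), g, 10), 0)
  expect_equal(potts_energy(c(1, 2, 3), g, 1), 3)
  co2 <- data.frame(spot_id = c("s1", "s2"), x = c(0, 1), y = 0)
  g2 <- build_neighbor_graph(mk_spots(co2, c(1L, 1L)), radius = 1.01)
  expect_equal(potts_energy(c(1, 2), g2, 10), 10)
  expect_equal(potts_energy(c(2, 2), g2, 10), 0)
  expect_error(potts_energy(c(1, NA), g2, 10), "label")
})

test_that("spot log-likelihood matches the Poisson closed form", {
  prof <- structure(list(count_mean = matrix(0.5, 1, 1),
                         log_mean = matrix(0, 1, 1),
                         type_names = "A", gene_names = "g1",
                         n_cells = 1L, mean_total = 10),
                    class = "reference_profile")
  eff <- mk_effects(1, sigma_eps = 0)
  ll <- spot_log_likelihood(5L, 10, 1L, prof, eff, alpha = 0)
  expect_equal(ll, dpois(5, 5, log = TRUE))
  expect_equal(round(ll, 4), -1.7403)
  # all-zero observation: -sum of rates
  expect_equal(spot_log_likelihood(0L, 10, 1L, prof, eff, alpha = 0), -5)
  # quadrature path is continuous at sigma_eps -> 0
  eff_eps <- mk_effects(1, sigma_eps = 1e-8)
  expect_lt(abs(spot_log_likelihood(5L, 10, 1L, prof, eff_eps, alpha = 0) - ll),
            1e-6)
  # a clearly nonzero sigma_eps spreads the rate and changes the likelihood
  eff2 <- mk_effects(1, sigma_eps = 0.5)
  expect_false(isTRUE(all.equal(
    spot_log_likelihood(5L, 10, 1L, prof, eff2, alpha = 0), ll)))
})

test_that("with nu = 0 and single cells, ICM is independent ML typing", {
  inst <- mk_typing_instance(31, n_spots = 4)
  # rebuild as single-cell spots
  spots <- spot_dataset(inst$spots$counts, inst$spots$coords,
                        rep(1L, nrow(inst$spots$counts)))
  graph <- build_neighbor_graph(spots, radius = 1.01)
  fl <- icm_map_labels(spots, graph, inst$profile, inst$effects, nu = 0,
                       n_restarts = 3, seed = 1)
  ml <- vapply(seq_len(nrow(spots$counts)), function(i) {
    ll <- vapply(seq_along(inst$profile$type_names), function(k)
      spot_log_likelihood(spots$counts[i, ], spots$umi_totals[i], k,
                          inst$profile, inst$effects, alpha = NULL),
      numeric(1))
    which.max(ll)
  }, integer(1))
  expect_equal(fl$label_idx, ml)
})

test_that("ICM attains the exhaustive MAP on small instances and descends monotonely", {
  hits <- 0L
  for (s in 1:5) {
    inst <- mk_typing_instance(40 + s)
    bf <- brute_force_map(inst, nu = 5)
    fl <- icm_map_labels(inst$spots, inst$graph, inst$profile, inst$effects,
                         nu = 5, n_restarts = 5, seed = s)
    expect_true(all(diff(fl$trace) <= 1e-6))
    if (abs(fl$energy - bf$energy) < 1e-6) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("a very large nu forces the best single-label field", {
  inst <- mk_typing_instance(77)
  K <- length(inst$profile$type_names)
  fl <- icm_map_labels(inst$spots, inst$graph, inst$profile, inst$effects,
                       nu = 1e6, n_restarts = 5, seed = 2)
  expect_equal(length(unique(fl$label_idx)), 1L)
  single_ll <- vapply(seq_len(K), function(k)
    sum(vapply(seq_len(nrow(inst$spots$counts)), function(i)
      spot_log_likelihood(inst$spots$counts[i, ], inst$spots$umi_totals[i],
                          c(k, k), inst$profile, inst$effects, alpha = NULL),
      numeric(1))), numeric(1))
  expect_equal(unique(fl$label_idx), which.max(single_ll))
})

test_that("deleting a reference type reassigns its cells to valid labels", {
  spec <- sim_spec(n_types = 3, n_genes = 30, cells_per_type = 200,
                   grid_shape = c(3, 3), cells_per_spot = c(1, 2), seed = 51)
  ref <- simulate_reference(spec)
  sim <- simulate_spots(ref, spec)
  keep <- ref$labels$type != "type3"
  prof <- estimate_type_profiles(ref$counts[, keep], ref$labels$type[keep])
  eff <- estimate_platform_effects(sim$spots, prof)
  g <- build_neighbor_graph(sim$spots, radius = 1.01)
  fl <- icm_map_labels(sim$spots, g, prof, eff, nu = 10, n_restarts = 2, seed = 1)
  expect_true(all(fl$labels %in% c("type1", "type2")))
})

test_that("singlet/doublet classification separates pure and mixed spots", {
  spec <- fix_oracle_counts()$spec
  prof <- fix_oracle_counts()$profile
  eff <- mk_effects(40, sigma_eps = 0.1)
  p1 <- prof$count_mean[1, ] / sum(prof$count_mean[1, ])
  p2 <- prof$count_mean[2, ] / sum(prof$count_mean[2, ])
  calls1 <- calls2 <- integer(100)
  set.seed(8)
  for (s in 1:100) {
    y_sing <- rpois(40, 500 * p1)
    y_doub <- rpois(40, 250 * p1 + 250 * p2)
    calls1[s] <- classify_spot_multiplicity(y_sing, prof, eff)$multiplicity
    calls2[s] <- classify_spot_multiplicity(y_doub, prof, eff)$multiplicity
  }
  expect_gte(mean(calls1 == 1L), 0.9)
  expect_gte(mean(calls2 == 2L), 0.9)
})

test_that("identical candidate profiles tie-break to singlet", {
  cm <- matrix(rep(c(0.5, 0.3, 0.2), 2), 2, 3, byrow = TRUE)
  prof <- structure(list(count_mean = cm, log_mean = log1p(cm * 100),
                         type_names = c("A", "B"), gene_names = paste0("g", 1:3),
                         n_cells = c(5L, 5L), mean_total = 100),
                    class = "reference_profile")
  eff <- mk_effects(3)
  res <- classify_spot_multiplicity(c(50L, 30L, 20L), prof, eff)
  expect_equal(res$multiplicity, 1L)
})
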