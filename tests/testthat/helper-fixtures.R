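# Shared fixtures, built once per test session. The trained score priors are
# the expensive pieces; they are memoised so module tests and the acceptance
# suite reuse the same objects.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- maker()
  .fixture_cache[[name]]
}

# 1-D Gaussian reference N(0, 0.5^2) in centered space: the score-learning
# fixture with a closed-form convolution score -x / (0.25 + sigma^2)
fix_gauss1d <- function() fixture("gauss1d", function() {
  set.seed(1)
  x <- matrix(rnorm(8192, 0, 0.5), ncol = 1)
  log_mean <- matrix(0, 1, 1, dimnames = list("typeA", NULL))
  schedule <- make_noise_schedule(0.01, 4, L = 50, T = 5)
  list(x = x, type_ids = rep(1L, nrow(x)), log_mean = log_mean,
       schedule = schedule, var = 0.25)
})

fix_prior_1d <- function() fixture("prior1d", function() {
  fx <- fix_gauss1d()
  train_score_model(fx$x, fx$type_ids, fx$log_mean, fx$schedule,
                    epochs = 2000, batch_size = 512, seed = 1)
})

# count-scale end-to-end fixture: K = 4 types, G = 64 genes, 2 cells per
# spot, ~500 UMI per spot, negative-binomial reference
fix_e2e_spec <- function(seed = 11L) {
  sim_spec(n_types = 4, n_genes = 64, cells_per_type = 500,
           type_means = default_type_means(4, 64, mean_depth = 250, seed = 11),
           grid_shape = c(6, 6), cells_per_spot = c(2, 2),
           label_coherence = 1.5, gamma_sd = 0.3, depth_sd = 0.2, seed = seed)
}

fix_e2e <- function() fixture("e2e", function() {
  spec <- fix_e2e_spec()
  ref <- simulate_reference(spec)
  profile <- estimate_type_profiles(ref$counts, ref$labels)
  cen <- center_log_expression(ref$counts, ref$labels, log_mean = profile$log_mean)
  schedule <- make_noise_schedule(0.01, default_sigma_max(cen$x), L = 50, T = 5)
  prior <- train_score_model(cen$x, cen$type_ids, cen$log_mean, schedule,
                             epochs = 600, seed = 1)
  list(spec = spec, ref = ref, profile = profile, schedule = schedule,
       prior = prior)
})

# analytic-oracle count-scale fixture: gaussian_log reference, so the
# Gaussian score oracle is the true prior of the centered data
fix_oracle_counts <- function() fixture("oracle_counts", function() {
  spec <- sim_spec(n_types = 3, n_genes = 40, cells_per_type = 300,
                   expression_model = "gaussian_log", log_sd = 0.3,
                   type_means = default_type_means(3, 40, mean_depth = 500, seed = 5),
                   grid_shape = c(5, 5), cells_per_spot = c(1, 2),
                   label_coherence = 1, seed = 5)
  ref <- simulate_reference(spec)
  profile <- estimate_type_profiles(ref$counts, ref$labels)
  prior <- analytic_gaussian_score(rep(0, 40), diag(0.3^2, 40))
  prior$log_mean <- profile$log_mean
  schedule <- make_noise_schedule(0.01, 6, L = 50, T = 5)
  list(spec = spec, ref = ref, profile = profile, prior = prior,
       schedule = schedule)
})

# minimal platform-effects object with known values, for likelihood tests
mk_effects <- function(G, I = 1L, gamma = rep(0, G), alpha = rep(0, I),
                       sigma_eps = 0) {
  structure(list(gamma = gamma, alpha = alpha, sigma_eps = sigma_eps,
                 sigma_gamma = 0, bulk_weights = NULL, flagged = integer(0)),
            class = "platform_effects")
}

# tiny typing instance: n_spots spots of 2 cells each on a line, K = 3
mk_typing_instance <- function(seed, n_spots = 3L, G = 10L, N = 100L) {
  set.seed(seed)
  means <- default_type_means(3, G, mean_depth = 50, seed = seed)
  ref <- simulate_reference(sim_spec(n_types = 3, n_genes = G,
                                     cells_per_type = 100, type_means = means,
                                     seed = seed))
  profile <- estimate_type_profiles(ref$counts, ref$labels)
  true_pairs <- replicate(n_spots, sample.int(3, 2, replace = TRUE))
  y <- t(vapply(seq_len(n_spots), function(i) {
    p <- colMeans(profile$count_mean[true_pairs[, i], , drop = FALSE])
    rpois(G, N * p / sum(p))
  }, numeric(G)))
  storage.mode(y) <- "integer"
  colnames(y) <- profile$gene_names
  rownames(y) <- paste0("spot", seq_len(n_spots))
  spots <- spot_dataset(y, data.frame(spot_id = rownames(y),
                                      x = seq_len(n_spots), y = 0),
                        cell_counts = rep(2L, n_spots))
  graph <- build_neighbor_graph(spots, radius = 1.01)
  list(spots = spots, graph = graph, profile = profile,
       effects = mk_effects(G, n_spots))
}

# exhaustive MAP search over all K^n labelings of a typing instance
brute_force_map <- function(inst, nu) {
  K <- length(inst$profile$type_names)
  n_spots <- nrow(inst$spots$counts)
  labelings <- expand.grid(rep(list(seq_len(K)), 2L * n_spots))
  ll_cache <- lapply(seq_len(n_spots), function(i) {
    env <- new.env()
    for (k1 in seq_len(K)) for (k2 in seq_len(K)) {
      key <- paste(sort(c(k1, k2)), collapse = ",")
      if (is.null(env[[key]]))
        env[[key]] <- spot_log_likelihood(inst$spots$counts[i, ],
                                          inst$spots$umi_totals[i],
                                          c(k1, k2), inst$profile,
                                          inst$effects, alpha = NULL)
    }
    env
  })
  obj <- apply(as.matrix(labelings), 1, function(lab) {
    ll <- sum(vapply(seq_len(n_spots), function(i) {
      key <- paste(sort(lab[c(2 * i - 1, 2 * i)]), collapse = ",")
      ll_cache[[i]][[key]]
    }, numeric(1)))
    -ll + potts_energy(lab, inst$graph, nu)
  })
  list(energy = min(obj), labeling = as.integer(labelings[which.min(obj), ]),
       all = obj, labelings = labelings)
}
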