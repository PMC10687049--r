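test_that("noise schedules are geometric with sigma^2 weights", {
  sch <- make_noise_schedule(0.01, 1, L = 3)
  expect_equal(sch$sigmas, c(0.01, 0.1, 1))
  expect_equal(sch$weights, sch$sigmas^2)
  expect_error(make_noise_schedule(0.01, 1, L = 1), "L")
  expect_error(make_noise_schedule(1, 0.5), "sigma_min")
  expect_error(make_noise_schedule(0.01, 1, T = 0), "T")
})

test_that("analytic Gaussian scores match the convolution formula", {
  pr <- analytic_gaussian_score(c(0, 0), diag(2))
  expect_equal(as.vector(pr$score(matrix(0, 1, 2), 1e-9)), c(0, 0))
  expect_equal(as.vector(pr$score(matrix(c(1, 2), 1), 1e-9)), c(-1, -2),
               tolerance = 1e-6)
  pr2 <- analytic_gaussian_score(0, matrix(0.25))
  expect_equal(as.vector(pr2$score(matrix(1), 0.5)), -2)
  # antisymmetry about the mean, exactly
  pr3 <- analytic_gaussian_score(c(1, -1), matrix(c(1, .5, .5, 1), 2))
  d <- matrix(c(0.3, -0.7), 1)
  expect_equal(pr3$score(matrix(c(1, -1), 1) + d, 0.3),
               -pr3$score(matrix(c(1, -1), 1) - d, 0.3))
  expect_error(analytic_gaussian_score(c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("the DSM loss of the zero score function is L * G", {
  G <- 3; n <- 200
  set.seed(4)
  x <- matrix(rnorm(n * G), n, G)
  sch <- make_noise_schedule(0.05, 2, L = 20)
  lm <- matrix(0, 1, G)
  loss <- dsm_loss(function(x, s, mu) 0 * x, x, rep(1L, n), sch, lm, seed = 7)
  # each level contributes mean of a chi-square_G; SE of the sum is
  # sqrt(L * 2G / n)
  expect_lt(abs(loss - sch$L * G), 3 * sqrt(sch$L * 2 * G / n))
})

test_that("the exact single-point denoiser has zero DSM loss", {
  x0 <- c(0.4, -1.2)
  x <- matrix(x0, 1)
  sch <- make_noise_schedule(0.05, 2, L = 10)
  exact <- function(xl, s, mu) -sweep(xl, 2, x0) / s^2
  expect_lt(dsm_loss(exact, x, 1L, sch, matrix(0, 1, 2), seed = 3), 1e-20)
})

test_that("the trained 1-D score matches the analytic convolution score", {
  fx <- fix_gauss1d()
  prior <- fix_prior_1d()
  grid <- seq(-2, 2, by = 1)
  for (l in 1:3) {
    s <- fx$schedule$sigmas[l]
    truth <- -grid / (fx$var + s^2)
    est <- as.vector(prior$score(matrix(grid, ncol = 1), s,
                                 matrix(0, length(grid), 1)))
    rel <- sqrt(sum((est - truth)^2) / sum(truth^2))
    expect_lt(rel, 0.1)
  }
})

test_that("training reduces the DSM loss over checkpoints and beats the zero score", {
  fx <- fix_gauss1d()
  prior <- fix_prior_1d()
  h <- prior$meta$loss_history
  for (e in c(100, 200, 400)) {
    l_early <- h$loss[h$epoch == e]
    l_late <- h$loss[h$epoch == 5 * e]
    expect_lte(l_late, l_early * 1.05)
  }
  set.seed(99)
  held <- matrix(rnorm(256, 0, 0.5), ncol = 1)
  l_trained <- dsm_loss(prior, held, rep(1L, 256), fx$schedule, fx$log_mean)
  l_zero <- dsm_loss(function(x, s, mu) 0 * x, held, rep(1L, 256),
                     fx$schedule, fx$log_mean)
  expect_lt(l_trained, l_zero)
})

test_that("type conditioning changes the learned score field", {
  set.seed(5)
  lm <- rbind(A = c(0, 2), B = c(2, 0))
  x <- matrix(rnorm(200 * 2, 0, 0.4), 200, 2)
  ids <- rep(1:2, each = 100)
  sch <- make_noise_schedule(0.01, 2, L = 10)
  pr <- train_score_model(x, ids, lm, sch, epochs = 100, seed = 3)
  probe <- matrix(seq(-1, 1, length.out = 5), 5, 2)
  sA <- pr$score(probe, 0.5, matrix(lm[1, ], 5, 2, byrow = TRUE))
  sB <- pr$score(probe, 0.5, matrix(lm[2, ], 5, 2, byrow = TRUE))
  expect_gt(max(abs(sA - sB)), 0)
})

test_that("training is deterministic given the seed", {
  fx <- fix_gauss1d()
  p1 <- train_score_model(fx$x[1:100, , drop = FALSE], rep(1L, 100),
                          fx$log_mean, fx$schedule, epochs = 30, seed = 11)
  p2 <- train_score_model(fx$x[1:100, , drop = FALSE], rep(1L, 100),
                          fx$log_mean, fx$schedule, epochs = 30, seed = 11)
  expect_identical(p1$meta$par, p2$meta$par)
  expect_error(train_score_model(fx$x, rep(1L, nrow(fx$x)),
                                 matrix(0, 1, 3), fx$schedule, epochs = 10),
               "mismatch")
})

test_that("annealed Langevin sampling reproduces Gaussian oracle moments", {
  sch <- make_noise_schedule(0.01, 4, L = 50, T = 5)
  pr <- analytic_gaussian_score(0, matrix(1))
  xs <- sample_prior(pr, 1, sch, n = 2000, seed = 2)
  expect_lt(abs(mean(xs)), 3 / sqrt(2000))
  expect_lt(abs(var(as.vector(xs)) - 1), 0.1)
  # identical draws under the same seed
  xs2 <- sample_prior(pr, 1, sch, n = 2000, seed = 2)
  expect_identical(xs, xs2)
  # 5-D with a nonzero mean: per-coordinate means within 3 MC SE
  mu <- c(1, -2, 0.5, 0, 3)
  pr5 <- analytic_gaussian_score(mu, diag(0.5^2, 5))
  x5 <- sample_prior(pr5, 1, sch, n = 2000, seed = 3)
  se <- apply(x5, 2, sd) / sqrt(2000)
  expect_true(all(abs(colMeans(x5) - mu) < 3 * se))
})

test_that("oracle samples pass a KS test against the target in most seeded runs", {
  sch <- make_noise_schedule(0.01, 4, L = 50, T = 5)
  pr <- analytic_gaussian_score(0, matrix(1))
  pass <- vapply(1:10, function(s) {
    xs <- sample_prior(pr, 1, sch, n = 2000, seed = s)
    stats::ks.test(as.vector(xs), "pnorm")$p.value > 0.01
  }, logical(1))
  expect_gte(sum(pass), 9L)
})

test_that("centering produces zero-mean per-type log expression", {
  spec <- fix_oracle_counts()$spec
  ref <- fix_oracle_counts()$ref
  cen <- center_log_expression(ref$counts, ref$labels)
  for (k in unique(cen$type_ids)) {
    expect_lt(max(abs(colMeans(cen$x[cen$type_ids == k, ]))), 1e-10)
  }
  expect_equal(dim(cen$log_mean), c(3L, 40L))
})
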