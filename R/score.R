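#' Geometric noise schedule for score training and annealed sampling
#'
#' Noise levels sigma_1 < ... < sigma_L are geometrically spaced between the
#' endpoints (inclusive), with the per-level denoising weight
#' lambda_l = sigma_l^2. The annealed Langevin step at level l is
#' `eta0 * sigma_l^2 / sigma_1^2`, so `eta0` is the step taken at the
#' smallest level.
#'
#' @param sigma_min smallest noise level (close to 0; default 0.01).
#' @param sigma_max largest noise level; [default_sigma_max()] estimates a
#'   data-driven value.
#' @param L number of levels (>= 2); 232 is the full-scale default, 50 the
#'   desk-scale default.
#' @param eta0 base Langevin step size; `NULL` uses `sigma_min^2`, which
#'   makes the level-l step equal to sigma_l^2 (accurate and stable for the
#'   Gaussian-convolution targets the ladder produces; the step must stay
#'   below twice the target variance to avoid divergence).
#' @param T Langevin steps per level (default 5).
#' @return Object of class `noise_schedule`: `sigmas` (ascending), `weights`
#'   (= sigmas^2), `L`, `eta0`, `T`.
#' @export
make_noise_schedule <- function(sigma_min = 0.01, sigma_max = 1, L = 50L,
                                eta0 = NULL, T = 5L) {
  .stop_if(sigma_min <= 0 || sigma_max <= sigma_min,
           "need 0 < sigma_min < sigma_max")
  L <- as.integer(L)
  .stop_if(L < 2L, "L must be >= 2")
  T <- as.integer(T)
  .stop_if(T < 1L, "T must be >= 1")
  if (is.null(eta0)) eta0 <- sigma_min^2
  .stop_if(eta0 <= 0, "eta0 must be positive")
  sigmas <- exp(seq(log(sigma_min), log(sigma_max), length.out = L))
  structure(list(sigmas = sigmas, weights = sigmas^2, L = L,
                 eta0 = eta0, T = T),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("Noise schedule: L = %d geometric levels in [%.4g, %.4g], T = %d, eta0 = %.3g\n",
              x$L, min(x$sigmas), max(x$sigmas), x$T, x$eta0))
  invisible(x)
}

#' Data-driven largest noise level
#'
#' The maximum pairwise Euclidean distance within a subsample of the training
#' vectors, the standard choice that lets the highest noise level bridge all
#' modes of the data.
#'
#' @param x n x G matrix of training vectors.
#' @param max_n subsample size cap.
#' @param seed subsampling seed.
#' @return Scalar sigma_max.
#' @export
default_sigma_max <- function(x, max_n = 500L, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) > max_n) {
    set.seed(seed)
    x <- x[sample.int(nrow(x), max_n), , drop = FALSE]
  }
  max(dist(x))
}

# rational conditioning features of the noise level: r_j = s0_j^2/(s0_j^2+s^2)
# plateau at 1 as sigma -> 0 and decay as sigma^-2, matching the asymptotics
# of Gaussian-convolution scores, so small-sigma behaviour is pinned by
# levels that carry training signal
.sigma_features <- function(sigma, ladder) {
  f <- outer(sigma^2, ladder^2, function(s2, l2) l2 / (l2 + s2))
  dimnames(f) <- NULL
  f
}

.make_ladder <- function(sigma_max, J = 8L) {
  exp(seq(log(sigma_max / 160), log(2 * sigma_max), length.out = J))
}

# ---- minimal MLP with sigma-gated linear skip -------------------------------
# score(x, sigma, mu) = x * (features(sigma) %*% U) + MLP([x, mu, features])
# The network is trained in the noise-prediction parametrisation
# raw = sigma * score, one minibatch row per (cell, level) draw, loss
# ||raw + z||^2, which is the sigma^2-weighted denoising objective.

.mlp_init <- function(d_in, width, G, n_feat, seed) {
  set.seed(seed)
  init <- function(d1, d2) matrix(rnorm(d1 * d2, 0, sqrt(2 / d1)), d1, d2)
  list(W1 = init(d_in, width), b1 = rep(0, width),
       W2 = init(width, width), b2 = rep(0, width),
       W3 = init(width, G), b3 = rep(0, G),
       U = matrix(0, n_feat + 1L, G))
}

# x: n x G, mu: n x G, feat: n x J, returns score (n x G) and caches
.mlp_forward <- function(par, x, mu, feat) {
  X <- cbind(x, mu, feat)
  h1 <- tanh(sweep(X %*% par$W1, 2, par$b1, "+"))
  h2 <- tanh(sweep(h1 %*% par$W2, 2, par$b2, "+"))
  mlp <- sweep(h2 %*% par$W3, 2, par$b3, "+")
  coef <- cbind(1, feat) %*% par$U
  list(score = x * coef + mlp, X = X, h1 = h1, h2 = h2,
       xin = x, Ea = cbind(1, feat))
}

# dscore: gradient of the loss w.r.t. the score output
.mlp_backward <- function(par, f, dscore) {
  g <- list()
  g$U <- crossprod(f$Ea, dscore * f$xin)
  g$W3 <- crossprod(f$h2, dscore); g$b3 <- colSums(dscore)
  dh2 <- (dscore %*% t(par$W3)) * (1 - f$h2^2)
  g$W2 <- crossprod(f$h1, dh2); g$b2 <- colSums(dh2)
  dh1 <- (dh2 %*% t(par$W2)) * (1 - f$h1^2)
  g$W1 <- crossprod(f$X, dh1); g$b1 <- colSums(dh1)
  g
}

.adam_new <- function(par) lapply(par, function(p) list(m = p * 0, v = p * 0))

.adam_step <- function(par, adam, grad, lr, step, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (nm in names(par)) {
    adam[[nm]]$m <- b1 * adam[[nm]]$m + (1 - b1) * grad[[nm]]
    adam[[nm]]$v <- b2 * adam[[nm]]$v + (1 - b2) * grad[[nm]]^2
    par[[nm]] <- par[[nm]] - lr * (adam[[nm]]$m / (1 - b1^step)) /
      (sqrt(adam[[nm]]$v / (1 - b2^step)) + eps)
  }
  list(par = par, adam = adam)
}

#' Construct a score prior around an arbitrary score function
#'
#' Low-level constructor; most users want [train_score_model()] or
#' [analytic_gaussian_score()]. The `score` contract: given an n x G matrix
#' of log-centered expression vectors, a single noise level `sigma` and the
#' conditioning type means `mu` (n x G matrix or length-G vector), return the
#' n x G estimated gradient of the log perturbed density.
#'
#' @param score function `(x, sigma, mu) -> matrix`.
#' @param backend `"trained_network"` or `"analytic_gaussian"`.
#' @param log_mean optional K x G matrix of per-type log1p means used for
#'   conditioning/centering.
#' @param meta list of metadata (epochs, seed, loss history, ...).
#' @return Object of class `score_prior`.
#' @export
score_prior <- function(score, backend, log_mean = NULL, meta = list()) {
  stopifnot(is.function(score))
  structure(list(score = score, backend = backend, log_mean = log_mean,
                 meta = meta),
            class = "score_prior")
}

#' @export
print.score_prior <- function(x, ...) {
  cat(sprintf("Score prior (%s backend)", x$backend))
  if (!is.null(x$log_mean))
    cat(sprintf(", %d types x %d genes", nrow(x$log_mean), ncol(x$log_mean)))
  cat("\n")
  if (!is.null(x$meta$epochs))
    cat(sprintf("  trained %d epochs, seed %s\n", x$meta$epochs,
                as.character(x$meta$seed)))
  invisible(x)
}

#' Exact score of a Gaussian density under the noise ladder
#'
#' For x ~ N(mean, Sigma), the density perturbed by N(0, sigma^2 I) noise is
#' N(mean, Sigma + sigma^2 I), whose score is
#' `-(Sigma + sigma^2 I)^{-1} (x - mean)`. Used as an oracle backend to
#' validate the Langevin samplers against conjugate closed forms; the type
#' conditioning argument is ignored (the centered space is shared).
#'
#' @param mean length-G mean vector.
#' @param covariance G x G symmetric positive-definite matrix.
#' @return A [score_prior()] with backend `"analytic_gaussian"`.
#' @export
analytic_gaussian_score <- function(mean, covariance) {
  mean <- as.numeric(mean)
  covariance <- as.matrix(covariance)
  G <- length(mean)
  .stop_if(!isTRUE(all.equal(covariance, t(covariance))),
           "covariance must be symmetric")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  .stop_if(any(ev <= 0), "covariance must be positive definite")
  score <- function(x, sigma, mu = NULL) {
    x <- matrix(x, ncol = G)
    P <- solve(covariance + sigma^2 * diag(G))
    -sweep(x, 2, mean) %*% P
  }
  score_prior(score, "analytic_gaussian",
              meta = list(mean = mean, covariance = covariance))
}

#' Denoising score-matching loss
#'
#' Monte-Carlo estimate of the multi-level objective
#' `sum_l lambda_l E || s(x + sigma_l z, sigma_l, mu_k) + z / sigma_l ||^2`
#' with `lambda_l = sigma_l^2` (one Gaussian perturbation draw per sample and
#' level). The zero score function has expected loss `L * G`.
#'
#' @param score_fn score function with the [score_prior()] contract, or a
#'   `score_prior`.
#' @param x n x G matrix of log-centered expression vectors.
#' @param type_ids integer or character type of each row (indices into
#'   `log_mean` rows).
#' @param schedule a [make_noise_schedule()].
#' @param log_mean K x G matrix of per-type conditioning means.
#' @param seed seed for the perturbation draws.
#' @return Scalar nonnegative loss.
#' @export
dsm_loss <- function(score_fn, x, type_ids, schedule, log_mean, seed = 1L) {
  if (inherits(score_fn, "score_prior")) score_fn <- score_fn$score
  x <- as.matrix(x)
  .stop_if(nrow(x) == 0, "batch is empty")
  if (is.character(type_ids)) type_ids <- match(type_ids, rownames(log_mean))
  mu <- log_mean[type_ids, , drop = FALSE]
  set.seed(seed)
  n <- nrow(x); G <- ncol(x)
  total <- 0
  for (l in seq_len(schedule$L)) {
    s <- schedule$sigmas[l]
    z <- matrix(rnorm(n * G), n, G)
    sc <- score_fn(x + s * z, s, mu)
    total <- total + schedule$weights[l] * mean(rowSums((sc + z / s)^2))
  }
  total
}

#' Train a conditional score network by denoising score matching
#'
#' Learns s(x, sigma_l, mu_k), the gradient of the log perturbed density of
#' log-centered expression conditional on cell type, across the noise ladder
#' of `schedule`. The type enters as its full mean-expression vector mu_k
#' (same dimension as x, so the conditioning cannot be ignored by the
#' network). Architecture: a sigma-gated linear skip `x * c(sigma)` (exact
#' for Gaussian-family scores, with rational-in-sigma^2 gate features) plus a
#' two-hidden-layer tanh perceptron taking `[x, mu_k, features(sigma)]`.
#' Optimised by Adam with cosine learning-rate decay in the noise-prediction
#' parametrisation of the sigma^2-weighted objective; fully deterministic
#' given `seed`.
#'
#' @param x n x G matrix of log-centered expression (`log1p(count) - mu_k`,
#'   see [center_log_expression()]).
#' @param type_ids type of each row (character names or indices into
#'   `log_mean`).
#' @param log_mean K x G matrix of per-type log1p means (conditioning
#'   vectors).
#' @param schedule a [make_noise_schedule()].
#' @param epochs training epochs (desk scale 2000; full scale 5000-10000,
#'   7500 typical).
#' @param batch_size minibatch rows.
#' @param lr peak Adam learning rate.
#' @param width hidden width; `NULL` gives `max(64, 4 G)`.
#' @param seed integer seed (initialisation, shuffling, perturbations).
#' @param checkpoint_every record the running epoch loss every this many
#'   epochs into `meta$loss_history`.
#' @param ema_decay exponential-moving-average decay for the returned
#'   weights (standard stabilisation for score models); 0 disables averaging.
#' @param weight_decay L2 penalty on the perceptron weights (not on the
#'   linear-skip gate), damping spurious wiggle outside the data range.
#' @return A [score_prior()] with backend `"trained_network"`; `meta` holds
#'   `par` (weights), `epochs`, `seed`, `loss_history`, `ladder`.
#' @export
train_score_model <- function(x, type_ids, log_mean, schedule,
                              epochs = 2000L, batch_size = 128L, lr = 1e-3,
                              width = NULL, seed = 1L, checkpoint_every = 100L,
                              ema_decay = 0.999, weight_decay = 1e-4) {
  x <- as.matrix(x)
  log_mean <- as.matrix(log_mean)
  .stop_if(ncol(x) != ncol(log_mean),
           sprintf("gene dimension mismatch: data has %d, log_mean has %d",
                   ncol(x), ncol(log_mean)))
  if (is.character(type_ids)) type_ids <- match(type_ids, rownames(log_mean))
  .stop_if(anyNA(type_ids) || any(type_ids < 1) || any(type_ids > nrow(log_mean)),
           "type_ids outside log_mean rows")
  n <- nrow(x); G <- ncol(x)
  mu_all <- log_mean[type_ids, , drop = FALSE]
  sig <- schedule$sigmas; L <- schedule$L
  ladder <- .make_ladder(max(sig))
  J <- length(ladder)
  if (is.null(width)) width <- max(64L, 4L * G)
  par <- .mlp_init(2L * G + J, width, G, J, seed)
  adam <- .adam_new(par)
  ema <- par
  set.seed(seed + 1L)
  step <- 0L
  loss_history <- data.frame(epoch = integer(0), loss = numeric(0))
  run_loss <- NA_real_
  window <- numeric(0)  # epoch losses since the last checkpoint
  for (ep in seq_len(epochs)) {
    lr_ep <- lr * (0.5 + 0.5 * cos(pi * (ep - 1) / epochs))
    idx <- sample.int(n)
    ep_loss <- 0; ep_n <- 0L
    for (s0 in seq(1, n, by = batch_size)) {
      rows <- idx[s0:min(s0 + batch_size - 1L, n)]
      nb <- length(rows)
      li <- sample.int(L, nb, replace = TRUE)
      sg <- sig[li]
      z <- matrix(rnorm(nb * G), nb, G)
      xt <- x[rows, , drop = FALSE] + sg * z
      feat <- .sigma_features(sg, ladder)
      f <- .mlp_forward(par, xt, mu_all[rows, , drop = FALSE], feat)
      raw <- sg * f$score                    # noise-prediction output
      resid <- raw + z
      ep_loss <- ep_loss + sum(resid^2); ep_n <- ep_n + nb
      dscore <- (2 * sg / nb) * resid        # d/dscore of mean ||sg*score+z||^2
      g <- .mlp_backward(par, f, dscore)
      if (weight_decay > 0) {
        for (nm in c("W1", "W2", "W3"))
          g[[nm]] <- g[[nm]] + weight_decay * par[[nm]]
      }
      step <- step + 1L
      upd <- .adam_step(par, adam, g, lr_ep, step)
      par <- upd$par; adam <- upd$adam
      if (ema_decay > 0) {
        d <- min(ema_decay, (step + 1) / (step + 10))  # warm-up
        for (nm in names(par)) ema[[nm]] <- d * ema[[nm]] + (1 - d) * par[[nm]]
      }
    }
    run_loss <- ep_loss / ep_n
    window <- c(window, run_loss)
    if (ep %% checkpoint_every == 0L || ep == epochs) {
      # smoothed over the window to damp the Monte-Carlo noise of the
      # per-epoch estimate
      loss_history <- rbind(loss_history,
                            data.frame(epoch = ep, loss = mean(window)))
      window <- numeric(0)
    }
  }
  par_use <- if (ema_decay > 0) ema else par
  score <- function(xq, sigma, mu = NULL) {
    xq <- matrix(xq, ncol = G)
    nq <- nrow(xq)
    if (is.null(mu)) mu <- matrix(0, nq, G)
    if (!is.matrix(mu)) mu <- matrix(mu, nq, G, byrow = TRUE)
    feat <- .sigma_features(rep(sigma, nq), ladder)
    .mlp_forward(par_use, xq, mu, feat)$score
  }
  score_prior(score, "trained_network", log_mean = log_mean,
              meta = list(par = par_use, epochs = epochs, seed = seed,
                          loss_history = loss_history, ladder = ladder,
                          width = width, final_loss = run_loss))
}

#' Center log-scale expression per cell type
#'
#' The space the score model lives in: `log1p(count) - mu_k` for each cell of
#' type k, with mu_k the per-type mean of `log1p(count)`.
#'
#' @param counts G x N count matrix (genes in rows).
#' @param labels cell-type labels.
#' @param log_mean optional precomputed K x G log1p mean matrix (rows named
#'   by type); computed from the data when `NULL`.
#' @return List: `x` (N x G centered matrix), `type_ids` (integer),
#'   `log_mean` (K x G), `type_names`.
#' @export
center_log_expression <- function(counts, labels, log_mean = NULL) {
  if (is.data.frame(labels)) labels <- labels$type
  labels <- as.character(labels)
  counts <- .as_dense(counts)
  type_names <- sort(unique(labels))
  lg <- t(log1p(counts))                       # cells x genes
  if (is.null(log_mean)) {
    log_mean <- do.call(rbind, lapply(type_names, function(k)
      colMeans(lg[labels == k, , drop = FALSE])))
    rownames(log_mean) <- type_names
  }
  type_ids <- match(labels, rownames(log_mean))
  list(x = lg - log_mean[type_ids, , drop = FALSE], type_ids = type_ids,
       log_mean = log_mean, type_names = rownames(log_mean))
}

#' Sample pseudo-cells from a score prior by annealed Langevin dynamics
#'
#' Runs the annealed chain from the largest to the smallest noise level with
#' warm starts between levels: at level l the step is
#' `eta = eta0 sigma_l^2 / sigma_1^2` and T update steps
#' `x <- x + eta s(x, sigma_l, mu_k) + sqrt(2 eta) eps` are taken. The final
#' states approximate draws from the prior density at sigma_1.
#'
#' @param prior a [score_prior()].
#' @param type_id conditioning type (name or row index of the prior's
#'   `log_mean`); ignored by the analytic oracle.
#' @param schedule a [make_noise_schedule()].
#' @param n number of samples (chains run in parallel as matrix rows).
#' @param seed integer seed.
#' @return n x G matrix of log-centered samples.
#' @export
sample_prior <- function(prior, type_id = 1L, schedule, n, seed = 1L) {
  stopifnot(inherits(prior, "score_prior"), inherits(schedule, "noise_schedule"))
  .stop_if(n < 1, "n must be >= 1")
  G <- if (!is.null(prior$log_mean)) ncol(prior$log_mean)
       else length(prior$meta$mean)
  .stop_if(is.null(G), "cannot infer gene dimension from the prior")
  mu <- .prior_mu(prior, type_id, n, G)
  .anneal_run(n, G, schedule, prior$score, mu, function(x, s) 0, seed,
              init = "prior")
}

# conditioning matrix for n chains of a given type
.prior_mu <- function(prior, type_id, n, G) {
  if (is.null(prior$log_mean)) return(matrix(0, n, G))
  if (is.character(type_id)) type_id <- match(type_id, rownames(prior$log_mean))
  .stop_if(anyNA(type_id), "unknown type for this prior")
  matrix(prior$log_mean[type_id, ], n, G, byrow = TRUE)
}
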