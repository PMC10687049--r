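# ---- annealed Langevin posterior sampling -----------------------------------
#
# One engine serves spot decomposition, dropout correction and imputation.
# The state stacks all cells of all spots as rows of an n x G matrix; at
# level l the update is
#   X <- X + eta [ grad log p(y | X) + s(x_m, sigma_l, mu_km) ] + sqrt(2 eta) eps
# with eta = eta0 sigma_l^2 / sigma_1^2, warm starts between levels, and the
# final state of each of R independent runs averaged into the posterior mean.

# per-level observation noise. "sqrt" is the production default
# (sigma_yl = sqrt(sigma_l)); "conjugate" inflates the stated noise by the
# current perturbation, sigma_yl^2 = sigma_y^2 + M sigma_l^2, which for the
# linear link makes every level's target exactly the Gaussian posterior of
# the perturbed variables (y = sum_m x_m + eps = sum_m x_m^(l) + eps', with
# eps' variance sigma_y^2 + M sigma_l^2); "constant" uses sigma_y as given
# at every level (only safe with very small steps). sigma_y_value may be a
# length-G vector (per-gene measurement noise); the return value divides an
# I x G residual matrix, so a scalar, a length-I recycling over M, or an
# I x G matrix all work.
.sigma_yl2 <- function(sigma_l, sigma_y, sigma_y_value, M) {
  switch(sigma_y,
         sqrt = sigma_l,
         conjugate = if (length(sigma_y_value) > 1)
           outer(M * sigma_l^2, rep(1, length(sigma_y_value))) +
             matrix(sigma_y_value^2, length(M), length(sigma_y_value),
                    byrow = TRUE)
         else sigma_y_value^2 + M * sigma_l^2,
         constant = if (length(sigma_y_value) > 1)
           matrix(sigma_y_value^2, length(M), length(sigma_y_value),
                  byrow = TRUE)
         else sigma_y_value^2)
}

# init: "zero" starts every chain at 0 (decomposition/imputation); "prior"
# starts at N(0, sigma_L^2) (prior sampling). The deterministic drift of each
# step is clamped elementwise to +/- max_drift * sigma_l, a trust region that
# keeps the exponential-link likelihood gradient from overshooting at the
# large-step high-noise levels; it is far outside the typical move size, so
# well-scaled problems are unaffected.
.anneal_run <- function(n, G, schedule, score_fn, mu, grad_lik, seed,
                        init = c("zero", "prior"), max_drift = 5) {
  init <- match.arg(init)
  set.seed(seed)
  sig <- schedule$sigmas
  x <- if (init == "prior") matrix(rnorm(n * G, 0, max(sig)), n, G)
       else matrix(0, n, G)
  for (l in rev(seq_len(schedule$L))) {
    s <- sig[l]
    eta <- schedule$eta0 * s^2 / sig[1]^2
    cap <- max_drift * s
    for (t in seq_len(schedule$T)) {
      drift <- eta * (grad_lik(x, s) + score_fn(x, s, mu))
      x <- x + pmin(pmax(drift, -cap), cap) +
        sqrt(2 * eta) * matrix(rnorm(n * G), n, G)
    }
  }
  x
}

#' Decompose spot expression into per-cell expression profiles
#'
#' Samples per-cell log-centered expression X_i = \[x_{i,1}; ...; x_{i,M_i}\]
#' from the posterior p(X_i | y_i, k_i) by annealed Langevin dynamics, where
#' y_i | X_i ~ N(f(X_i), sigma_y^2 I) with the count-scale link
#' `f = sum_m (exp(x_m + mu_{k_m}) - 1)` and the prior score of each cell is
#' the conditional score model. All spots are decomposed in one batched run;
#' the result is the average of R independent annealed runs.
#'
#' The `"linear"` link (`f = sum_m x_m`, Gaussian likelihood in the centered
#' space) exists so the sampler can be validated against conjugate-Gaussian
#' closed forms with the [analytic_gaussian_score()] oracle.
#'
#' @param y length-G batch-corrected spot expression vector, or I x G matrix
#'   for several spots.
#' @param labels per-cell type labels: vector for one spot, list of vectors
#'   (one per spot) for a matrix `y`. Types are names or row indices of the
#'   prior's `log_mean`.
#' @param prior a [score_prior()] covering every label present.
#' @param schedule a [make_noise_schedule()].
#' @param R independent annealed runs averaged into the posterior mean.
#' @param seed integer seed.
#' @param link `"exp"` (count-scale model) or `"linear"` (validation mode).
#' @param sigma_y per-level observation noise rule: `"sqrt"` (default for the
#'   exp link) uses sigma_yl = sqrt(sigma_l); `"conjugate"` (default for the
#'   linear link) uses sigma_yl^2 = sigma_y_value^2 + M_i sigma_l^2, the
#'   exact annealing of a fixed Gaussian observation noise under the linear
#'   link; `"constant"` uses sigma_y_value at every level (requires a very
#'   small `eta0` for stability).
#' @param sigma_y_value observation noise sd entering `"conjugate"` and
#'   `"constant"`.
#' @param keep_runs also return the R per-run final states.
#' @return List: `log_centered` (n x G posterior-mean matrix, cells in spot
#'   order), `counts` (count-scale view `pmax(exp(x + mu) - 1, 0)`; in linear
#'   mode the centered state itself), `cells` (data.frame `spot`, `m`,
#'   `type`), `fitted` (per-spot reconstruction `sum_m` of the count view),
#'   and `runs` (R x n x G array) if `keep_runs`.
#' @export
decompose_spots <- function(y, labels, prior, schedule, R = 10L, seed = 1L,
                            link = c("exp", "linear"),
                            sigma_y = NULL, sigma_y_value = 1,
                            keep_runs = FALSE) {
  link <- match.arg(link)
  if (is.null(sigma_y)) sigma_y <- if (link == "exp") "sqrt" else "conjugate"
  sigma_y <- match.arg(sigma_y, c("sqrt", "conjugate", "constant"))
  stopifnot(inherits(prior, "score_prior"), inherits(schedule, "noise_schedule"))
  if (!is.matrix(y)) y <- matrix(y, nrow = 1)
  if (!is.list(labels)) labels <- list(labels)
  .stop_if(length(labels) != nrow(y), "one label vector per spot required")
  .stop_if(any(!is.finite(y)), "y must be finite")
  G <- ncol(y)
  I <- nrow(y)
  M <- lengths(labels)
  .stop_if(any(M < 1L), "every spot needs at least one cell")
  spot_of_cell <- rep(seq_len(I), M)
  n <- length(spot_of_cell)

  if (!is.null(prior$log_mean)) {
    lab_idx <- lapply(labels, function(l) {
      if (is.character(l)) l <- match(l, rownames(prior$log_mean))
      .stop_if(anyNA(l) || any(l < 1) || any(l > nrow(prior$log_mean)),
               "label absent from prior")
      l
    })
    mu <- prior$log_mean[unlist(lab_idx), , drop = FALSE]
    type_names <- if (!is.null(rownames(prior$log_mean)))
      rownames(prior$log_mean)[unlist(lab_idx)] else as.character(unlist(lab_idx))
  } else {
    mu <- matrix(0, n, G)
    type_names <- as.character(unlist(labels))
  }

  grp <- factor(spot_of_cell, levels = seq_len(I))
  grad_lik <- if (link == "exp") {
    function(x, s) {
      syl2 <- .sigma_yl2(s, sigma_y, sigma_y_value, M)   # per spot
      C <- exp(pmin(x + mu, 30))
      f <- rowsum(C - 1, grp)
      C * ((y - f) / syl2)[spot_of_cell, , drop = FALSE]
    }
  } else {
    function(x, s) {
      syl2 <- .sigma_yl2(s, sigma_y, sigma_y_value, M)
      f <- rowsum(x, grp)
      ((y - f) / syl2)[spot_of_cell, , drop = FALSE]
    }
  }

  xsum <- matrix(0, n, G)
  runs <- if (keep_runs) array(NA_real_, c(R, n, G)) else NULL
  for (r in seq_len(R)) {
    xr <- .anneal_run(n, G, schedule, prior$score, mu, grad_lik, seed + r - 1L)
    xsum <- xsum + xr
    if (keep_runs) runs[r, , ] <- xr
  }
  xbar <- xsum / R
  warn_clip <- any(xbar + mu > 30)
  if (warn_clip) warning("exp link overflow guarded: x + mu clipped at 30",
                         call. = FALSE)
  counts <- if (link == "exp") pmax(exp(pmin(xbar + mu, 30)) - 1, 0) else xbar
  out <- list(log_centered = xbar, counts = counts,
              cells = data.frame(spot = spot_of_cell,
                                 m = unlist(lapply(M, seq_len)),
                                 type = type_names, stringsAsFactors = FALSE),
              fitted = rowsum(counts, grp))
  if (keep_runs) out$runs <- runs
  out
}

#' @rdname decompose_spots
#' @export
decompose_spot <- function(y, labels, prior, schedule, ...) {
  decompose_spots(matrix(y, nrow = 1), list(labels), prior, schedule, ...)
}

#' Impute unmeasured genes of a single-cell ST measurement
#'
#' For imaging-based ST a cell measures only the gene panel `mask` (indices
#' into the reference panel of G genes). With
#' y | x ~ N(I_mask (exp(x + mu_k) - 1), sigma_eps^2 I) and the conditional
#' score prior of type k, annealed Langevin sampling from p(x | y) reproduces
#' the observed coordinates and draws the unobserved ones from the learned
#' conditional; the average over R runs is the imputed profile. An empty mask
#' reduces to prior sampling, a full mask to denoising.
#'
#' @param y_obs observed expression vector, length `length(mask)` (already
#'   batch-corrected; count scale for `link = "exp"`, centered-log scale for
#'   `"linear"`).
#' @param mask integer indices of the observed genes (unique, in 1..G).
#' @param type_id conditioning cell type (name or index).
#' @param prior a [score_prior()].
#' @param schedule a [make_noise_schedule()].
#' @param sigma_eps measurement noise sd.
#' @param R independent runs averaged.
#' @param seed integer seed.
#' @param link `"exp"` or `"linear"` (validation mode).
#' @param anneal_noise inflate the measurement noise by the current
#'   perturbation, `sigma_l^2 + sigma_eps^2` (exact for the linear link;
#'   default), instead of using `sigma_eps` at every level.
#' @param keep_runs also return the R final states.
#' @return List: `log_centered` (length-G posterior mean), `counts`
#'   (count-scale view), `runs` (R x G matrix) if `keep_runs`.
#' @export
impute_cell <- function(y_obs, mask, type_id, prior, schedule, sigma_eps,
                        R = 10L, seed = 1L, link = c("exp", "linear"),
                        anneal_noise = TRUE, keep_runs = FALSE) {
  link <- match.arg(link)
  stopifnot(inherits(prior, "score_prior"), inherits(schedule, "noise_schedule"))
  G <- if (!is.null(prior$log_mean)) ncol(prior$log_mean)
       else length(prior$meta$mean)
  mask <- as.integer(mask)
  .stop_if(anyDuplicated(mask) > 0 || any(mask < 1L) || any(mask > G),
           "mask indices must be unique and within the gene panel")
  .stop_if(length(y_obs) != length(mask), "y_obs and mask lengths differ")
  .stop_if(sigma_eps <= 0, "sigma_eps must be positive")

  mu1 <- .prior_mu(prior, type_id, 1L, G)[1, ]
  mu <- matrix(mu1, R, G, byrow = TRUE)
  # R independent chains as rows, averaged at the end
  se2 <- function(s) if (anneal_noise) sigma_eps^2 + s^2 else sigma_eps^2
  grad_lik <- if (length(mask) == 0L) {
    function(x, s) 0
  } else if (link == "exp") {
    function(x, s) {
      C <- exp(pmin(sweep(x, 2, mu1, "+"), 30))
      g <- matrix(0, nrow(x), G)
      resid <- matrix(y_obs, nrow(x), length(mask), byrow = TRUE) -
        (C[, mask, drop = FALSE] - 1)
      g[, mask] <- C[, mask, drop = FALSE] * resid / se2(s)
      g
    }
  } else {
    function(x, s) {
      g <- matrix(0, nrow(x), G)
      resid <- matrix(y_obs, nrow(x), length(mask), byrow = TRUE) -
        x[, mask, drop = FALSE]
      g[, mask] <- resid / se2(s)
      g
    }
  }
  xr <- .anneal_run(R, G, schedule, prior$score, mu, grad_lik, seed)
  xbar <- colMeans(xr)
  counts <- if (link == "exp") pmax(exp(pmin(xbar + mu1, 30)) - 1, 0) else xbar
  out <- list(log_centered = xbar, counts = counts)
  if (keep_runs) out$runs <- xr
  out
}

#' Correct dropouts in a sparse high-resolution spot
#'
#' Applies the two-step batch correction to the raw spot counts, then reuses
#' the decomposition sampler with the singlet/doublet classification of
#' [classify_spot_multiplicity()]: a singlet is decomposed with M = 1, a
#' doublet with M = 2 and the classified type pair. The count-scale posterior
#' means are the dropout-corrected per-cell profiles.
#'
#' @param y raw length-G count vector of the spot.
#' @param classification result of [classify_spot_multiplicity()] (or a list
#'   with `multiplicity` and `types`).
#' @param prior a [score_prior()].
#' @param schedule a [make_noise_schedule()].
#' @param effects a [platform_effects][estimate_platform_effects()].
#' @param target_depth per-cell depth target; the corrected spot total is set
#'   to `multiplicity * target_depth` (use the reference `mean_total`).
#' @param seed integer seed.
#' @param sigma_y observation-noise rule passed to [decompose_spots()]. The
#'   default `"capture"` models the binomial capture noise of the corrected
#'   counts: gene g is observed with capture rate `exp(gamma_g)` (the
#'   gene-level platform effect doubles as the detection-efficiency
#'   estimate), so after division by `exp(gamma_g)` its measurement variance
#'   is about `1 + f_g * max(exp(-gamma_g) - 1, 0)` with `f_g` the
#'   prior-mean reconstruction of the spot. Sparse, heavily-dropped genes
#'   therefore get a weak likelihood (the learned expression distribution
#'   fills them in) while well-measured genes stay anchored to the data.
#' @param ... passed to [decompose_spots()] (`R`, ...).
#' @return The [decompose_spots()] result, plus `corrected_spot` (column sum
#'   of the per-cell count views) and `y_corrected` (the batch-corrected
#'   input).
#' @export
correct_dropout <- function(y, classification, prior, schedule, effects,
                            target_depth, seed = 1L, sigma_y = "capture", ...) {
  mult <- classification$multiplicity
  .stop_if(!mult %in% c(1L, 2L), "multiplicity must be 1 or 2")
  yc <- correct_spot_expression(y, effects, target_depth * mult)
  labels <- classification$types
  .stop_if(length(labels) != mult, "classification types/multiplicity mismatch")
  if (identical(sigma_y, "capture")) {
    lab_idx <- if (is.character(labels)) match(labels, rownames(prior$log_mean))
               else labels
    fhat <- colSums(pmax(expm1(prior$log_mean[lab_idx, , drop = FALSE]), 0))
    sy <- sqrt(1 + fhat * pmax(exp(-effects$gamma) - 1, 0))
    out <- decompose_spots(matrix(yc, nrow = 1), list(labels), prior, schedule,
                           seed = seed, sigma_y = "conjugate",
                           sigma_y_value = sy, ...)
  } else {
    out <- decompose_spots(matrix(yc, nrow = 1), list(labels), prior, schedule,
                           seed = seed, sigma_y = sigma_y, ...)
  }
  out$corrected_spot <- colSums(out$counts)
  out$y_corrected <- yc
  out
}
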