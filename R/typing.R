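#' Build the cell-level neighbour graph
#'
#' Every segmented cell is a node. Cells sharing a spot are mutually
#' adjacent; cells in two same-slice spots whose centres are within `radius`
#' are adjacent; with `z_link = TRUE`, cells of a spot are also adjacent to
#' the cells of the nearest spot in each adjacent slice (slices are assumed
#' externally aligned in x/y).
#'
#' @param spots a [spot_dataset()].
#' @param radius spot-centre distance below which same-slice spots are
#'   neighbours.
#' @param z_link link cells across adjacent slices.
#' @return Object of class `neighbor_graph`: `nodes` (data.frame `cell`,
#'   `spot`, `m`), `edges` (2-column matrix of cell indices, unordered,
#'   deduplicated), `adj` (per-cell adjacency list), `n_cells`.
#' @export
build_neighbor_graph <- function(spots, radius, z_link = FALSE) {
  stopifnot(inherits(spots, "spot_dataset"))
  .stop_if(radius <= 0, "radius must be positive")
  co <- spots$coords
  M <- spots$cell_counts
  I <- nrow(co)
  key <- paste(co$x, co$y, co$slice)
  .stop_if(anyDuplicated(key) > 0, "duplicate spot coordinates within a slice")

  cell_spot <- rep(seq_len(I), M)
  cell_m <- unlist(lapply(M, seq_len), use.names = FALSE)
  n <- length(cell_spot)
  first <- c(1L, 1L + cumsum(M))[seq_len(I)]  # first cell index of each spot

  ef <- integer(0); et <- integer(0)
  add_spot_pair <- function(i, j) {
    ci <- first[i] + seq_len(M[i]) - 1L
    cj <- first[j] + seq_len(M[j]) - 1L
    grid <- expand.grid(a = ci, b = cj)
    ef <<- c(ef, grid$a); et <<- c(et, grid$b)
  }
  # within-spot cliques
  for (i in seq_len(I)) {
    if (M[i] > 1L) {
      ci <- first[i] + seq_len(M[i]) - 1L
      pr <- utils::combn(ci, 2L)
      ef <- c(ef, pr[1, ]); et <- c(et, pr[2, ])
    }
  }
  # same-slice spot neighbours within radius
  for (sl in unique(co$slice)) {
    idx <- which(co$slice == sl)
    if (length(idx) < 2L) next
    d <- as.matrix(dist(cbind(co$x[idx], co$y[idx])))
    pairs <- which(d <= radius & upper.tri(d), arr.ind = TRUE)
    for (p in seq_len(nrow(pairs))) add_spot_pair(idx[pairs[p, 1]], idx[pairs[p, 2]])
  }
  # nearest spot in each adjacent slice
  if (z_link) {
    slices <- sort(unique(co$slice))
    for (s in seq_along(slices)[-1]) {
      ia <- which(co$slice == slices[s - 1]); ib <- which(co$slice == slices[s])
      for (i in ia) {
        d <- (co$x[ib] - co$x[i])^2 + (co$y[ib] - co$y[i])^2
        add_spot_pair(i, ib[which.min(d)])
      }
      for (j in ib) {
        d <- (co$x[ia] - co$x[j])^2 + (co$y[ia] - co$y[j])^2
        add_spot_pair(ia[which.min(d)], j)
      }
    }
  }
  edges <- cbind(pmin(ef, et), pmax(ef, et))
  edges <- unique(edges)
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      adj[[edges[e, 1]]] <- c(adj[[edges[e, 1]]], edges[e, 2])
      adj[[edges[e, 2]]] <- c(adj[[edges[e, 2]]], edges[e, 1])
    }
  }
  structure(list(nodes = data.frame(cell = seq_len(n), spot = cell_spot, m = cell_m),
                 edges = edges, adj = adj, n_cells = n, spot_first = first),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("Neighbour graph: %d cells, %d edges\n", x$n_cells, nrow(x$edges)))
  invisible(x)
}

#' Potts prior energy of a label field
#'
#' U(K) = sum over unordered neighbour pairs of `nu * [labels differ]`.
#' Smooth fields (few discordant neighbour pairs) have low energy.
#'
#' @param labels vector with one label per graph node.
#' @param graph a [build_neighbor_graph()] result.
#' @param nu smoothness strength (>= 0).
#' @return Scalar energy.
#' @export
potts_energy <- function(labels, graph, nu) {
  stopifnot(inherits(graph, "neighbor_graph"))
  .stop_if(nu < 0, "nu must be >= 0")
  .stop_if(length(labels) != graph$n_cells || anyNA(labels),
           "labels must cover every cell")
  if (!nrow(graph$edges)) return(0)
  nu * sum(labels[graph$edges[, 1]] != labels[graph$edges[, 2]])
}

# Poisson rate for a spot given its cells' type indices:
# lambda_g = exp(alpha) * mean_m(mu_{k_m,g}) * exp(gamma_g); alpha = NULL
# refits the closed-form ML intercept (total rate = N).
.spot_rate <- function(labels_idx, profile, gamma, alpha, N, warn = FALSE, y = NULL) {
  mbar <- colMeans(profile$count_mean[labels_idx, , drop = FALSE])
  lam0 <- mbar * exp(gamma)
  floored <- lam0 < 1e-12
  if (warn && !is.null(y) && any(floored & y > 0)) {
    warning(sprintf("%d gene(s) with positive counts but zero candidate-type mean; rate floored",
                    sum(floored & y > 0)), call. = FALSE)
  }
  lam0 <- pmax(lam0, 1e-12)
  if (is.null(alpha)) alpha <- -log(sum(lam0))
  N * exp(alpha) * lam0
}

#' Poisson log-likelihood of one spot given its cells' types
#'
#' Evaluates the observation model y_ig ~ Poisson(N_i lambda_ig) with
#' log lambda = alpha_i + log(mean over the spot's cells of the type means)
#' + gamma_g + epsilon, where the gene-level noise epsilon ~ N(0, sigma_eps^2)
#' is marginalised by Gauss-Hermite quadrature (`sigma_eps = 0` uses the
#' closed form).
#'
#' @param y length-G count vector of the spot.
#' @param N UMI total of the spot.
#' @param labels type labels (names or indices into the profile) of the
#'   spot's cells.
#' @param profile a [reference_profile][estimate_type_profiles()].
#' @param effects a [platform_effects][estimate_platform_effects()]; its
#'   `sigma_eps` selects the marginalisation.
#' @param alpha spot intercept; `NULL` refits the closed-form maximum
#'   likelihood intercept for the candidate labels.
#' @param gh_nodes quadrature nodes for the epsilon integral.
#' @return Scalar log-likelihood.
#' @export
spot_log_likelihood <- function(y, N, labels, profile, effects,
                                alpha = NULL, gh_nodes = 16L) {
  stopifnot(inherits(profile, "reference_profile"))
  if (is.character(labels)) labels <- match(labels, profile$type_names)
  .stop_if(anyNA(labels), "unknown type label")
  rate <- .spot_rate(labels, profile, effects$gamma, alpha, N, warn = TRUE, y = y)
  sigma <- effects$sigma_eps
  if (sigma < 1e-10) return(sum(dpois(y, rate, log = TRUE)))
  gh <- pracma::gaussHermite(gh_nodes)
  # G x Q matrix of log Pois(y | rate * exp(sqrt(2) sigma z_q))
  lr <- log(rate)
  ll <- outer(lr, sqrt(2) * sigma * gh$x, "+")
  lp <- y * ll - exp(ll) - lgamma(y + 1)
  sum(.row_logsumexp(sweep(lp, 2, log(gh$w), "+")) - 0.5 * log(pi))
}

#' MAP cell-type labelling by pairwise iterated conditional modes
#'
#' Minimises `-log p(Y | K) + U(K)` over the label field K: the Poisson
#' spot likelihood of [spot_log_likelihood()] plus the Potts prior energy of
#' [potts_energy()]. Spots are visited in seed-shuffled order; within a spot
#' all unordered label pairs are updated jointly over the K^2 candidates
#' (single-label updates where M_i = 1), which is the pairwise
#' conditional-modes scheme. Multiple restarts perturb the independent
#' maximum-likelihood initialisation by random label flips and the
#' best-energy local optimum is returned.
#'
#' @param spots a [spot_dataset()].
#' @param graph a [build_neighbor_graph()] on the same spots.
#' @param profile a [reference_profile][estimate_type_profiles()].
#' @param effects a [platform_effects][estimate_platform_effects()].
#' @param nu Potts smoothness (default 10).
#' @param n_restarts random restarts (first start is unperturbed).
#' @param seed integer seed for sweep order and restart perturbations.
#' @param max_sweeps cap on full sweeps per restart.
#' @param refit_alpha refit each spot's intercept per candidate labelling
#'   (closed form); `FALSE` keeps `effects$alpha`.
#' @param perturb_frac fraction of cells re-randomised per restart.
#' @return Object of class `label_field`: `labels` (type names per cell,
#'   graph node order), `label_idx`, `energy` (best objective), `n_sweeps`,
#'   `trace` (objective after each sweep of the winning restart), `nodes`.
#' @export
icm_map_labels <- function(spots, graph, profile, effects, nu = 10,
                           n_restarts = 5L, seed = 1L, max_sweeps = 100L,
                           refit_alpha = TRUE, perturb_frac = 0.1) {
  stopifnot(inherits(spots, "spot_dataset"), inherits(graph, "neighbor_graph"))
  .stop_if(nu < 0, "nu must be >= 0")
  K <- length(profile$type_names)
  I <- nrow(spots$counts)
  M <- spots$cell_counts
  first <- graph$spot_first
  adj <- graph$adj
  gamma <- effects$gamma
  sigma <- effects$sigma_eps
  gh <- if (sigma >= 1e-10) pracma::gaussHermite(16L) else NULL

  # per-spot log-likelihood with memoisation on the label multiset
  caches <- lapply(seq_len(I), function(i) new.env(parent = emptyenv()))
  spot_ll <- function(i, lab) {
    key <- paste(sort(lab), collapse = ",")
    cache <- caches[[i]]
    if (!is.null(v <- cache[[key]])) return(v)
    y <- spots$counts[i, ]; N <- spots$umi_totals[i]
    alpha <- if (refit_alpha) NULL else effects$alpha[i]
    rate <- .spot_rate(lab, profile, gamma, alpha, N)
    v <- if (is.null(gh)) sum(dpois(y, rate, log = TRUE)) else {
      lr <- outer(log(rate), sqrt(2) * sigma * gh$x, "+")
      lp <- y * lr - exp(lr) - lgamma(y + 1)
      sum(.row_logsumexp(sweep(lp, 2, log(gh$w), "+")) - 0.5 * log(pi))
    }
    cache[[key]] <- v
    v
  }

  objective <- function(lab_by_spot) {
    labels <- unlist(lab_by_spot, use.names = FALSE)
    ll <- sum(vapply(seq_len(I), function(i) spot_ll(i, lab_by_spot[[i]]), numeric(1)))
    -ll + potts_energy(labels, graph, nu)
  }

  set.seed(seed)
  # independent per-spot ML initialisation (prior ignored): best common
  # singlet type, then one coordinate pass per cell
  init_ml <- lapply(seq_len(I), function(i) {
    ll1 <- vapply(seq_len(K), function(k) spot_ll(i, rep(k, M[i])), numeric(1))
    lab <- rep(which.max(ll1), M[i])
    if (M[i] > 1L) {
      for (m in seq_len(M[i])) {
        lls <- vapply(seq_len(K), function(k) {
          lab2 <- lab; lab2[m] <- k
          spot_ll(i, lab2)
        }, numeric(1))
        lab[m] <- which.max(lls)
      }
    }
    lab
  })

  n_cells <- graph$n_cells
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    lab_by_spot <- lapply(init_ml, identity)
    if (rs > 1L) {
      flip <- sample.int(n_cells, max(1L, round(perturb_frac * n_cells)))
      for (c in flip) {
        i <- graph$nodes$spot[c]; m <- graph$nodes$m[c]
        lab_by_spot[[i]][m] <- sample.int(K, 1L)
      }
    }
    labels <- unlist(lab_by_spot, use.names = FALSE)
    trace <- objective(lab_by_spot)
    n_sweeps <- 0L
    repeat {
      n_sweeps <- n_sweeps + 1L
      changed <- FALSE
      for (i in sample.int(I)) {
        lab <- lab_by_spot[[i]]
        cells <- first[i] + seq_len(M[i]) - 1L
        if (M[i] == 1L) {
          c1 <- cells[1]
          nb <- adj[[c1]]
          nb_lab <- labels[nb]
          cur <- -spot_ll(i, lab) + nu * sum(nb_lab != lab[1])
          obj <- vapply(seq_len(K), function(k)
            -spot_ll(i, k) + nu * sum(nb_lab != k), numeric(1))
          k <- which.min(obj)
          if (obj[k] < cur - 1e-9) {
            lab_by_spot[[i]] <- k; labels[c1] <- k; changed <- TRUE
          }
        } else {
          prs <- utils::combn(seq_len(M[i]), 2L)
          for (p in seq_len(ncol(prs))) {
            a <- prs[1, p]; b <- prs[2, p]
            ca <- cells[a]; cb <- cells[b]
            lab <- lab_by_spot[[i]]
            nb_a <- setdiff(adj[[ca]], cb); la <- labels[nb_a]
            nb_b <- setdiff(adj[[cb]], ca); lb <- labels[nb_b]
            linked <- cb %in% adj[[ca]]
            cand <- expand.grid(k1 = seq_len(K), k2 = seq_len(K))
            obj <- vapply(seq_len(nrow(cand)), function(q) {
              k1 <- cand$k1[q]; k2 <- cand$k2[q]
              lab2 <- lab; lab2[a] <- k1; lab2[b] <- k2
              -spot_ll(i, lab2) + nu * (sum(la != k1) + sum(lb != k2) +
                                          (if (linked) (k1 != k2) else 0))
            }, numeric(1))
            cur <- -spot_ll(i, lab) + nu * (sum(la != lab[a]) + sum(lb != lab[b]) +
                                              (if (linked) (lab[a] != lab[b]) else 0))
            q <- which.min(obj)
            if (obj[q] < cur - 1e-9) {
              lab[a] <- cand$k1[q]; lab[b] <- cand$k2[q]
              lab_by_spot[[i]] <- lab
              labels[ca] <- lab[a]; labels[cb] <- lab[b]
              changed <- TRUE
            }
          }
        }
      }
      trace <- c(trace, objective(lab_by_spot))
      if (!changed || n_sweeps >= max_sweeps) break
    }
    en <- trace[length(trace)]
    if (is.null(best) || en < best$energy - 1e-12) {
      best <- list(labels = labels, energy = en, n_sweeps = n_sweeps, trace = trace)
    }
  }
  structure(list(labels = profile$type_names[best$labels],
                 label_idx = best$labels, energy = best$energy,
                 n_sweeps = best$n_sweeps, trace = best$trace,
                 nodes = graph$nodes, nu = nu),
            class = "label_field")
}

#' @export
print.label_field <- function(x, ...) {
  cat(sprintf("Label field: %d cells, objective %.3f after %d sweep(s), nu = %g\n",
              length(x$labels), x$energy, x$n_sweeps, x$nu))
  print(table(x$labels))
  invisible(x)
}

#' Singlet/doublet classification for high-resolution spots
#'
#' For platforms without images (no segmented cell count), compares the best
#' single-type spot likelihood against the best two-type likelihood (type
#' pair averaged in the Poisson rate, M = 2) and declares a doublet only when
#' the log-likelihood gain exceeds `threshold`. Ties, including a candidate
#' pair of identical profiles, stay singlets.
#'
#' @param y length-G count vector of the spot.
#' @param profile a [reference_profile][estimate_type_profiles()].
#' @param effects a [platform_effects][estimate_platform_effects()].
#' @param threshold log-likelihood gain required to call a doublet.
#' @return List: `multiplicity` (1 or 2), `types` (best type or pair),
#'   `gain` (doublet minus singlet log-likelihood).
#' @export
classify_spot_multiplicity <- function(y, profile, effects, threshold = 2) {
  K <- length(profile$type_names)
  N <- sum(y)
  ll <- function(lab) spot_log_likelihood(y, N, lab, profile, effects, alpha = NULL)
  ll1 <- vapply(seq_len(K), function(k) ll(k), numeric(1))
  b1 <- which.max(ll1)
  pairs <- utils::combn(K, 2L)
  ll2 <- vapply(seq_len(ncol(pairs)), function(p) ll(pairs[, p]), numeric(1))
  b2 <- which.max(ll2)
  gain <- ll2[b2] - ll1[b1]
  if (gain > threshold) {
    list(multiplicity = 2L, types = profile$type_names[pairs[, b2]], gain = gain)
  } else {
    list(multiplicity = 1L, types = profile$type_names[b1], gain = gain)
  }
}
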