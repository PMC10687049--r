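#' Specification for a synthetic reference + spatial dataset
#'
#' Bundles every parameter of the synthetic-data generator: a parametric
#' per-type expression model standing in for an annotated scRNA-seq reference,
#' and a gridded spot layout in which reference cells are aggregated into
#' spots under a spatially coherent label field, gene-level platform effects
#' and per-spot depth effects.
#'
#' @param n_types number of cell types K.
#' @param n_genes number of genes G.
#' @param cells_per_type integer vector (length `n_types`, or scalar recycled)
#'   of reference cells per type.
#' @param expression_model `"negative_binomial"` (counts ~ NB per gene per
#'   type), `"poisson"` (the dispersion-free limit), or `"gaussian_log"`
#'   (log1p-scale Gaussian with per-type mean `log1p(type_means)` and standard
#'   deviation `log_sd`; exists so that the analytic Gaussian score oracle is
#'   exact for the generated data).
#' @param type_means K x G matrix of per-type mean expression on the count
#'   scale, or `NULL` to build one with [default_type_means()].
#' @param dispersion NB size parameter (must be positive).
#' @param log_sd log-scale standard deviation for `"gaussian_log"`.
#' @param grid_shape `c(rows, cols)` of the spot grid (unit spacing,
#'   4-neighbourhood).
#' @param cells_per_spot integer range `c(min, max)` within \[1, 20\].
#' @param label_coherence Potts interaction strength of the true spot label
#'   field; 0 gives independent uniform labels.
#' @param gamma_sd standard deviation of the true gene platform effects
#'   gamma_g (log scale); 0 disables them.
#' @param depth_sd log-normal sd of the per-spot multiplicative depth effect;
#'   0 disables it.
#' @param potts_sweeps Gibbs sweeps used to sample the true label field.
#' @param seed integer seed; the whole generator is reproducible from it.
#' @return An object of class `sim_spec`.
#' @seealso [simulate_reference()], [simulate_spots()]
#' @export
sim_spec <- function(n_types = 3L, n_genes = 50L,
                     cells_per_type = 200L,
                     expression_model = c("negative_binomial", "poisson", "gaussian_log"),
                     type_means = NULL, dispersion = 2, log_sd = 0.3,
                     grid_shape = c(10L, 10L), cells_per_spot = c(1L, 5L),
                     label_coherence = 2, gamma_sd = 0, depth_sd = 0,
                     potts_sweeps = 50L, seed = 1L) {
  expression_model <- match.arg(expression_model)
  n_types <- as.integer(n_types); n_genes <- as.integer(n_genes)
  .stop_if(n_types < 1L || n_genes < 1L, "n_types and n_genes must be positive")
  if (length(cells_per_type) == 1L) cells_per_type <- rep(cells_per_type, n_types)
  cells_per_type <- as.integer(cells_per_type)
  .stop_if(length(cells_per_type) != n_types || any(cells_per_type < 1L),
           "cells_per_type must give a positive count for each type")
  .stop_if(expression_model == "negative_binomial" && dispersion <= 0,
           "dispersion must be positive")
  .stop_if(log_sd <= 0, "log_sd must be positive")
  grid_shape <- as.integer(grid_shape)
  .stop_if(length(grid_shape) != 2L || any(grid_shape < 1L),
           "grid_shape must be two positive integers")
  cells_per_spot <- as.integer(cells_per_spot)
  .stop_if(length(cells_per_spot) != 2L || cells_per_spot[1] > cells_per_spot[2] ||
             cells_per_spot[1] < 1L || cells_per_spot[2] > 20L,
           "cells_per_spot must be an increasing range within [1, 20]")
  .stop_if(label_coherence < 0, "label_coherence must be >= 0")
  .stop_if(gamma_sd < 0, "gamma_sd must be >= 0")
  .stop_if(depth_sd < 0, "depth_sd must be >= 0")
  if (is.null(type_means)) {
    type_means <- default_type_means(n_types, n_genes, seed = seed)
  }
  type_means <- as.matrix(type_means)
  .stop_if(nrow(type_means) != n_types || ncol(type_means) != n_genes,
           "type_means must be a n_types x n_genes matrix")
  .stop_if(any(type_means < 0), "type_means must be nonnegative")
  structure(list(
    n_types = n_types, n_genes = n_genes, cells_per_type = cells_per_type,
    expression_model = expression_model, type_means = type_means,
    dispersion = dispersion, log_sd = log_sd, grid_shape = grid_shape,
    cells_per_spot = cells_per_spot, label_coherence = label_coherence,
    gamma_sd = gamma_sd, depth_sd = depth_sd,
    potts_sweeps = as.integer(potts_sweeps), seed = as.integer(seed)
  ), class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("Synthetic dataset specification\n")
  cat(sprintf("  %d types, %d genes, %s cells/type, model = %s\n",
              x$n_types, x$n_genes, paste(unique(x$cells_per_type), collapse = "/"),
              x$expression_model))
  cat(sprintf("  grid %d x %d, %d-%d cells/spot, label coherence %.2g\n",
              x$grid_shape[1], x$grid_shape[2], x$cells_per_spot[1],
              x$cells_per_spot[2], x$label_coherence))
  cat(sprintf("  gamma_sd %.2g, depth_sd %.2g, seed %d\n",
              x$gamma_sd, x$depth_sd, x$seed))
  invisible(x)
}

#' Build a default per-type mean-expression matrix
#'
#' Gene baseline means are log-normal; each type up-regulates an exclusive
#' block of marker genes by a constant fold change, giving types distinct,
#' partially overlapping expression programs.
#'
#' @param n_types,n_genes dimensions of the matrix.
#' @param mean_depth expected total counts per cell.
#' @param marker_frac fraction of genes assigned as markers to each type.
#' @param marker_fold fold change of marker genes in their own type.
#' @param seed integer seed.
#' @return K x G matrix of mean counts.
#' @export
default_type_means <- function(n_types, n_genes, mean_depth = 1000,
                               marker_frac = 0.1, marker_fold = 5, seed = 1L) {
  set.seed(seed)
  base <- rlnorm(n_genes, meanlog = 0, sdlog = 0.7)
  m <- matrix(rep(base, each = n_types), n_types, n_genes)
  n_mark <- max(1L, floor(marker_frac * n_genes))
  free <- seq_len(n_genes)
  for (k in seq_len(n_types)) {
    take <- free[seq_len(min(n_mark, length(free)))]
    m[k, take] <- m[k, take] * marker_fold
    free <- setdiff(free, take)
  }
  m / rowSums(m) * mean_depth
}

#' Simulate an annotated single-cell reference
#'
#' Draws `sum(cells_per_type)` cells from the per-type expression model of a
#' [sim_spec()]. Under `"negative_binomial"` each entry is NB with the type's
#' gene mean and shared dispersion; `"poisson"` drops the overdispersion;
#' `"gaussian_log"` draws log1p-scale Gaussians and maps them back to
#' rounded counts.
#'
#' @param spec a [sim_spec()].
#' @return List with `counts` (G x N integer matrix, genes in rows),
#'   `labels` (data.frame with columns `cell`, `type`).
#' @export
simulate_reference <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  K <- spec$n_types; G <- spec$n_genes
  N <- sum(spec$cells_per_type)
  counts <- matrix(0L, G, N)
  types <- character(N)
  type_names <- paste0("type", seq_len(K))
  col <- 0L
  for (k in seq_len(K)) {
    nk <- spec$cells_per_type[k]
    mu <- spec$type_means[k, ]
    block <- switch(spec$expression_model,
      negative_binomial = matrix(rnbinom(G * nk, mu = mu, size = spec$dispersion), G, nk),
      poisson = matrix(rpois(G * nk, lambda = mu), G, nk),
      gaussian_log = {
        x <- matrix(rnorm(G * nk, mean = log1p(mu), sd = spec$log_sd), G, nk)
        matrix(as.integer(pmax(0, round(expm1(x)))), G, nk)
      })
    counts[, col + seq_len(nk)] <- block
    types[col + seq_len(nk)] <- type_names[k]
    col <- col + nk
  }
  rownames(counts) <- paste0("gene", seq_len(G))
  colnames(counts) <- paste0("cell", seq_len(N))
  list(counts = counts,
       labels = data.frame(cell = colnames(counts), type = types,
                           stringsAsFactors = FALSE))
}

# one Gibbs sweep update per site of a K-state Potts field on a rows x cols
# grid with 4-neighbourhood; beta is the interaction strength
.sample_potts_field <- function(rows, cols, K, beta, sweeps) {
  z <- matrix(sample.int(K, rows * cols, replace = TRUE), rows, cols)
  if (beta <= 0 || sweeps < 1L) return(z)
  for (s in seq_len(sweeps)) {
    for (r in seq_len(rows)) for (c in seq_len(cols)) {
      cnt <- numeric(K)
      if (r > 1)    cnt[z[r - 1, c]] <- cnt[z[r - 1, c]] + 1
      if (r < rows) cnt[z[r + 1, c]] <- cnt[z[r + 1, c]] + 1
      if (c > 1)    cnt[z[r, c - 1]] <- cnt[z[r, c - 1]] + 1
      if (c < cols) cnt[z[r, c + 1]] <- cnt[z[r, c + 1]] + 1
      p <- exp(beta * cnt - max(beta * cnt))
      z[r, c] <- sample.int(K, 1L, prob = p)
    }
  }
  z
}

#' Aggregate reference cells into simulated spots on a grid
#'
#' Emulates benchmarking by gridding and aggregation: a spatially coherent
#' cell-type field is sampled on the spot grid by Gibbs sweeps of a Potts
#' model, each spot draws its cells (without replacement) from the reference
#' pool of its type, per-spot counts are the exact sums of the drawn cells'
#' counts, and gene-level platform effects `exp(gamma_g)` plus a per-spot
#' log-normal depth factor are applied afterwards (with rounding back to
#' integer counts). With `gamma_sd = 0` and `depth_sd = 0` the spot counts
#' equal the per-cell sums exactly.
#'
#' @param reference list with `counts` and `labels`, as returned by
#'   [simulate_reference()] (any annotated reference with the same shape
#'   works).
#' @param spec a [sim_spec()].
#' @return List with `spots` (a [spot_dataset()]) and `truth`, a ground-truth
#'   bundle: `cell_counts` (cells x genes), `cell_type`, `cell_spot`,
#'   `spot_label`, `pre_counts` (spot sums before platform effects), `gamma`,
#'   `depth`, `label_coherence`.
#' @export
simulate_spots <- function(reference, spec) {
  stopifnot(inherits(spec, "sim_spec"))
  .stop_if(is.null(reference$counts) || ncol(reference$counts) == 0,
           "reference is empty")
  set.seed(spec$seed + 1L)
  counts <- .as_dense(reference$counts)
  G <- nrow(counts)
  rows <- spec$grid_shape[1]; cols <- spec$grid_shape[2]
  I <- rows * cols
  type_names <- sort(unique(reference$labels$type))
  K <- length(type_names)

  z <- .sample_potts_field(rows, cols, K, spec$label_coherence, spec$potts_sweeps)
  M <- sample(seq(spec$cells_per_spot[1], spec$cells_per_spot[2]), I, replace = TRUE)

  pool <- split(seq_len(ncol(counts)), reference$labels$type)
  spot_of_cell <- integer(0); cell_ids <- integer(0)
  for (i in seq_len(I)) {
    k <- type_names[z[i]]
    avail <- pool[[k]]
    .stop_if(length(avail) < M[i],
             sprintf("reference pool exhausted for %s (need %d, have %d)",
                     k, M[i], length(avail)))
    take <- avail[seq_len(M[i])]
    pool[[k]] <- avail[-seq_len(M[i])]
    cell_ids <- c(cell_ids, take)
    spot_of_cell <- c(spot_of_cell, rep(i, M[i]))
  }
  cell_counts <- t(counts[, cell_ids, drop = FALSE])  # cells x genes
  pre <- rowsum(cell_counts, spot_of_cell)            # spots x genes
  storage.mode(pre) <- "double"

  gamma <- if (spec$gamma_sd > 0) rnorm(G, 0, spec$gamma_sd) else numeric(G)
  depth <- if (spec$depth_sd > 0) rlnorm(I, 0, spec$depth_sd) else rep(1, I)
  y <- if (spec$gamma_sd == 0 && spec$depth_sd == 0) pre else
    round(sweep(pre, 2, exp(gamma), "*") * depth)
  storage.mode(y) <- "integer"
  rownames(y) <- paste0("spot", seq_len(I))
  colnames(y) <- rownames(counts)

  coords <- data.frame(
    spot_id = rownames(y),
    x = as.numeric((seq_len(I) - 1L) %% rows + 1L),
    y = as.numeric((seq_len(I) - 1L) %/% rows + 1L),
    slice = 1L, stringsAsFactors = FALSE)

  spots <- spot_dataset(counts = y, coords = coords, cell_counts = M)
  truth <- list(cell_counts = cell_counts,
                cell_type = reference$labels$type[cell_ids],
                cell_spot = spot_of_cell,
                spot_label = type_names[as.vector(z)],
                pre_counts = pre, gamma = gamma, depth = depth,
                label_coherence = spec$label_coherence)
  list(spots = spots, truth = truth)
}

#' Binomial thinning of a count matrix
#'
#' Replaces every count by a Binomial(count, rate) draw, simulating a reduced
#' UMI capture rate. `rate = 1` returns the input unchanged.
#'
#' @param m integer count matrix (dense or `Matrix` sparse).
#' @param rate retention probability in (0, 1\].
#' @param seed integer seed.
#' @return Matrix of the same class and dimension.
#' @export
downsample_counts <- function(m, rate, seed = 1L) {
  .stop_if(!is.numeric(rate) || length(rate) != 1 || rate <= 0 || rate > 1,
           "rate must be a single value in (0, 1]")
  .stop_if(!.is_count_matrix(m), "input must be a nonnegative integer matrix")
  if (rate == 1) return(m)
  set.seed(seed)
  if (inherits(m, "sparseMatrix")) {
    m@x <- as.numeric(rbinom(length(m@x), as.integer(m@x), rate))
    return(Matrix::drop0(m))
  }
  out <- m
  out[] <- rbinom(length(m), as.integer(m), rate)
  out
}
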