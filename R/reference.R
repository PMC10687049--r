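#' Estimate per-type expression profiles from an annotated reference
#'
#' Two conventions are produced, matching the two places profiles enter the
#' model. `count_mean` holds relative expression: each cell is normalised to
#' sum to one before averaging within its type, so the Poisson rate of the
#' typing model is a composition and the spot effect absorbs depth.
#' `log_mean` holds the per-type mean of `log1p(count)` on raw counts, the
#' centering vector of the score model's log-centered space.
#'
#' @param counts G x N count matrix (genes in rows).
#' @param labels character/factor vector of cell types (length N), or a
#'   data.frame with a `type` column.
#' @return Object of class `reference_profile`: `count_mean` and `log_mean`
#'   (both K x G), `type_names`, `gene_names`, `n_cells` per type, and
#'   `mean_total` (mean per-cell total counts, the depth-normalisation target
#'   of [correct_spot_expression()]).
#' @export
estimate_type_profiles <- function(counts, labels) {
  if (is.data.frame(labels)) labels <- labels$type
  type_names <- if (is.factor(labels)) levels(labels) else sort(unique(labels))
  labels <- as.character(labels)
  counts <- .as_dense(counts)
  .stop_if(length(labels) != ncol(counts),
           "labels must have one entry per reference cell")
  empty <- setdiff(type_names, labels)
  .stop_if(length(empty) > 0, "empty cell type: ", paste(empty, collapse = ", "))
  totals <- colSums(counts)
  .stop_if(any(totals == 0), "reference contains all-zero cells")
  K <- length(type_names); G <- nrow(counts)
  count_mean <- matrix(0, K, G, dimnames = list(type_names, rownames(counts)))
  log_mean <- count_mean
  rel <- sweep(counts, 2, totals, "/")
  lg <- log1p(counts)
  for (k in seq_len(K)) {
    idx <- which(labels == type_names[k])
    count_mean[k, ] <- rowMeans(rel[, idx, drop = FALSE])
    log_mean[k, ] <- rowMeans(lg[, idx, drop = FALSE])
  }
  structure(list(count_mean = count_mean, log_mean = log_mean,
                 type_names = type_names, gene_names = rownames(counts),
                 n_cells = as.integer(table(factor(labels, type_names))),
                 mean_total = mean(totals)),
            class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf("Reference profile: %d types x %d genes (%s cells)\n",
              length(x$type_names), length(x$gene_names), sum(x$n_cells)))
  cat("  types:", paste(x$type_names, collapse = ", "), "\n")
  cat(sprintf("  mean per-cell total: %.1f counts\n", x$mean_total))
  invisible(x)
}

#' Select highly variable genes plus per-type markers
#'
#' Ranks genes by variance of `log1p` expression after per-cell depth
#' normalisation (to the median total), then adds for every type its top
#' marker genes by log fold change against the mean of the other types.
#'
#' @param counts G x N reference count matrix.
#' @param labels cell-type labels (length N).
#' @param n_hvg number of highly variable genes.
#' @param n_markers markers kept per type.
#' @return Integer vector of gene indices (sorted, unique).
#' @export
select_genes <- function(counts, labels, n_hvg = 1000L, n_markers = 50L) {
  if (is.data.frame(labels)) labels <- labels$type
  counts <- .as_dense(counts)
  totals <- colSums(counts)
  norm <- log1p(sweep(counts, 2, totals / median(totals), "/"))
  v <- apply(norm, 1, var)
  hvg <- order(v, decreasing = TRUE)[seq_len(min(n_hvg, nrow(counts)))]
  type_names <- sort(unique(as.character(labels)))
  means <- vapply(type_names,
                  function(k) rowMeans(norm[, labels == k, drop = FALSE]),
                  numeric(nrow(counts)))
  markers <- integer(0)
  for (k in seq_along(type_names)) {
    lfc <- means[, k] - rowMeans(means[, -k, drop = FALSE])
    markers <- c(markers, order(lfc, decreasing = TRUE)[seq_len(min(n_markers, nrow(counts)))])
  }
  sort(unique(c(hvg, markers)))
}

#' Estimate platform effects linking reference and ST data
#'
#' Follows the pseudo-bulk strategy: all spots are summed into one bulk
#' vector, the overall cell-type weights are obtained by nonnegative least
#' squares of the bulk composition on the profile rows, and the gene effect
#' gamma_g is the log-ratio of observed to fitted bulk counts, shrunk toward
#' zero by the factor `sigma_gamma^2 / (sigma_gamma^2 + 1/fitted_g)` (the
#' Poisson sampling variance of a log count is approximately 1/fitted).
#' `sigma_gamma` is estimated by method of moments from the raw log-ratios;
#' spot effects alpha_i are the per-spot Poisson maximum-likelihood
#' intercepts given the bulk composition; `sigma_eps` matches the excess
#' variance of spot-level log residuals beyond Poisson noise.
#'
#' Genes with zero counts in both the pseudo-bulk and all profiles get
#' `gamma_g = 0` and are recorded in `flagged`.
#'
#' @param spots a [spot_dataset()].
#' @param profile a [reference_profile][estimate_type_profiles()] sharing the
#'   same gene panel (matched by name when both are named).
#' @return Object of class `platform_effects`: `gamma` (length G), `alpha`
#'   (length I), `sigma_eps`, `sigma_gamma`, `bulk_weights` (type weights),
#'   `flagged` (indices of zero-information genes).
#' @export
estimate_platform_effects <- function(spots, profile) {
  stopifnot(inherits(spots, "spot_dataset"), inherits(profile, "reference_profile"))
  Y <- spots$counts
  gn_y <- colnames(Y); gn_p <- profile$gene_names
  if (!is.null(gn_y) && !is.null(gn_p)) {
    .stop_if(!identical(gn_y, gn_p), "gene panels of spots and profile differ")
  } else {
    .stop_if(ncol(Y) != length(profile$gene_names) &&
               ncol(Y) != ncol(profile$count_mean),
             "gene panels of spots and profile differ in size")
  }
  G <- ncol(Y)
  bulk <- colSums(Y)
  A <- t(profile$count_mean)                       # G x K
  w <- pracma::lsqnonneg(A, bulk / sum(bulk))$x
  .stop_if(sum(w) == 0, "nonnegative fit collapsed to zero weights")
  fitted <- as.vector(A %*% w)
  fitted <- fitted / sum(fitted) * sum(bulk)
  flagged <- which(bulk == 0 & fitted < 1e-12)

  r <- log((bulk + 0.5) / (fitted + 0.5))
  pois_var <- 1 / (fitted + 0.5)
  sigma_gamma2 <- max(mean(r^2) - mean(pois_var), 1e-8)
  shrink <- sigma_gamma2 / (sigma_gamma2 + pois_var)
  gamma <- r * shrink
  gamma[flagged] <- 0
  names(gamma) <- gn_y

  # spot intercepts: MLE of exp(alpha_i) given the bulk composition,
  # lambda_ig = exp(alpha_i) * mbar_g * exp(gamma_g),  y_i+ = N_i => closed form
  mbar <- as.vector(A %*% (w / sum(w)))
  denom <- sum(mbar * exp(gamma))
  alpha <- rep(-log(denom), nrow(Y))

  # excess variance of spot-level log residuals beyond Poisson
  E <- outer(spots$umi_totals * exp(alpha), mbar * exp(gamma))
  keep <- E > 5
  if (any(keep)) {
    rr <- log((Y[keep] + 0.5) / (E[keep] + 0.5))
    sigma_eps <- sqrt(max(mean(rr^2) - mean(1 / E[keep]), 0))
  } else sigma_eps <- 0

  structure(list(gamma = gamma, alpha = alpha, sigma_eps = sigma_eps,
                 sigma_gamma = sqrt(sigma_gamma2), bulk_weights = w,
                 flagged = flagged),
            class = "platform_effects")
}

#' @export
print.platform_effects <- function(x, ...) {
  cat(sprintf("Platform effects: %d genes, %d spots\n",
              length(x$gamma), length(x$alpha)))
  cat(sprintf("  gamma sd %.3f (prior sigma_gamma %.3f), sigma_eps %.3f\n",
              sd(x$gamma), x$sigma_gamma, x$sigma_eps))
  if (length(x$flagged)) cat(sprintf("  %d zero-information genes flagged\n",
                                     length(x$flagged)))
  invisible(x)
}

#' Batch-correct a spot expression vector
#'
#' Two-step correction applied before decomposition: divide gene g by
#' `exp(gamma_g)` to remove the gene-level platform effect, then rescale the
#' total to `target_depth` (normally the reference mean per-cell total times
#' the number of cells in the spot) to remove the sequencing-depth
#' difference.
#'
#' @param y length-G nonnegative vector (or I x G matrix, corrected row-wise).
#' @param effects a [platform_effects][estimate_platform_effects()].
#' @param target_depth positive total to rescale to (scalar, or one per row).
#' @return Corrected vector/matrix; totals equal `target_depth`.
#' @export
correct_spot_expression <- function(y, effects, target_depth) {
  stopifnot(inherits(effects, "platform_effects"))
  .stop_if(any(target_depth <= 0), "target_depth must be positive")
  if (is.matrix(y)) {
    .stop_if(any(rowSums(y) == 0), "all-zero spot; filter before correction")
    out <- sweep(y, 2, exp(effects$gamma), "/")
    out * (target_depth / rowSums(out))
  } else {
    .stop_if(sum(y) == 0, "all-zero spot; filter before correction")
    out <- y / exp(effects$gamma)
    out * (target_depth / sum(out))
  }
}
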