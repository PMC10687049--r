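#' Cosine similarity between two vectors
#'
#' @param a,b numeric vectors of equal length.
#' @return Scalar in \[-1, 1\]; `NA` if either vector is all zero.
#' @export
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Row-wise cosine similarity between two matrices
#'
#' @param A,B numeric matrices of identical dimension; similarity is computed
#'   between corresponding rows.
#' @return Numeric vector of length `nrow(A)`.
#' @export
cosine_rows <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  vapply(seq_len(nrow(A)), function(i) cosine_sim(A[i, ], B[i, ]), numeric(1))
}

# log(sum(exp(x))) along rows of a matrix, guarded against -Inf rows
.row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  bad <- !is.finite(mx)
  out <- mx + log(rowSums(exp(m - ifelse(bad, 0, mx))))
  out[bad] <- -Inf
  out
}

.is_count_matrix <- function(m) {
  x <- if (inherits(m, "sparseMatrix")) m@x else as.numeric(m)
  all(is.finite(x)) && all(x >= 0) && all(x == round(x))
}

.stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

# dense numeric matrix view, keeping dimnames
.as_dense <- function(m) {
  if (inherits(m, "sparseMatrix")) as.matrix(m) else m
}
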