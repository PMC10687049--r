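#' Spot-level spatial expression dataset
#'
#' Container for spot-level ST data: an I x G integer count matrix, per-spot
#' UMI totals, spatial coordinates (with slice id for multi-slice data) and
#' the per-spot cell count from external segmentation.
#'
#' @param counts I x G integer matrix (spots in rows, genes in columns).
#' @param coords data.frame with columns `spot_id`, `x`, `y` and optionally
#'   `slice` (defaults to 1).
#' @param cell_counts integer vector of cells per spot (M_i >= 1).
#' @return Object of class `spot_dataset` with elements `counts`,
#'   `umi_totals`, `coords`, `cell_counts`.
#' @export
spot_dataset <- function(counts, coords, cell_counts) {
  counts <- .as_dense(counts)
  .stop_if(!.is_count_matrix(counts), "counts must be nonnegative integers")
  I <- nrow(counts)
  .stop_if(!all(c("spot_id", "x", "y") %in% names(coords)),
           "coords needs columns spot_id, x, y")
  if (is.null(coords$slice)) coords$slice <- 1L
  .stop_if(nrow(coords) != I, "coords must have one row per spot")
  cell_counts <- as.integer(cell_counts)
  .stop_if(length(cell_counts) != I || any(cell_counts < 1L),
           "cell_counts must be >= 1 for every spot")
  key <- paste(coords$x, coords$y, coords$slice)
  .stop_if(anyDuplicated(key) > 0, "duplicate spot coordinates within a slice")
  structure(list(counts = counts, umi_totals = rowSums(counts),
                 coords = coords, cell_counts = cell_counts),
            class = "spot_dataset")
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat(sprintf("Spot dataset: %d spots x %d genes, %d slice(s)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$coords$slice))))
  cat(sprintf("  median UMI/spot %.0f, cells/spot %d-%d (total %d cells)\n",
              median(x$umi_totals), min(x$cell_counts), max(x$cell_counts),
              sum(x$cell_counts)))
  invisible(x)
}
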