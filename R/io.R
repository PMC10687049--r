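#' Read an expression matrix with gene and sample names
#'
#' Supported formats: Matrix Market (`.mtx` with `<base>.genes.tsv` and
#' `<base>.cells.tsv` sidecars, genes in rows) and dense CSV/TSV (first
#' column gene names, header = sample names). Integer counts and name order
#' are preserved exactly; writing with [write_expression_matrix()] and
#' reading back is the identity.
#'
#' @param path file path; format inferred from the extension when
#'   `format = "auto"`.
#' @param format `"auto"`, `"mtx"`, `"csv"` or `"tsv"`.
#' @return List: `counts` (dense G x N matrix with dimnames), `genes`,
#'   `cells`, and `labels` (cell-type column of the cells sidecar, or `NULL`).
#' @export
load_expression_matrix <- function(path, format = c("auto", "mtx", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     stop("cannot infer format of ", path, call. = FALSE))
  }
  .stop_if(!file.exists(path), "file not found: ", path)
  if (format == "mtx") {
    base <- sub("\\.mtx$", "", path)
    m <- as.matrix(Matrix::readMM(path))
    gf <- paste0(base, ".genes.tsv"); cf <- paste0(base, ".cells.tsv")
    .stop_if(!file.exists(gf) || !file.exists(cf),
             "missing sidecar files ", gf, " / ", cf)
    genes <- read.table(gf, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    cells <- read.table(cf, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    .stop_if(nrow(genes) != nrow(m),
             sprintf("gene sidecar has %d rows but matrix has %d", nrow(genes), nrow(m)))
    .stop_if(nrow(cells) != ncol(m),
             sprintf("cell sidecar has %d rows but matrix has %d columns",
                     nrow(cells), ncol(m)))
    dimnames(m) <- list(genes$gene, cells$cell)
    storage.mode(m) <- "integer"
    return(list(counts = m, genes = genes$gene, cells = cells$cell,
                labels = cells$type))
  }
  sep <- if (format == "csv") "," else "\t"
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  body <- read.table(path, sep = sep, header = TRUE, row.names = 1L,
                     check.names = FALSE, stringsAsFactors = FALSE)
  .stop_if(length(header) != ncol(body) + 1L,
           sprintf("header has %d fields but rows have %d",
                   length(header), ncol(body) + 1L))
  m <- as.matrix(body)
  .stop_if(!.is_count_matrix(m), "non-integer or negative entries in ", path)
  storage.mode(m) <- "integer"
  list(counts = m, genes = rownames(m), cells = colnames(m), labels = NULL)
}

#' @rdname load_expression_matrix
#' @param counts G x N matrix with gene rownames and cell colnames.
#' @param labels optional cell-type vector written into the cells sidecar.
#' @export
write_expression_matrix <- function(counts, path,
                                    format = c("auto", "mtx", "csv", "tsv"),
                                    labels = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv",
                     stop("cannot infer format of ", path, call. = FALSE))
  }
  counts <- .as_dense(counts)
  .stop_if(is.null(rownames(counts)) || is.null(colnames(counts)),
           "counts must have gene rownames and cell colnames")
  if (format == "mtx") {
    base <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    write.table(data.frame(gene = rownames(counts)),
                paste0(base, ".genes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    cells <- data.frame(cell = colnames(counts))
    if (!is.null(labels)) cells$type <- labels
    write.table(cells, paste0(base, ".cells.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read/write a spot dataset
#'
#' The counts go through [write_expression_matrix()] (spots as "cells"); the
#' spot table `<base>.spots.tsv` holds `spot_id`, `x`, `y`, `slice`,
#' `n_cells`, `total_umi`.
#'
#' @param spots a [spot_dataset()].
#' @param base path prefix; files `<base>.mtx`, `<base>.genes.tsv`,
#'   `<base>.cells.tsv`, `<base>.spots.tsv`.
#' @return `load_spot_dataset()` returns a [spot_dataset()];
#'   `write_spot_dataset()` returns `base` invisibly.
#' @export
write_spot_dataset <- function(spots, base) {
  stopifnot(inherits(spots, "spot_dataset"))
  write_expression_matrix(t(spots$counts), paste0(base, ".mtx"), "mtx")
  tab <- data.frame(spot_id = spots$coords$spot_id, x = spots$coords$x,
                    y = spots$coords$y, slice = spots$coords$slice,
                    n_cells = spots$cell_counts, total_umi = spots$umi_totals)
  write.table(tab, paste0(base, ".spots.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(base)
}

#' @rdname write_spot_dataset
#' @export
load_spot_dataset <- function(base) {
  m <- load_expression_matrix(paste0(base, ".mtx"))
  tab <- read.table(paste0(base, ".spots.tsv"), sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  .stop_if(nrow(tab) != ncol(m$counts), "spot table does not match matrix")
  spot_dataset(counts = t(m$counts),
               coords = tab[, c("spot_id", "x", "y", "slice")],
               cell_counts = tab$n_cells)
}
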