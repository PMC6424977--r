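#' Single-cell count container
#'
#' A light container holding a sparse genes x barcodes UMI count matrix
#' together with a gene annotation table and per-barcode metadata. All
#' downstream functions take either this container or a bare matrix.
#'
#' @param counts sparse (or dense) numeric matrix, genes in rows, barcodes
#'   in columns. Row and column names are required and must be unique.
#' @param genes tibble of gene annotation with at least `gene_id`; typically
#'   also `symbol`, `chrom`, `start`, `end`, `strand` and `class`
#'   (one of `"autosome"`, `"X"`, `"Y"`, `"MT"`). Row order must match
#'   `rownames(counts)`.
#' @param cells tibble of per-barcode metadata with at least `barcode`,
#'   matching `colnames(counts)`.
#'
#' @return An object of class `sperm_counts`.
#' @export
sperm_counts <- function(counts, genes = NULL, cells = NULL) {
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
    "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene and barcode names")
  }
  if (anyDuplicated(colnames(counts))) stop("duplicate identifiers: barcodes")
  if (anyDuplicated(rownames(counts))) stop("duplicate identifiers: genes")
  if (any(counts@x < 0)) stop("negative entries in count matrix")
  if (is.null(genes)) genes <- tibble::tibble(gene_id = rownames(counts))
  if (is.null(cells)) cells <- tibble::tibble(barcode = colnames(counts))
  stopifnot(identical(genes$gene_id, rownames(counts)),
            identical(cells$barcode, colnames(counts)))
  structure(list(counts = counts, genes = genes, cells = cells),
            class = "sperm_counts")
}

#' @export
dim.sperm_counts <- function(x) dim(x$counts)

#' @method print sperm_counts
#' @export
print.sperm_counts <- function(x, ...) {
  cat(sprintf("<sperm_counts> %d genes x %d barcodes\n", nrow(x$counts), ncol(x$counts)))
  cls <- table(x$genes$class)
  if (length(cls)) cat("  gene classes:", paste(names(cls), cls, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
`[.sperm_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(i)) i <- match(i, rownames(x$counts))
  if (is.character(j)) j <- match(j, colnames(x$counts))
  sperm_counts(x$counts[i, j, drop = FALSE],
               x$genes[i, , drop = FALSE],
               x$cells[j, , drop = FALSE])
}

#' Read a droplet count matrix from MatrixMarket + TSV sidecars
#'
#' Reads the de facto droplet interchange triple: an MTX file of UMI counts
#' (genes x barcodes), a barcode TSV (one barcode per line, optional
#' metadata columns with header) and a feature TSV
#' (`gene_id`, `symbol`, `chrom`, `start`, `end`, `strand`, `class`).
#'
#' @param mtx,barcodes,features file paths.
#' @return A [sperm_counts] object.
#' @export
read_counts <- function(mtx, barcodes, features) {
  for (f in c(mtx, barcodes, features)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  m <- Matrix::readMM(mtx)
  # readMM may return a symmetric/triangular class whose invariants
  # forbid distinct row and column names
  m <- methods::as(m, "generalMatrix")
  bc <- readr::read_tsv(barcodes, show_col_types = FALSE,
                        col_names = grepl("^barcode\\b", readLines(barcodes, n = 1L)))
  if (!"barcode" %in% names(bc)) names(bc)[1] <- "barcode"
  ft <- readr::read_tsv(features, show_col_types = FALSE,
                        col_names = grepl("^gene_id\\b", readLines(features, n = 1L)))
  if (!"gene_id" %in% names(ft)) {
    names(ft)[seq_len(min(7, ncol(ft)))] <-
      c("gene_id", "symbol", "chrom", "start", "end", "strand", "class")[seq_len(min(7, ncol(ft)))]
  }
  if (nrow(m) != nrow(ft) || ncol(m) != nrow(bc)) {
    stop("dimension mismatch between matrix and annotation files")
  }
  if (anyDuplicated(bc$barcode) || anyDuplicated(ft$gene_id)) {
    stop("duplicate identifiers")
  }
  dimnames(m) <- list(ft$gene_id, bc$barcode)
  sperm_counts(m, tibble::as_tibble(ft), tibble::as_tibble(bc))
}

#' Write a count matrix as MTX + sidecar TSVs
#'
#' @param x a [sperm_counts] object.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_counts <- function(x, dir, prefix = "") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("matrix.mtx", "barcodes.tsv", "features.tsv")))
  Matrix::writeMM(x$counts, paths[1])
  readr::write_tsv(x$cells, paths[2])
  readr::write_tsv(x$genes, paths[3])
  invisible(paths)
}

# dense numeric matrix view (genes x cells); used by statistics that need it
as_dense <- function(x) {
  if (inherits(x, "sperm_counts")) x <- x$counts
  as.matrix(x)
}
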