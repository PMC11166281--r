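#' Validate a sparse gene-by-cell count matrix
#'
#' Checks the container invariants: a sparse matrix of non-negative integer
#' UMI counts whose row (gene) and column (barcode) names are unique and
#' match the matrix dimensions.
#'
#' @param counts A `Matrix::dgCMatrix` (or coercible matrix), genes in rows,
#'   cells in columns, with `dimnames` set.
#' @return The validated matrix as a `dgCMatrix`, invisibly usable downstream.
#' @export
validate_counts <- function(counts) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must carry gene and barcode dimnames", call. = FALSE)
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("gene IDs and barcodes must be unique", call. = FALSE)
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("count matrix entries must be non-negative integers", call. = FALSE)
  counts
}

#' Read a 10x-style Matrix Market count matrix
#'
#' Reads a coordinate MTX file plus the accompanying one-column gene and
#' barcode TSV files (first column used as identifier).
#'
#' @param matrix_path Path to the `.mtx` file.
#' @param genes_path Path to the gene TSV (no header; first column = gene ID).
#' @param barcodes_path Path to the barcode TSV (no header).
#' @return A validated `dgCMatrix` with genes in rows and cells in columns.
#' @examples
#' d <- tempfile(); dir.create(d)
#' m <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(5, 7), dims = c(3, 2))
#' dimnames(m) <- list(paste0("g", 1:3), paste0("bc", 1:2))
#' write_counts(m, d)
#' m2 <- read_counts(file.path(d, "matrix.mtx"), file.path(d, "genes.tsv"),
#'                   file.path(d, "barcodes.tsv"))
#' all(m2 == m)
#' @export
read_counts <- function(matrix_path, genes_path, barcodes_path) {
  for (p in c(matrix_path, genes_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  m <- Matrix::readMM(matrix_path)
  genes <- utils::read.table(genes_path, sep = "\t", header = FALSE,
                             colClasses = "character")[[1]]
  barcodes <- utils::read.table(barcodes_path, sep = "\t", header = FALSE,
                                colClasses = "character")[[1]]
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
    stop("MTX dimensions (", nrow(m), "x", ncol(m),
         ") do not match gene/barcode lists (", length(genes), "/",
         length(barcodes), ")", call. = FALSE)
  dimnames(m) <- list(genes, barcodes)
  validate_counts(m)
}

#' Write a count matrix as MTX plus gene/barcode TSVs
#'
#' Writes the 10x convention: a 1-based coordinate Matrix Market file with
#' the `integer` field and `general` symmetry, plus `genes.tsv` and
#' `barcodes.tsv`. Inverse of [read_counts()].
#'
#' @param counts Validated count matrix (genes x cells).
#' @param dir Output directory (created if missing).
#' @param prefix Optional filename prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_counts <- function(counts, dir, prefix = "") {
  counts <- validate_counts(counts)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mp <- file.path(dir, paste0(prefix, "matrix.mtx"))
  gp <- file.path(dir, paste0(prefix, "genes.tsv"))
  bp <- file.path(dir, paste0(prefix, "barcodes.tsv"))
  tm <- methods::as(counts, "TsparseMatrix")
  # integer-field MTX dialect (Matrix::writeMM would emit a `real` header)
  con <- file(mp, open = "wb")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(nrow(counts), ncol(counts), length(tm@x))), con)
  if (length(tm@x)) {
    o <- order(tm@j, tm@i)
    writeLines(paste(tm@i[o] + 1L, tm@j[o] + 1L,
                     format(tm@x[o], scientific = FALSE, trim = TRUE)), con)
  }
  writeLines(rownames(counts), gp)
  writeLines(colnames(counts), bp)
  invisible(c(matrix = mp, genes = gp, barcodes = bp))
}

#' Read a gene annotation table
#'
#' @param path TSV with header columns `gene_id`, `symbol`, `chromosome`,
#'   `start`, `is_mito`.
#' @return A tibble, validated (unique gene IDs, `start >= 1`, non-empty
#'   chromosome labels).
#' @export
read_gene_table <- function(path) {
  g <- tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                           stringsAsFactors = FALSE))
  validate_gene_table(g)
}

#' @rdname read_gene_table
#' @param genes A gene table to validate.
#' @export
validate_gene_table <- function(genes) {
  need <- c("gene_id", "symbol", "chromosome", "start", "is_mito")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id", call. = FALSE)
  if (any(genes$start < 1)) stop("gene start positions must be >= 1", call. = FALSE)
  if (any(!nzchar(genes$chromosome))) stop("empty chromosome label", call. = FALSE)
  genes$is_mito <- as.logical(genes$is_mito)
  tibble::as_tibble(genes)
}

#' Read a per-cell metadata table
#'
#' @param path TSV with header; must contain `barcode`, `patient`, `tissue`
#'   (`Normal`/`Tumor`) and `method` (`cell`/`nucleus`/`immune_depleted`).
#' @return A tibble with one row per barcode.
#' @export
read_cell_table <- function(path) {
  ct <- tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                            stringsAsFactors = FALSE))
  need <- c("barcode", "patient", "tissue", "method")
  miss <- setdiff(need, names(ct))
  if (length(miss)) stop("cell table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ct$barcode)) stop("duplicate barcodes", call. = FALSE)
  bad <- setdiff(unique(ct$tissue), c("Normal", "Tumor"))
  if (length(bad)) stop("unknown tissue level(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(unique(ct$method), c("cell", "nucleus", "immune_depleted"))
  if (length(bad)) stop("unknown method level(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  ct
}
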