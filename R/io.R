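#' Read a count matrix with gene and spot labels
#'
#' Reads a genes x spots count matrix from either a MatrixMarket triplet file
#' (`.mtx`) accompanied by one-column gene and spot label files, or from a
#' dense CSV with gene rows, spot columns, a header of spot ids and gene ids
#' in the first column (label files then optional and used for validation).
#'
#' @param matrix_path path to the `.mtx` or `.csv` matrix file.
#' @param genes_path path to a one-gene-per-line label file (required for
#'   `.mtx`, optional cross-check for CSV).
#' @param spots_path path to a one-spot-per-line label file (same rules).
#' @param coords optional coordinate table as returned by [read_coords()]; if
#'   supplied, an [st_dataset] is returned, otherwise a labelled matrix.
#' @param transpose set `TRUE` when the file stores spots x genes; the matrix
#'   is transposed to the internal genes x spots orientation.
#' @return A labelled count matrix, or an [st_dataset] when `coords` is given.
#' @export
read_counts <- function(matrix_path, genes_path = NULL, spots_path = NULL,
                        coords = NULL, transpose = FALSE) {
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) {
    m <- tryCatch(Matrix::readMM(matrix_path),
                  error = function(e) stop("malformed MatrixMarket file: ",
                                           conditionMessage(e)))
    m <- methods::as(m, "CsparseMatrix")
    if (is.null(genes_path) || is.null(spots_path))
      stop("gene and spot label files are required with a .mtx matrix")
    genes <- readLines(genes_path)
    spots <- readLines(spots_path)
  } else {
    tab <- utils::read.csv(matrix_path, row.names = 1, check.names = FALSE)
    if (nrow(tab) == 0 || ncol(tab) == 0) stop("empty matrix file")
    m <- as.matrix(tab)
    genes <- if (is.null(genes_path)) rownames(m) else readLines(genes_path)
    spots <- if (is.null(spots_path)) colnames(m) else readLines(spots_path)
    if (!is.null(genes_path) && !identical(rownames(m), genes))
      stop("gene labels in CSV disagree with the gene label file")
    if (!is.null(spots_path) && !identical(colnames(m), spots))
      stop("spot labels in CSV disagree with the spot label file")
  }
  if (transpose) {
    m <- Matrix::t(m)
    tmp <- genes; genes <- spots; spots <- tmp
  }
  if (length(genes) != nrow(m) || length(spots) != ncol(m))
    stop(sprintf("label/matrix dimension mismatch: %d x %d matrix, %d genes, %d spots",
                 nrow(m), ncol(m), length(genes), length(spots)))
  dimnames(m) <- list(genes, spots)
  .check_counts(m)
  if (!is.null(coords)) return(st_dataset(m, genes, spots, coords))
  m
}

#' Read a spot coordinate table
#'
#' Reads a CSV/TSV with columns `spot_id`, `x` (row coordinate) and `y`
#' (column coordinate).
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (`.tsv`/`.txt` -> tab, otherwise comma).
#' @return data.frame with columns `spot_id`, `x`, `y`.
#' @export
read_coords <- function(path) {
  if (!file.exists(path)) stop("coordinate file not found: ", path)
  tab <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE))
    utils::read.delim(path) else utils::read.csv(path)
  need <- c("spot_id", "x", "y")
  if (!all(need %in% names(tab)))
    stop("coordinate file must have columns spot_id, x, y")
  tab <- tab[need]
  tab$spot_id <- as.character(tab$spot_id)
  if (anyDuplicated(tab$spot_id)) stop("duplicated spot_id in coordinate file")
  if (anyNA(tab$x) || anyNA(tab$y)) stop("missing coordinate value")
  if (!is.numeric(tab$x) || !is.numeric(tab$y))
    stop("coordinates must be numeric")
  tab
}

#' Read a 10X Visium-style directory
#'
#' Expects `matrix.mtx`, `features.tsv` (gene ids in the first column),
#' `barcodes.tsv`, and a `tissue_positions_list.csv` mapping each barcode to
#' its array row/column (columns: barcode, in_tissue, array_row, array_col,
#' ... ; no header, as emitted by Space Ranger v1).
#'
#' @param dir directory containing the four files.
#' @return An [st_dataset] restricted to in-tissue spots.
#' @export
read_visium <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  feat <- file.path(dir, "features.tsv")
  bc <- file.path(dir, "barcodes.tsv")
  pos <- file.path(dir, "tissue_positions_list.csv")
  for (f in c(mtx, feat, bc, pos))
    if (!file.exists(f)) stop("missing Visium file: ", f)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  genes <- utils::read.delim(feat, header = FALSE)[[1]]
  barcodes <- readLines(bc)
  p <- utils::read.csv(pos, header = FALSE)
  names(p)[1:4] <- c("barcode", "in_tissue", "array_row", "array_col")
  p <- p[p$in_tissue == 1, ]
  keep <- match(p$barcode, barcodes)
  if (anyNA(keep)) stop("tissue positions refer to unknown barcodes")
  co <- data.frame(spot_id = p$barcode, x = p$array_row, y = p$array_col)
  st_dataset(m[, keep, drop = FALSE], genes, p$barcode, co)
}

#' Write an st_dataset (or simulation) to disk in plain-text formats
#'
#' Writes `matrix.mtx`, `genes.txt`, `spots.txt` and `coords.csv` into `dir`;
#' for a simulation ([simulate_dataset()]) additionally writes `truth.tsv`
#' with columns `gene_id`, `is_svg`.
#'
#' @param x an [st_dataset] or `sim_truth` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(x, dir) {
  truth <- NULL
  if (inherits(x, "sim_truth")) {
    truth <- data.frame(gene_id = x$dataset$gene_ids, is_svg = x$is_svg)
    x <- x$dataset
  }
  stopifnot(inherits(x, "st_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(x$counts, "dMatrix"),
                              "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(x$gene_ids, file.path(dir, "genes.txt"))
  writeLines(x$spot_ids, file.path(dir, "spots.txt"))
  utils::write.csv(x$coords, file.path(dir, "coords.csv"), row.names = FALSE)
  if (!is.null(truth))
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read back a directory written by write_dataset
#'
#' @param dir directory containing `matrix.mtx`, `genes.txt`, `spots.txt`,
#'   `coords.csv`.
#' @return An [st_dataset].
#' @export
read_dataset <- function(dir) {
  read_counts(file.path(dir, "matrix.mtx"),
              file.path(dir, "genes.txt"),
              file.path(dir, "spots.txt"),
              coords = read_coords(file.path(dir, "coords.csv")))
}

#' Write an SVG results table as TSV
#'
#' @param results data.frame from [detect_svg()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  write.table(results, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
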