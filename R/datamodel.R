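#' Spatial transcriptomics dataset
#'
#' Container for a genes x spots count matrix together with per-spot spatial
#' coordinates. Each gene at each spot is the triple (x, y, e): the row
#' coordinate, the column coordinate, and the raw expression count. Counts are
#' kept on the raw integer scale; the downstream test is distribution-free and
#' is defined on counts, so normalized input is rejected rather than rounded.
#'
#' @param counts genes x spots matrix of non-negative integer counts; a base
#'   matrix or a sparse [Matrix::Matrix]. Row/column names, when present, must
#'   agree with `gene_ids` / `spot_ids`.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   `rownames(counts)`).
#' @param spot_ids character vector of unique spot identifiers (defaults to
#'   `colnames(counts)`).
#' @param coords data.frame with columns `spot_id`, `x` (row coordinate) and
#'   `y` (column coordinate), one row per spot; rows may be in any order and
#'   are matched to `spot_ids` by `spot_id`.
#' @return An object of class `st_dataset`: a list with elements `counts`,
#'   `gene_ids`, `spot_ids` and `coords` (reordered to the spot order of the
#'   matrix).
#' @examples
#' cnt <- matrix(rpois(12, 1), 3, 4,
#'               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' co <- data.frame(spot_id = paste0("s", 1:4),
#'                  x = c(0, 0, 1, 1), y = c(0, 1, 0, 1))
#' ds <- st_dataset(cnt, coords = co)
#' ds
#' @export
st_dataset <- function(counts, gene_ids = rownames(counts),
                       spot_ids = colnames(counts), coords) {
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(ncol(counts)))
  gene_ids <- as.character(gene_ids)
  spot_ids <- as.character(spot_ids)
  if (length(gene_ids) != nrow(counts) || length(spot_ids) != ncol(counts))
    stop("counts must have shape (length(gene_ids), length(spot_ids))")
  if (anyDuplicated(gene_ids)) stop("gene_ids contain duplicates")
  if (anyDuplicated(spot_ids)) stop("spot_ids contain duplicates")
  .check_counts(counts)
  coords <- .check_coords(coords, spot_ids)
  structure(list(counts = counts, gene_ids = gene_ids, spot_ids = spot_ids,
                 coords = coords),
            class = "st_dataset")
}

.check_counts <- function(counts) {
  vals <- if (inherits(counts, "sparseMatrix")) counts@x else counts
  if (length(vals)) {
    if (anyNA(vals)) stop("counts contain missing values")
    if (min(vals) < 0) stop("counts contain negative entries")
    if (!is.integer(vals) && any(vals != floor(vals)))
      stop("counts are not integers; the method is defined on raw counts ",
           "and normalized input is rejected")
  }
  invisible(counts)
}

.check_coords <- function(coords, spot_ids) {
  coords <- as.data.frame(coords)
  need <- c("spot_id", "x", "y")
  if (!all(need %in% names(coords)))
    stop("coords must have columns spot_id, x, y")
  coords <- coords[need]
  coords$spot_id <- as.character(coords$spot_id)
  if (anyDuplicated(coords$spot_id)) stop("duplicated spot_id in coords")
  if (anyNA(coords)) stop("missing values in coords")
  if (!setequal(coords$spot_id, spot_ids))
    stop("coords must contain exactly one (x, y) pair per spot_id")
  coords <- coords[match(spot_ids, coords$spot_id), , drop = FALSE]
  rownames(coords) <- NULL
  coords
}

#' @export
print.st_dataset <- function(x, ...) {
  cat(sprintf("st_dataset: %d genes x %d spots\n",
              length(x$gene_ids), length(x$spot_ids)))
  cat(sprintf("  x range: [%.3g, %.3g]   y range: [%.3g, %.3g]\n",
              min(x$coords$x), max(x$coords$x),
              min(x$coords$y), max(x$coords$y)))
  nz <- if (inherits(x$counts, "sparseMatrix")) length(x$counts@x)
        else sum(x$counts != 0)
  cat(sprintf("  nonzero entries: %d (%.1f%%)\n", nz,
              100 * nz / (length(x$gene_ids) * length(x$spot_ids))))
  invisible(x)
}

#' @export
dim.st_dataset <- function(x) c(length(x$gene_ids), length(x$spot_ids))

#' Subset an st_dataset by gene and/or spot
#'
#' @param x an [st_dataset].
#' @param genes gene identifiers or indices to keep (default all).
#' @param spots spot identifiers or indices to keep (default all).
#' @return The subsetted `st_dataset`.
#' @export
subset_genes <- function(x, genes = NULL, spots = NULL) {
  stopifnot(inherits(x, "st_dataset"))
  gi <- if (is.null(genes)) seq_along(x$gene_ids)
        else if (is.character(genes)) match(genes, x$gene_ids) else genes
  si <- if (is.null(spots)) seq_along(x$spot_ids)
        else if (is.character(spots)) match(spots, x$spot_ids) else spots
  if (anyNA(gi)) stop("unknown gene ids")
  if (anyNA(si)) stop("unknown spot ids")
  st_dataset(x$counts[gi, si, drop = FALSE], x$gene_ids[gi], x$spot_ids[si],
             x$coords[si, , drop = FALSE])
}

#' Filter genes detected in too few spots
#'
#' Quality control used before SVG testing: genes detected (nonzero) in less
#' than a minimum fraction of spots are excluded. The boundary is inclusive:
#' a gene whose detection fraction equals `min_fraction` is kept, genes
#' strictly below are dropped.
#'
#' @param ds an [st_dataset].
#' @param min_fraction minimum detection fraction in \[0, 1\] (default 0.01,
#'   i.e. the conventional 1%-of-spots rule).
#' @return A list with elements `dataset` (the filtered [st_dataset]) and
#'   `report`, a `qc_report` list with fields `n_genes_in`, `n_genes_kept`,
#'   `dropped_gene_ids` and `min_detection_fraction`.
#' @examples
#' co <- data.frame(spot_id = as.character(1:100), x = runif(100), y = runif(100))
#' cnt <- rbind(rep(0:1, c(99, 1)), rep(1L, 100))
#' rownames(cnt) <- c("rare", "common"); colnames(cnt) <- co$spot_id
#' out <- filter_low_quality_genes(st_dataset(cnt, coords = co), 0.05)
#' out$report
#' @export
filter_low_quality_genes <- function(ds, min_fraction = 0.01) {
  stopifnot(inherits(ds, "st_dataset"))
  if (!is.numeric(min_fraction) || min_fraction < 0 || min_fraction > 1)
    stop("min_fraction must be in [0, 1]")
  det <- Matrix::rowSums(ds$counts > 0) / length(ds$spot_ids)
  keep <- det >= min_fraction
  report <- structure(list(
    n_genes_in = length(ds$gene_ids),
    n_genes_kept = sum(keep),
    dropped_gene_ids = ds$gene_ids[!keep],
    min_detection_fraction = min_fraction), class = "qc_report")
  if (!any(keep))
    warning("all genes dropped by QC filter")
  list(dataset = subset_genes(ds, genes = which(keep)), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: kept %d / %d genes (detection fraction >= %g)\n",
              x$n_genes_kept, x$n_genes_in, x$min_detection_fraction))
  if (length(x$dropped_gene_ids))
    cat("  dropped:", paste(head(x$dropped_gene_ids, 5), collapse = ", "),
        if (length(x$dropped_gene_ids) > 5) "..." else "", "\n")
  invisible(x)
}
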