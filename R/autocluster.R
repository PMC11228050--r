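# Auto-clustering of detected SVGs: pairwise spatial-profile similarity,
# complete-linkage hierarchical clustering, a breakpoint (Yamamoto-type) cut
# of the dendrogram, and per-cluster spatial-domain prediction.

#' Pairwise distance between genes' spatial expression profiles
#'
#' Each gene is binned onto a common 2D grid (mean expression per occupied
#' cell, so the spot-density profile shared by all genes cancels; empty cells
#' are dropped) and the distance between two genes is `1 - Pearson
#' correlation` of their flattened binned profiles, giving a symmetric matrix
#' with zero diagonal and range \[0, 2\]. Correlation is scale-invariant, so
#' genes with the same spatial pattern but different expression magnitudes
#' are close. A constant profile carries no spatial information and is placed
#' at distance 1 from everything.
#'
#' @param ds an [st_dataset] restricted to the genes of interest (at least 2).
#' @param genes optional gene ids/indices to restrict to.
#' @param grid_bins bins per axis for the common grid (default
#'   `max(4, round(n_spots^0.25))`).
#' @return A `dist`-convertible symmetric matrix of distances.
#' @export
gene_similarity <- function(ds, genes = NULL, grid_bins = NULL) {
  stopifnot(inherits(ds, "st_dataset"))
  if (!is.null(genes)) ds <- subset_genes(ds, genes = genes)
  g <- length(ds$gene_ids)
  if (g < 2) stop("at least 2 genes are required")
  n <- length(ds$spot_ids)
  nb <- grid_bins %||% max(4L, round(n^0.25))
  bx <- build_bins(ds$coords$x, nb)
  by <- build_bins(ds$coords$y, nb)
  cell <- (as.integer(bx) - 1L) * nb + as.integer(by)
  B <- Matrix::sparseMatrix(i = seq_len(n), j = cell, x = 1,
                            dims = c(n, nb * nb))
  occ <- Matrix::colSums(B)
  B <- B[, occ > 0, drop = FALSE]
  prof <- as.matrix(ds$counts %*% B)  # genes x occupied grid cells
  prof <- sweep(prof, 2, occ[occ > 0], "/")  # mean per cell
  sds <- apply(prof, 1, sd)
  D <- matrix(1, g, g, dimnames = list(ds$gene_ids, ds$gene_ids))
  ok <- sds > 0
  if (sum(ok) >= 2)
    D[ok, ok] <- 1 - cor(t(prof[ok, , drop = FALSE]))
  diag(D) <- 0
  D
}

#' Build a complete-linkage dendrogram from a gene distance matrix
#'
#' @param dist_mat symmetric distance matrix (e.g. from [gene_similarity()]).
#' @return An [stats::hclust] tree (complete linkage); `$height` holds the
#'   non-decreasing merge heights.
#' @export
build_dendrogram <- function(dist_mat) {
  hclust(as.dist(dist_mat), method = "complete")
}

#' Choose a dendrogram cut height by breakpoint detection
#'
#' Scans every breakpoint of the ordered merge-height series and computes the
#' signal-to-noise ratio of the mean shift,
#' `SNR = |mean_after - mean_before| / (sd_before + sd_after)` (the Yamamoto
#' convention, with qualification threshold `SNR >= 1`). The cut is placed
#' between the two heights at the qualifying breakpoint with maximum SNR;
#' when no breakpoint qualifies (or fewer than 4 heights are available), the
#' fallback is the midpoint of the largest consecutive height gap.
#'
#' @param merge_heights numeric vector of dendrogram merge heights
#'   (non-decreasing, as from `hclust()$height`).
#' @param snr_threshold qualification threshold (default 1).
#' @return The cut height (scalar), with attributes `breakpoint` (index of
#'   the last height before the cut) and `snr` (its SNR, `NA` on the
#'   fallback path).
#' @export
yamamoto_cut <- function(merge_heights, snr_threshold = 1) {
  h <- sort(as.numeric(merge_heights))
  nh <- length(h)
  if (nh < 2) stop("at least 2 merge heights are required")
  fallback <- function() {
    gaps <- diff(h)
    b <- which.max(gaps)
    structure((h[b] + h[b + 1]) / 2, breakpoint = b, snr = NA_real_)
  }
  if (nh < 4) return(fallback())
  best_b <- NA_integer_; best_snr <- -Inf
  # >= 2 heights before the break so its sd exists; the trailing segment may
  # be a single height (sd taken as 0), so a cut just below the final merge
  # -- the two-cluster solution -- remains reachable
  for (b in 2:(nh - 1)) {
    before <- h[1:b]; after <- h[(b + 1):nh]
    sd_after <- if (length(after) > 1) sd(after) else 0
    denom <- sd(before) + sd_after
    shift <- abs(mean(after) - mean(before))
    snr <- if (denom == 0) { if (shift > 0) Inf else 0 } else shift / denom
    if (snr > best_snr) { best_snr <- snr; best_b <- b }
  }
  if (best_snr >= snr_threshold)
    structure((h[best_b] + h[best_b + 1]) / 2, breakpoint = best_b,
              snr = best_snr)
  else fallback()
}

#' Cluster SVGs by spatial-profile similarity
#'
#' Runs [gene_similarity()], [build_dendrogram()] and [yamamoto_cut()], then
#' extracts cluster labels at the chosen height.
#'
#' @param ds an [st_dataset].
#' @param genes gene ids/indices of the SVGs to cluster (default: all genes
#'   of `ds`).
#' @param grid_bins passed to [gene_similarity()].
#' @return A `cluster_result` list with `labels` (named integer vector),
#'   `merge_heights`, `cut_height`, `n_clusters` and the `tree`.
#' @export
cluster_svgs <- function(ds, genes = NULL, grid_bins = NULL) {
  D <- gene_similarity(ds, genes = genes, grid_bins = grid_bins)
  tree <- build_dendrogram(D)
  cut <- yamamoto_cut(tree$height)
  labels <- cutree(tree, h = as.numeric(cut))
  structure(list(labels = labels, merge_heights = tree$height,
                 cut_height = as.numeric(cut),
                 n_clusters = length(unique(labels)), tree = tree),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d genes in %d clusters (cut height %.3g)\n",
              length(x$labels), x$n_clusters, x$cut_height))
  print(table(x$labels))
  invisible(x)
}

#' Predict spatial domains from SVG clusters
#'
#' For each cluster, member genes' spatial profiles (each gene scaled by its
#' total count so highly expressed genes do not dominate) are averaged per
#' spot, smoothed over the `k` nearest spatial neighbours, and spots above
#' the `threshold_quantile` of the smoothed profile form the domain mask.
#'
#' @param ds an [st_dataset] containing the clustered genes.
#' @param labels named cluster assignment (gene id -> cluster), e.g.
#'   `cluster_svgs(ds)$labels`.
#' @param k number of nearest neighbours for smoothing (default 6).
#' @param threshold_quantile quantile of the smoothed profile above which a
#'   spot belongs to the domain (default 0.75).
#' @return List of `spatial_domain` entries: `cluster_id`, `spot_mask`,
#'   `mean_profile` (smoothed), one per non-empty cluster.
#' @export
predict_domains <- function(ds, labels, k = 6, threshold_quantile = 0.75) {
  stopifnot(inherits(ds, "st_dataset"))
  labels <- labels[names(labels) %in% ds$gene_ids]
  if (!length(labels)) stop("labels do not match any gene of the dataset")
  co <- ds$coords
  n <- nrow(co)
  dmat <- as.matrix(dist(co[, c("x", "y")]))
  knn <- apply(dmat, 1, function(d) order(d)[seq_len(min(k + 1, n))])
  out <- list()
  for (cl in sort(unique(labels))) {
    ids <- names(labels)[labels == cl]
    X <- as.matrix(ds$counts[match(ids, ds$gene_ids), , drop = FALSE])
    tot <- rowSums(X)
    if (all(tot == 0)) {
      warning("cluster ", cl, " has no expression; skipped")
      next
    }
    X <- X[tot > 0, , drop = FALSE] / tot[tot > 0]
    profile <- colMeans(X)
    smoothed <- vapply(seq_len(n), function(i) mean(profile[knn[, i]]),
                       numeric(1))
    thr <- quantile(smoothed, threshold_quantile)
    out[[as.character(cl)]] <- structure(
      list(cluster_id = cl, spot_mask = smoothed >= thr,
           mean_profile = smoothed), class = "spatial_domain")
  }
  out
}
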