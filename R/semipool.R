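#' Semi-pooling configuration
#'
#' The semi-pooling step converts a gene's two-dimensional spatial expression
#' into four one-dimensional marginal expression series: row and column axis,
#' each at a fine and a coarse resolution. Fine bin counts default to
#' `min(number of distinct coordinate values on the axis, round(2 * sqrt(n_spots)))`
#' so the expected occupancy per bin grows like `sqrt(n_spots)` and stays
#' stable across dataset sizes, while the series is long enough for the
#' chi-square approximation of the Portmanteau statistic to be accurate; the
#' coarse count is the fine count divided by `coarse_factor` (floored,
#' minimum 2), capturing structure at two well-separated scales.
#'
#' @param ds an [st_dataset], used to derive defaults; may be `NULL` when all
#'   bin counts are given explicitly.
#' @param fine_bins_row,fine_bins_col fine bin counts per axis (default auto).
#' @param coarse_bins_row,coarse_bins_col coarse bin counts (default
#'   `max(2, fine %/% coarse_factor)`).
#' @param coarse_factor ratio between fine and coarse resolutions (default 4,
#'   so the two scales probe clearly separated structure and their test
#'   statistics are only weakly correlated).
#' @return A `semipool_config` list.
#' @export
semipool_config <- function(ds = NULL, fine_bins_row = NULL,
                            fine_bins_col = NULL, coarse_bins_row = NULL,
                            coarse_bins_col = NULL, coarse_factor = 4) {
  if (!is.null(ds)) {
    stopifnot(inherits(ds, "st_dataset"))
    n <- length(ds$spot_ids)
    auto <- function(v) max(5L, min(length(unique(v)), round(2 * sqrt(n))))
    fine_bins_row <- fine_bins_row %||% auto(ds$coords$x)
    fine_bins_col <- fine_bins_col %||% auto(ds$coords$y)
  }
  if (is.null(fine_bins_row) || is.null(fine_bins_col))
    stop("supply a dataset or explicit fine bin counts")
  # the Portmanteau test needs T >= 4, so auto coarse series never go below 4
  coarse_bins_row <- coarse_bins_row %||%
    max(4L, fine_bins_row %/% coarse_factor)
  coarse_bins_col <- coarse_bins_col %||%
    max(4L, fine_bins_col %/% coarse_factor)
  if (fine_bins_row < 2 || fine_bins_col < 2)
    stop("fine bin counts must be >= 2")
  if (coarse_bins_row >= fine_bins_row || coarse_bins_col >= fine_bins_col)
    stop("coarse bin counts must be smaller than fine bin counts")
  structure(list(fine_bins_row = as.integer(fine_bins_row),
                 coarse_bins_row = as.integer(coarse_bins_row),
                 fine_bins_col = as.integer(fine_bins_col),
                 coarse_bins_col = as.integer(coarse_bins_col),
                 coarse_factor = coarse_factor),
            class = "semipool_config")
}

#' Assign spots to bins along one coordinate axis
#'
#' Two binning rules are available. `"quantile"` (the default) places bin
#' edges at empirical quantiles of the coordinates so every bin holds (up to
#' ties) the same number of spots: on spots placed by a spatial point
#' process this keeps the per-bin occupancy constant, which matters because
#' with equal-width bins the random occupancy profile is shared by every
#' gene and injects a common spurious autocorrelation into all marginal
#' series. `"width"` partitions `[min, max]` into `n_bins` equal-width
#' half-open intervals `[lo, hi)` (the last interval closed). Both rules are
#' invariant under translation and uniform scaling of the coordinates and
#' under permutation of the spot order.
#'
#' @param coords_1d numeric vector of coordinates along one axis.
#' @param n_bins number of bins (>= 2).
#' @param method `"quantile"` (equal occupancy, default) or `"width"`
#'   (equal width).
#' @return Integer vector of bin indices in `1..n_bins`, with attributes
#'   `n_bins` and `edges` (the `n_bins + 1` bin boundaries).
#' @examples
#' build_bins(c(0, 1, 2, 3), 2)                      # 1 1 2 2
#' build_bins(c(0, 0.4, 2.0), 2, method = "width")   # 1 1 2 (edge at 1.0)
#' @export
build_bins <- function(coords_1d, n_bins, method = c("quantile", "width")) {
  method <- match.arg(method)
  if (n_bins < 2) stop("n_bins must be >= 2")
  lo <- min(coords_1d); hi <- max(coords_1d)
  if (!(hi > lo)) stop("degenerate axis: all coordinates identical")
  if (method == "width") {
    idx <- as.integer(floor((coords_1d - lo) / (hi - lo) * n_bins)) + 1L
    idx[idx > n_bins] <- as.integer(n_bins)  # max point closes the last bin
    edges <- lo + (hi - lo) * (0:n_bins) / n_bins
  } else {
    # type-1 quantile edges: ties always fall on one side, so equal
    # coordinates always share a bin and spot order cannot matter
    inner <- quantile(coords_1d, probs = seq_len(n_bins - 1) / n_bins,
                      type = 1, names = FALSE)
    idx <- findInterval(coords_1d, inner, left.open = TRUE) + 1L
    edges <- c(lo, inner, hi)
  }
  attr(idx, "n_bins") <- as.integer(n_bins)
  attr(idx, "edges") <- edges
  idx
}

#' Pool a gene's per-spot counts into a marginal expression series
#'
#' `values[t]` is the sum of the gene's counts over the spots assigned to bin
#' `t`; empty bins contribute 0 (dropping them would splice distant regions
#' together and fabricate autocorrelation). The series conserves the gene's
#' total count.
#'
#' @param gene_counts numeric vector of per-spot counts.
#' @param bins bin assignment from [build_bins()].
#' @param axis optional axis label (`"row"` or `"column"`).
#' @return A `marginal_series` object: list with `values`, `T` (series
#'   length), `axis`, `n_bins` and `bin_edges`.
#' @export
marginal_series <- function(gene_counts, bins, axis = NA_character_) {
  n_bins <- attr(bins, "n_bins") %||% max(bins)
  if (length(gene_counts) != length(bins))
    stop("bins must cover every spot")
  values <- numeric(n_bins)
  s <- rowsum(as.numeric(gene_counts), group = bins)
  values[as.integer(rownames(s))] <- s[, 1]
  structure(list(values = values, T = n_bins, axis = axis,
                 n_bins = n_bins, bin_edges = attr(bins, "edges")),
            class = "marginal_series")
}

#' @export
print.marginal_series <- function(x, ...) {
  cat(sprintf("marginal_series (%s axis, T = %d): ", x$axis, x$T))
  cat(head(x$values, 8), if (x$T > 8) "...", "\n")
  invisible(x)
}

# internal: the four (axis, n_bins) binning specifications for a dataset.
# When one axis is degenerate (all coordinates equal) the other axis is used
# at both scales in its place, so the combiner still receives four series;
# the returned list carries a "duplicated_axis" attribute naming the axis.
.semi_pool_plan <- function(coords, cfg) {
  row_ok <- max(coords$x) > min(coords$x)
  col_ok <- max(coords$y) > min(coords$y)
  if (!row_ok && !col_ok) stop("both coordinate axes are degenerate")
  plan <- list(
    row_fine   = list(axis = "row", n_bins = cfg$fine_bins_row),
    row_coarse = list(axis = "row", n_bins = cfg$coarse_bins_row),
    col_fine   = list(axis = "column", n_bins = cfg$fine_bins_col),
    col_coarse = list(axis = "column", n_bins = cfg$coarse_bins_col))
  dup <- NULL
  if (!row_ok) {
    plan$row_fine <- plan$col_fine; plan$row_coarse <- plan$col_coarse
    dup <- "row"
  }
  if (!col_ok) {
    plan$col_fine <- plan$row_fine; plan$col_coarse <- plan$row_coarse
    dup <- "column"
  }
  attr(plan, "duplicated_axis") <- dup
  plan
}

.axis_values <- function(coords, axis) if (axis == "row") coords$x else coords$y

#' Semi-pool one gene into its four marginal expression series
#'
#' @param gene_counts numeric vector of the gene's per-spot counts.
#' @param coords coordinate data.frame with columns `x`, `y` (one row per
#'   spot, same order as `gene_counts`).
#' @param cfg a [semipool_config()]; defaults are derived from the
#'   coordinates when omitted.
#' @return Named list of four [marginal_series()]: `row_fine`, `row_coarse`,
#'   `col_fine`, `col_coarse`. If one axis is degenerate the other axis is
#'   substituted at both scales and the result carries a `duplicated_axis`
#'   attribute.
#' @export
semi_pool <- function(gene_counts, coords, cfg = NULL) {
  if (is.null(cfg)) {
    n <- nrow(coords)
    auto <- function(v) max(5L, min(length(unique(v)), round(2 * sqrt(n))))
    cfg <- semipool_config(fine_bins_row = auto(coords$x),
                           fine_bins_col = auto(coords$y))
  }
  plan <- .semi_pool_plan(coords, cfg)
  out <- lapply(plan, function(p) {
    b <- build_bins(.axis_values(coords, p$axis), p$n_bins)
    marginal_series(gene_counts, b, axis = p$axis)
  })
  attr(out, "duplicated_axis") <- attr(plan, "duplicated_axis")
  out
}
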