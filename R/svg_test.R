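#' Sample autocovariance of a marginal expression series
#'
#' For a series \eqn{r_1,\dots,r_T} with mean \eqn{\bar r}, the lag-k sample
#' autocovariance is
#' \deqn{\hat\gamma_k = \frac{1}{T-k} \sum_{t=k+1}^{T} (r_t-\bar r)(r_{t-k}-\bar r),}
#' i.e. with the \eqn{1/(T-k)} divisor (not the more common \eqn{1/T}).
#'
#' @param r numeric vector or a [marginal_series()].
#' @param k lag, `0 <= k <= T - 1`.
#' @return The sample autocovariance (a scalar).
#' @examples
#' autocovariance(c(1, 2, 3, 4), 0)  # 1.25
#' autocovariance(c(1, 2, 3, 4), 1)  # 0.41667
#' @export
autocovariance <- function(r, k) {
  r <- .series_values(r)
  T <- length(r)
  if (k < 0 || k >= T) stop("lag k must satisfy 0 <= k <= T - 1")
  m <- mean(r)
  x <- r - m
  sum(x[(k + 1):T] * x[seq_len(T - k)]) / (T - k)
}

#' Sample autocorrelation (ACF) of a marginal expression series
#'
#' \eqn{\hat\rho_k = \hat\gamma_k / \hat\gamma_0}. Because of the
#' \eqn{1/(T-k)} divisor in the autocovariance, \eqn{|\hat\rho_k|} can
#' slightly exceed 1 at large lags.
#'
#' @inheritParams autocovariance
#' @return The lag-k sample autocorrelation.
#' @examples
#' autocorrelation(c(1, 2, 3, 4), 1)  # 1/3
#' @export
autocorrelation <- function(r, k) {
  g0 <- autocovariance(r, 0)
  if (g0 <= 0) stop("constant series: autocorrelation undefined")
  autocovariance(r, k) / g0
}

.series_values <- function(r) {
  if (inherits(r, "marginal_series")) r$values else as.numeric(r)
}

#' Portmanteau test for serial autocorrelation of one series
#'
#' Tests \eqn{H_0: \rho_1 = \dots = \rho_m = 0} against the alternative that
#' some \eqn{\rho_k \neq 0} with the statistic
#' \eqn{Q_m = T \sum_{l=1}^{m} \hat\rho_l^2} (Box-Pierce weighting), referred
#' to a chi-square distribution with \eqn{m = \max(1, \lfloor \ln T \rfloor)}
#' degrees of freedom; the test is one-sided. A constant series carries no
#' evidence of spatial structure and yields `p = 1`.
#'
#' @param r numeric vector or [marginal_series()] with `T >= 4`.
#' @param m number of lags tested (default `max(1, floor(log(T)))`).
#' @return A `portmanteau_result` list with fields `Q_m`, `m`, `p`.
#' @examples
#' portmanteau_test(c(1, 2, 3, 4))  # Q = 4/9, p ~ 0.505
#' @export
portmanteau_test <- function(r, m = NULL) {
  r <- .series_values(r)
  T <- length(r)
  if (T < 4) stop("series too short: T >= 4 required")
  m <- m %||% max(1L, floor(log(T)))
  if (m >= T) stop("m must be smaller than T")
  res <- .portmanteau_matrix(matrix(r, nrow = 1), m = m)
  structure(list(Q_m = res$Q[1], m = m, p = res$p[1]),
            class = "portmanteau_result")
}

#' @export
print.portmanteau_result <- function(x, ...) {
  cat(sprintf("Portmanteau test: Q_%d = %.4g, p = %.4g\n", x$m, x$Q_m, x$p))
  invisible(x)
}

# internal vectorized core: one series per row of S.
# Returns Q, m and one-sided chi-square p per row; constant rows get p = 1.
.portmanteau_matrix <- function(S, m = NULL) {
  T <- ncol(S)
  if (T < 4) stop("series too short: T >= 4 required")
  m <- m %||% max(1L, floor(log(T)))
  stopifnot(m >= 1, m < T)
  X <- S - rowMeans(S)
  g0 <- rowSums(X * X) / T
  const <- g0 <= 0
  g0[const] <- 1  # placeholder; overwritten below
  Q <- numeric(nrow(S))
  for (k in seq_len(m)) {
    gk <- rowSums(X[, (k + 1):T, drop = FALSE] *
                  X[, seq_len(T - k), drop = FALSE]) / (T - k)
    Q <- Q + (gk / g0)^2
  }
  Q <- T * Q
  Q[const] <- 0
  p <- pchisq(Q, df = m, lower.tail = FALSE)
  p[const] <- 1
  list(Q = Q, m = m, p = p)
}

#' Combine four one-sided p-values by Stouffer's method
#'
#' Each p-value is transformed to a z-score \eqn{z_i = \Phi^{-1}(1 - p_i)}
#' (after clamping into `[clamp, 1 - clamp]` to keep z finite) and the
#' combined score is \eqn{z_s = \sum_i z_i / \sqrt{4}}. The default combined
#' p-value is one-sided, \eqn{p_c = 1 - \Phi(z_s)}; a two-sided variant
#' \eqn{p_c = 2(1 - \Phi(|z_s|))} is selectable.
#'
#' @param p_values numeric vector of exactly four p-values in \[0, 1\].
#' @param two_sided use the two-sided combined p-value (default `FALSE`).
#' @param clamp clamping bound applied before the probit transform
#'   (default `1e-15`).
#' @return List with `z_scores`, `z_stouffer`, `p_combined`.
#' @examples
#' stouffer_combine(rep(0.5, 4))            # z = 0, p = 0.5
#' stouffer_combine(rep(pnorm(-2), 4))      # z = 4, p ~ 3.17e-5
#' @export
stouffer_combine <- function(p_values, two_sided = FALSE, clamp = 1e-15) {
  if (length(p_values) != 4) stop("exactly four p-values are required")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  p <- pmin(pmax(p_values, clamp), 1 - clamp)
  z <- qnorm(p, lower.tail = FALSE)
  zs <- sum(z) / 2
  pc <- if (two_sided) 2 * pnorm(abs(zs), lower.tail = FALSE)
        else pnorm(zs, lower.tail = FALSE)
  list(z_scores = z, z_stouffer = zs, p_combined = min(pc, 1))
}

#' Holm step-down multiple-testing adjustment
#'
#' Familywise-error-controlling step-down adjustment applied across all genes
#' surviving QC (thin wrapper over [stats::p.adjust]).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, in the input order; always `>=` the raw values.
#' @export
holm_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "holm")
}

#' Detect spatially variable genes
#'
#' End-to-end SVG caller: each gene is semi-pooled into four marginal
#' expression series (row/column axis at fine/coarse resolution), each series
#' is tested for serial autocorrelation with the Portmanteau statistic, the
#' four one-sided p-values are combined by Stouffer's method, and the
#' combined p-values are Holm-adjusted across genes. A gene is called an SVG
#' when its adjusted p-value is below `alpha`. Genes are processed
#' independently, so results do not depend on gene order or chunking.
#'
#' @param ds an [st_dataset] (apply [filter_low_quality_genes()] first).
#' @param config a [semipool_config()] (default: derived from the dataset).
#' @param alpha call threshold on the Holm-adjusted p-value (default 0.05).
#' @param two_sided combine with the two-sided Stouffer p-value (default
#'   `FALSE`, the one-sided form).
#' @param p_clamp clamping bound for the probit transform (default `1e-15`).
#' @return data.frame with one row per gene and columns `gene_id`,
#'   `p_row_fine`, `p_row_coarse`, `p_col_fine`, `p_col_coarse`,
#'   `z_stouffer`, `p_combined`, `p_adjusted`, `is_svg`.
#' @examples
#' sim <- simulate_dataset(n_genes = 50, n_spots = 400, seed = 1)
#' res <- detect_svg(sim$dataset)
#' table(called = res$is_svg, truth = sim$is_svg)
#' @export
detect_svg <- function(ds, config = NULL, alpha = 0.05, two_sided = FALSE,
                       p_clamp = 1e-15) {
  stopifnot(inherits(ds, "st_dataset"))
  cfg <- config %||% semipool_config(ds)
  plan <- .semi_pool_plan(ds$coords, cfg)
  n <- length(ds$spot_ids)
  G <- length(ds$gene_ids)
  tX <- t(as.matrix(ds$counts))  # spots x genes, pooled by grouped row sums
  P <- matrix(NA_real_, nrow = G, ncol = 4)
  for (j in seq_along(plan)) {
    p <- plan[[j]]
    b <- build_bins(.axis_values(ds$coords, p$axis), p$n_bins)
    S0 <- rowsum(tX, group = as.integer(b))
    S <- matrix(0, nrow = p$n_bins, ncol = G)  # empty bins stay 0
    S[as.integer(rownames(S0)), ] <- S0
    P[, j] <- .portmanteau_matrix(t(S))$p
  }
  # a gene with identical counts at every spot carries no spatial evidence,
  # even where uneven bin occupancy would make its pooled series non-constant
  const_gene <- Matrix::rowSums(ds$counts != ds$counts[, 1]) == 0
  P[const_gene, ] <- 1
  Pc <- pmin(pmax(P, p_clamp), 1 - p_clamp)
  Z <- qnorm(Pc, lower.tail = FALSE)
  zs <- rowSums(Z) / 2
  pc <- if (two_sided) pmin(2 * pnorm(abs(zs), lower.tail = FALSE), 1)
        else pnorm(zs, lower.tail = FALSE)
  padj <- holm_adjust(pc)
  out <- data.frame(gene_id = ds$gene_ids,
                    p_row_fine = P[, 1], p_row_coarse = P[, 2],
                    p_col_fine = P[, 3], p_col_coarse = P[, 4],
                    z_stouffer = zs, p_combined = pc, p_adjusted = padj,
                    is_svg = padj < alpha,
                    stringsAsFactors = FALSE)
  if (!is.null(attr(plan, "duplicated_axis")))
    attr(out, "duplicated_axis") <- attr(plan, "duplicated_axis")
  out
}
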