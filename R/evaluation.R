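#' Confusion-matrix metrics for SVG calls against simulation truth
#'
#' Computes TP/FP/FN/TN and the derived rates Precision = TP/(TP+FP),
#' TPR (recall) = TP/(TP+FN), FPR = FP/(FP+TN), FDP = FP/(TP+FP) and
#' F1 = 2*Precision*Recall/(Precision+Recall). Ratios with a zero
#' denominator are defined as 0 (with a warning).
#'
#' @param calls logical vector of SVG calls, one per gene.
#' @param truth logical vector of true labels, same length.
#' @return One-row data.frame of class `metric_report` with columns `TP`,
#'   `FP`, `FN`, `TN`, `precision`, `recall_tpr`, `fpr`, `f1`, `fdp`.
#' @examples
#' confusion(c(rep(TRUE, 10), rep(FALSE, 90)),
#'           c(rep(TRUE, 9), FALSE, TRUE, rep(FALSE, 89)))
#' @export
confusion <- function(calls, truth) {
  if (length(calls) != length(truth))
    stop("calls and truth must have equal length")
  calls <- as.logical(calls); truth <- as.logical(truth)
  tp <- sum(calls & truth); fp <- sum(calls & !truth)
  fn <- sum(!calls & truth); tn <- sum(!calls & !truth)
  div0 <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (0/0); reported as 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  precision <- div0(tp, tp + fp, "precision")
  tpr <- div0(tp, tp + fn, "TPR")
  fpr <- div0(fp, fp + tn, "FPR")
  fdp <- div0(fp, tp + fp, "FDP")
  f1 <- if (precision + tpr == 0) 0 else
    2 * precision * tpr / (precision + tpr)
  structure(data.frame(TP = tp, FP = fp, FN = fn, TN = tn,
                       precision = precision, recall_tpr = tpr, fpr = fpr,
                       f1 = f1, fdp = fdp),
            class = c("metric_report", "data.frame"))
}

#' Rank-based AUC of a ranking score against truth
#'
#' The probability that a randomly chosen true SVG scores higher than a
#' randomly chosen non-SVG, with ties counted 1/2 (the normalized
#' Mann-Whitney U). The conventional ranking score for SVG results is
#' `-log(p_combined)`.
#'
#' @param scores numeric ranking score per gene (higher = more SVG-like).
#' @param truth logical true labels.
#' @return AUC in \[0, 1\].
#' @export
auc_from_scores <- function(scores, truth) {
  if (length(scores) != length(truth))
    stop("scores and truth must have equal length")
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: truth contains a single class")
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Run a simulation benchmark grid
#'
#' For each cell of `patterns x families x n_spots x noise` and each
#' replicate: simulate, apply noise, run [detect_svg()], score with
#' [confusion()]. Emits one row per replicate plus one average row per cell
#' (flagged by `is_average`). Replicate seeds are derived deterministically
#' from `seed`, so the table is reproducible bit-for-bit.
#'
#' @param patterns character vector of pattern names.
#' @param families character vector of count families.
#' @param n_spots integer vector of spot counts.
#' @param noise `"none"`, or `"gaussian:<strength>"` / `"exchange:<pct>"` /
#'   `"mixture"` (optionally `"mixture:<w>"`).
#' @param replicates replicates per cell (default 3).
#' @param n_genes genes per dataset (default 10000).
#' @param pct_svg fraction of true SVGs (default 0.1).
#' @param seed base seed (default 1).
#' @param ... further arguments passed to [simulate_dataset()].
#' @return data.frame with one row per replicate and per-cell average rows.
#' @export
run_benchmark <- function(patterns = "big_circles", families = "zinb",
                          n_spots = 3000, noise = "none", replicates = 3,
                          n_genes = 10000, pct_svg = 0.1, seed = 1, ...) {
  grid <- expand.grid(pattern = patterns, family = families,
                      n_spots = n_spots, noise = noise,
                      stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    reps <- lapply(seq_len(replicates), function(r) {
      s <- seed * 10000 + i * 100 + r
      tr <- simulate_dataset(pattern = cell$pattern, family = cell$family,
                             n_spots = cell$n_spots, n_genes = n_genes,
                             pct_svg = pct_svg, seed = s, ...)
      tr <- .apply_noise(tr, cell$noise)
      res <- detect_svg(tr$dataset)
      met <- confusion(res$is_svg, tr$is_svg)
      cbind(cell, rep = r, seed = s, met, is_average = FALSE,
            row.names = NULL)
    })
    reps <- do.call(rbind, reps)
    avg <- reps[1, , drop = FALSE]
    avg$rep <- NA_integer_; avg$seed <- NA_integer_; avg$is_average <- TRUE
    for (col in c("TP", "FP", "FN", "TN", "precision", "recall_tpr",
                  "fpr", "f1", "fdp"))
      avg[[col]] <- mean(reps[[col]])
    rows[[i]] <- rbind(reps, avg)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# internal: parse and apply a noise directive to a sim_truth
.apply_noise <- function(truth, noise) {
  if (is.null(noise) || noise == "none") return(truth)
  parts <- strsplit(noise, ":", fixed = TRUE)[[1]]
  kind <- parts[1]
  level <- if (length(parts) > 1) as.numeric(parts[2]) else NA_real_
  switch(kind,
    gaussian = add_gaussian_noise(truth, level),
    exchange = exchange_noise(truth, level),
    mixture = mixture_noise(truth, w = if (is.na(level)) 0.5 else level),
    stop("unknown noise directive: ", noise))
}
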