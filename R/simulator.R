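# Synthetic spatial transcriptomics data: Poisson-process spot placement, a
# catalog of spatial expression patterns, four count families and three noise
# models. All generators are deterministic given (seed, configuration).

.in_circle <- function(u, v, cx, cy, r) (u - cx)^2 + (v - cy)^2 <= r^2

.in_ellipse <- function(u, v, cx, cy, a, b, th = 0) {
  du <- u - cx; dv <- v - cy
  ru <- du * cos(th) + dv * sin(th)
  rv <- -du * sin(th) + dv * cos(th)
  (ru / a)^2 + (rv / b)^2 <= 1
}

# corner right triangle with legs `s` at corner (cu, cv) in {0,1}^2
.in_corner_tri <- function(u, v, cu, cv, s) {
  du <- abs(u - cu); dv <- abs(v - cv)
  du + dv <= s
}

.quad_centers <- cbind(c(.25, .75, .25, .75), c(.25, .25, .75, .75))

#' Catalog of simulated spatial expression patterns
#'
#' Returns the built-in catalog of 22 named patterns covering the families
#' big/small triangles, circles and squares, hotspots, stripes and streaks,
#' rings, gradients, and irregular blobs, with nominal marked-area fractions
#' spanning roughly 2% to 40% of the tissue. Each entry carries the pattern's
#' deterministic membership test on the unit square, its nominal marked
#' fraction, and a default marked-area fold-change used by
#' [simulate_dataset()] (patterns with small marked areas need a stronger
#' fold-change to be detectable at all, because marginal pooling dilutes
#' them; see the package vignette).
#'
#' @return Named list of `pattern_spec` entries with fields `name`,
#'   `marked_fraction`, `fold`, and `fun(u, v)`.
#' @export
pattern_catalog <- function() {
  spec <- function(name, frac, fold, fun)
    structure(list(name = name, marked_fraction = frac, fold = fold,
                   fun = fun), class = "pattern_spec")
  qc <- .quad_centers
  list(
    big_circles = spec("big_circles", 0.246, 4, function(u, v) {
      m <- FALSE
      for (i in 1:4) m <- m | .in_circle(u, v, qc[i, 1], qc[i, 2], 0.14)
      m
    }),
    small_circles = spec("small_circles", 0.050, 10, function(u, v) {
      m <- FALSE
      for (i in 1:4) m <- m | .in_circle(u, v, qc[i, 1], qc[i, 2], 0.063)
      m
    }),
    big_triangles = spec("big_triangles", 0.25, 3, function(u, v)
      .in_corner_tri(u, v, 0, 0, .5) | .in_corner_tri(u, v, 0, 1, .5)),
    small_triangles = spec("small_triangles", 0.051, 12, function(u, v) {
      m <- FALSE
      for (cu in c(0, 1)) for (cv in c(0, 1))
        m <- m | .in_corner_tri(u, v, cu, cv, .16)
      m
    }),
    big_squares = spec("big_squares", 0.25, 4, function(u, v) {
      m <- FALSE
      for (i in 1:4)
        m <- m | (abs(u - qc[i, 1]) <= .125 & abs(v - qc[i, 2]) <= .125)
      m
    }),
    small_squares = spec("small_squares", 0.048, 12, function(u, v) {
      m <- FALSE
      for (i in 1:4)
        m <- m | (abs(u - qc[i, 1]) <= .055 & abs(v - qc[i, 2]) <= .055)
      m
    }),
    hotspot = spec("hotspot", 0.100, 5, function(u, v)
      .in_circle(u, v, .5, .5, .178)),
    tiny_hotspots = spec("tiny_hotspots", 0.047, 16, function(u, v) {
      cs <- cbind(c(.15, .5, .85, .3, .7, .5), c(.2, .15, .25, .6, .7, .85))
      m <- FALSE
      for (i in 1:6) m <- m | .in_circle(u, v, cs[i, 1], cs[i, 2], .05)
      m
    }),
    stripes = spec("stripes", 0.30, 5, function(u, v)
      (u >= .1 & u < .2) | (u >= .45 & u < .55) | (u >= .8 & u < .9)),
    thin_stripes = spec("thin_stripes", 0.16, 14, function(u, v) {
      m <- FALSE
      for (c0 in c(.125, .375, .625, .875)) m <- m | (abs(u - c0) <= .02)
      m
    }),
    vertical_stripes = spec("vertical_stripes", 0.30, 4, function(u, v)
      (v >= .1 & v < .2) | (v >= .45 & v < .55) | (v >= .8 & v < .9)),
    diagonal_wedge = spec("diagonal_wedge", 0.245, 3, function(u, v)
      u - v >= 0.3),
    ring = spec("ring", 0.188, 8, function(u, v) {
      d2 <- (u - .5)^2 + (v - .5)^2
      d2 >= .25^2 & d2 <= .35^2
    }),
    double_ring = spec("double_ring", 0.157, 16, function(u, v) {
      d2 <- (u - .5)^2 + (v - .5)^2
      (d2 >= .15^2 & d2 <= .2^2) | (d2 >= .3^2 & d2 <= .35^2)
    }),
    gradient_band = spec("gradient_band", 0.40, 3, function(u, v) u > .6),
    corner_gradient = spec("corner_gradient", 0.196, 3, function(u, v)
      .in_circle(u, v, 0, 0, .5)),
    irregular_blobs = spec("irregular_blobs", 0.118, 10, function(u, v)
      .in_ellipse(u, v, .3, .3, .18, .10, pi / 6) |
      .in_ellipse(u, v, .72, .5, .12, .08, -pi / 4) |
      .in_ellipse(u, v, .45, .78, .14, .07, pi / 3)),
    crescent = spec("crescent", 0.072, 7, function(u, v)
      .in_circle(u, v, .5, .5, .3) & !.in_circle(u, v, .62, .5, .3)),
    checkers = spec("checkers", 0.25, 4, function(u, v) {
      iu <- pmin(floor(u * 4), 3); iv <- pmin(floor(v * 4), 3)
      iu %% 2 == 0 & iv %% 2 == 0
    }),
    quadrant = spec("quadrant", 0.25, 3, function(u, v) u < .5 & v < .5),
    cross = spec("cross", 0.260, 3, function(u, v)
      abs(u - .5) <= .07 | abs(v - .5) <= .07),
    frame = spec("frame", 0.19, 6, function(u, v)
      u < .05 | u > .95 | v < .05 | v > .95)
  )
}

#' Sample spot locations from a homogeneous Poisson point process
#'
#' Spots are placed uniformly on a square window sized so that the expected
#' point count at the given intensity equals `n_target` (window area
#' `n_target / lambda`). The realized count is Poisson-random unless `fix_n`
#' is set, in which case exactly `n_target` uniform points (a binomial
#' process) are drawn.
#'
#' @param n_target expected (or exact, with `fix_n`) number of spots.
#' @param lambda process intensity (points per unit area; default 0.5).
#' @param seed optional RNG seed.
#' @param fix_n draw exactly `n_target` points (default `FALSE`).
#' @return data.frame with columns `spot_id`, `x`, `y`, and attributes
#'   `window` (side length) and `lambda`.
#' @export
sample_spots <- function(n_target, lambda = 0.5, seed = NULL, fix_n = FALSE) {
  stopifnot(n_target >= 1, lambda > 0)
  if (!is.null(seed)) set.seed(seed)
  L <- sqrt(n_target / lambda)
  n <- if (fix_n) as.integer(n_target) else rpois(1, lambda * L^2)
  co <- data.frame(spot_id = paste0("spot", seq_len(n)),
                   x = runif(n, 0, L), y = runif(n, 0, L))
  attr(co, "window") <- L
  attr(co, "lambda") <- lambda
  co
}

#' Evaluate a pattern's marked-area mask on spot coordinates
#'
#' Membership is a deterministic geometric test on coordinates normalized to
#' the unit square by the coordinate range.
#'
#' @param pattern a pattern name from [pattern_catalog()] or a
#'   `pattern_spec`.
#' @param coords coordinate data.frame with columns `x`, `y`.
#' @return Logical vector, `TRUE` for spots inside the marked area.
#' @export
make_mask <- function(pattern, coords) {
  if (is.character(pattern)) {
    cat <- pattern_catalog()
    if (!pattern %in% names(cat)) stop("unknown pattern: ", pattern)
    pattern <- cat[[pattern]]
  }
  stopifnot(inherits(pattern, "pattern_spec"))
  u <- (coords$x - min(coords$x)) / diff(range(coords$x))
  v <- (coords$y - min(coords$y)) / diff(range(coords$y))
  as.logical(pattern$fun(u, v))
}

#' Draw counts from one of the four count families
#'
#' Families: `pois` (Poisson), `zip` (zero-inflated Poisson), `nb` (negative
#' binomial parameterized by mean and size), `zinb` (zero-inflated NB). For
#' the zero-inflated families, `mu` is the mean of the count component and an
#' extra point mass of probability `pi_zero` is placed at zero.
#'
#' @param n number of draws.
#' @param family one of `"pois"`, `"zip"`, `"nb"`, `"zinb"`.
#' @param mu mean of the count component (scalar or length-`n` vector).
#' @param dispersion NB size parameter (ignored for Poisson families).
#' @param pi_zero zero-inflation probability (ignored for `pois`/`nb`).
#' @return Integer vector of counts.
#' @export
sample_counts <- function(n, family = c("zinb", "nb", "zip", "pois"),
                          mu, dispersion = 1, pi_zero = 0.5) {
  family <- match.arg(family)
  stopifnot(dispersion > 0, pi_zero >= 0, pi_zero <= 1)
  x <- switch(family,
    pois = rpois(n, mu),
    zip = rpois(n, mu),
    nb = rnbinom(n, mu = mu, size = dispersion),
    zinb = rnbinom(n, mu = mu, size = dispersion))
  if (family %in% c("zip", "zinb") && pi_zero > 0)
    x <- x * (runif(n) >= pi_zero)
  as.integer(x)
}

#' Draw one gene's per-spot counts under a marked-area expression model
#'
#' Spots inside the mask receive counts with mean `mu_in`, spots outside with
#' mean `mu_out`, independently across spots.
#'
#' @param model list with fields `family`, `mu_in`, `mu_out`, `dispersion`,
#'   `pi_zero` (see [sample_counts()]).
#' @param mask logical marked-area indicator per spot.
#' @param seed optional RNG seed.
#' @return Integer vector of counts, one per spot.
#' @export
sample_gene <- function(model, mask, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- ifelse(mask, model$mu_in, model$mu_out)
  sample_counts(length(mask), model$family, mu,
                model$dispersion %||% 1, model$pi_zero %||% 0.5)
}

#' Simulate a labelled spatial transcriptomics dataset
#'
#' Spots are placed by a homogeneous Poisson point process; a fraction
#' `pct_svg` of genes are true SVGs whose counts have an elevated mean inside
#' the pattern's marked area (`mu_in = fold_change * mu_out`), while non-SVGs
#' draw all spots from the background mean and are therefore exchangeable
#' across spots.
#'
#' @param pattern pattern name from [pattern_catalog()] (default
#'   `"big_circles"`).
#' @param family count family (see [sample_counts()]; default `"zinb"`).
#' @param n_spots expected number of spots (default 3000).
#' @param n_genes total number of genes (default 10000).
#' @param pct_svg fraction of true SVGs (default 0.1, i.e. 1000 of 10000).
#' @param mu_out background mean of the count component (default 0.5).
#' @param fold_change marked-area mean multiplier; default is the pattern's
#'   calibrated catalog value.
#' @param dispersion NB size parameter (default 1).
#' @param pi_zero zero-inflation probability (default 0.5).
#' @param lambda Poisson-process intensity (default 0.5).
#' @param seed optional RNG seed.
#' @param fix_n place exactly `n_spots` spots (default `FALSE`).
#' @return A `sim_truth` object: list with `dataset` ([st_dataset]), logical
#'   `is_svg` per gene, `mask` (shared marked-area indicator), `masks` (per-
#'   SVG list of masks), `seed`, `lambda`, `pattern`, `family` and `params`.
#' @export
simulate_dataset <- function(pattern = "big_circles", family = "zinb",
                             n_spots = 3000, n_genes = 10000, pct_svg = 0.1,
                             mu_out = 0.5, fold_change = NULL, dispersion = 1,
                             pi_zero = 0.5, lambda = 0.5, seed = NULL,
                             fix_n = FALSE) {
  if (pct_svg < 0 || pct_svg > 1) stop("pct_svg must be in [0, 1]")
  if (mu_out < 0) stop("mu_out must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  cat <- pattern_catalog()
  if (!pattern %in% names(cat)) stop("unknown pattern: ", pattern)
  pat <- cat[[pattern]]
  fold <- fold_change %||% pat$fold
  if (fold < 1) stop("fold_change must be >= 1")
  co <- sample_spots(n_spots, lambda = lambda, fix_n = fix_n)
  n <- nrow(co)
  mask <- make_mask(pat, co)
  n_svg <- round(n_genes * pct_svg)
  mu_in <- mu_out * fold
  counts <- matrix(0L, nrow = n_genes, ncol = n)
  if (n_svg > 0) {
    mu_vec <- ifelse(mask, mu_in, mu_out)
    # draw spots-major so the per-spot mean vector recycles down columns
    counts[seq_len(n_svg), ] <-
      t(matrix(sample_counts(n * n_svg, family, mu_vec, dispersion, pi_zero),
               nrow = n))
  }
  if (n_svg < n_genes)
    counts[(n_svg + 1):n_genes, ] <-
      matrix(sample_counts(n * (n_genes - n_svg), family, mu_out, dispersion,
                           pi_zero), nrow = n_genes - n_svg)
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  is_svg <- seq_len(n_genes) <= n_svg
  names(is_svg) <- gene_ids
  ds <- st_dataset(counts, gene_ids, co$spot_id,
                   data.frame(spot_id = co$spot_id, x = co$x, y = co$y))
  masks <- if (n_svg > 0) {
    ml <- rep(list(mask), n_svg); names(ml) <- gene_ids[seq_len(n_svg)]; ml
  } else list()
  structure(list(dataset = ds, is_svg = is_svg, mask = mask, masks = masks,
                 seed = seed, lambda = lambda, pattern = pattern,
                 family = family,
                 params = list(mu_out = mu_out, mu_in = mu_in, fold = fold,
                               dispersion = dispersion, pi_zero = pi_zero)),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: pattern %s, family %s, %d genes (%d SVGs) x %d spots\n",
              x$pattern, x$family, length(x$is_svg), sum(x$is_svg),
              length(x$dataset$spot_ids)))
  invisible(x)
}

#' Add truncated-rounded Gaussian noise to simulated counts
#'
#' Each count `e` becomes `max(0, round(e + eps))` with
#' `eps ~ N(0, (strength * sd_gene)^2)`, where `sd_gene` is the gene's
#' empirical count standard deviation; labels are unchanged and counts stay
#' non-negative integers.
#'
#' @param truth a `sim_truth` from [simulate_dataset()].
#' @param strength noise level relative to each gene's count SD (>= 0).
#' @param seed optional RNG seed.
#' @return The perturbed `sim_truth`.
#' @export
add_gaussian_noise <- function(truth, strength, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"), strength >= 0)
  if (strength == 0) return(truth)
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(truth$dataset$counts)
  n <- ncol(X)
  mu <- rowMeans(X)
  sdg <- sqrt(pmax(0, rowMeans(X^2) - mu^2) * n / (n - 1))
  eps <- matrix(rnorm(length(X)), nrow = nrow(X)) * (strength * sdg)
  Y <- round(X + eps)
  Y[Y < 0] <- 0
  storage.mode(Y) <- "integer"
  dimnames(Y) <- dimnames(X)
  truth$dataset$counts <- Y
  truth
}

#' Exchange expression values between marked and unmarked spots
#'
#' For every SVG gene, `ceiling(pct * n_marked)` marked spots and equally
#' many unmarked spots are chosen at random and their expression values are
#' swapped pairwise, conserving each gene's total count exactly.
#'
#' @param truth a `sim_truth`.
#' @param pct fraction of marked spots to exchange, in \[0, 1\].
#' @param seed optional RNG seed.
#' @return The perturbed `sim_truth`.
#' @export
exchange_noise <- function(truth, pct, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"), pct >= 0, pct <= 1)
  if (pct == 0) return(truth)
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(truth$dataset$counts)
  svg_idx <- which(truth$is_svg)
  for (g in svg_idx) {
    mask <- truth$masks[[truth$dataset$gene_ids[g]]] %||% truth$mask
    marked <- which(mask); unmarked <- which(!mask)
    k <- ceiling(pct * length(marked))
    if (k > length(unmarked))
      stop("pct exceeds the number of available unmarked spots")
    a <- sample(marked, k); b <- sample(unmarked, k)
    tmp <- X[g, a]; X[g, a] <- X[g, b]; X[g, b] <- tmp
  }
  truth$dataset$counts <- X
  truth
}

#' Build the mixture-noise gene sets from a set of simulated SVGs
#'
#' From the SVG genes of `truth`, four labelled gene sets are emitted:
#' `svg` (the originals), `non_svg` (spot-permuted copies, which destroy the
#' spatial pattern but keep each gene's count histogram), `svg_noise` (convex
#' mixture `round((1 - w) * original + w * permuted_copy)`), and
#' `non_svg_noise` (the same mixture built from two independent permuted
#' copies). The positive sets are `svg` and `svg_noise`.
#'
#' @param truth a `sim_truth` whose SVG genes seed the mixture.
#' @param w mixture weight of the permuted copy in the noisy sets, in
#'   \[0, 1\] (default 0.5; `w = 0` reproduces the originals, `w = 1` is
#'   indistinguishable from a permuted non-SVG).
#' @param seed optional RNG seed.
#' @return A `sim_truth` whose dataset stacks the four sets (gene ids
#'   suffixed by set), with `is_svg` labels and a `gene_set` factor.
#' @export
mixture_noise <- function(truth, w = 0.5, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"), w >= 0, w <= 1)
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(truth$dataset$counts)[truth$is_svg, , drop = FALSE]
  n1 <- nrow(X); n <- ncol(X)
  if (n1 < 1) stop("truth contains no SVG genes")
  perm_rows <- function(M) t(apply(M, 1, function(r) r[sample.int(n)]))
  P1 <- perm_rows(X); P2 <- perm_rows(X); P3 <- perm_rows(X)
  P4 <- perm_rows(X)
  mix <- function(A, B) {
    Y <- round((1 - w) * A + w * B); storage.mode(Y) <- "integer"; Y
  }
  blocks <- list(svg = X, non_svg = P1, svg_noise = mix(X, P2),
                 non_svg_noise = mix(P3, P4))
  counts <- do.call(rbind, blocks)
  base_ids <- truth$dataset$gene_ids[truth$is_svg]
  gene_ids <- unlist(lapply(names(blocks), function(s) paste0(base_ids, "_", s)))
  gene_set <- factor(rep(names(blocks), each = n1), levels = names(blocks))
  is_svg <- gene_set %in% c("svg", "svg_noise")
  names(is_svg) <- gene_ids
  ds <- st_dataset(counts, gene_ids, truth$dataset$spot_ids,
                   truth$dataset$coords)
  masks <- rep(list(truth$mask), 2 * n1)
  names(masks) <- gene_ids[is_svg]
  structure(list(dataset = ds, is_svg = is_svg, gene_set = gene_set,
                 mask = truth$mask, masks = masks, seed = seed,
                 lambda = truth$lambda, pattern = truth$pattern,
                 family = truth$family, params = c(truth$params, w = w)),
            class = "sim_truth")
}
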