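test_that("spot sampling follows the intensity and is reproducible", {
  co1 <- sample_spots(3000, lambda = 0.5, seed = 21)
  co2 <- sample_spots(3000, lambda = 0.5, seed = 21)
  expect_identical(co1, co2)
  expect_equal(attr(co1, "window")^2 * 0.5, 3000)
  # realized count within a generous Poisson tail bound
  expect_lt(abs(nrow(co1) - 3000), 4 * sqrt(3000))
  expect_equal(nrow(sample_spots(3000, seed = 22, fix_n = TRUE)), 3000)
  expect_true(all(co1$x >= 0 & co1$x <= attr(co1, "window")))
})

test_that("the pattern catalog has 22 valid entries with plausible areas", {
  ctl <- pattern_catalog()
  expect_length(ctl, 22)
  set.seed(23)
  co <- data.frame(x = runif(20000), y = runif(20000))
  for (p in ctl) {
    frac <- mean(make_mask(p, co))
    expect_gt(frac, 0.015)
    expect_lt(frac, 0.45)
    # empirical spot fraction close to the catalog's nominal area
    expect_lt(abs(frac - p$marked_fraction), 0.02)
  }
  expect_lt(mean(make_mask("small_circles", co)),
            mean(make_mask("big_circles", co)))
  expect_error(make_mask("no_such_pattern", co), "unknown pattern")
})

test_that("hotspot membership is exactly the within-radius disc", {
  set.seed(24)
  co <- data.frame(x = runif(5000), y = runif(5000))
  m <- make_mask("hotspot", co)
  u <- (co$x - min(co$x)) / diff(range(co$x))
  v <- (co$y - min(co$y)) / diff(range(co$y))
  d <- sqrt((u - 0.5)^2 + (v - 0.5)^2)
  expect_identical(m, d <= 0.178)
})

test_that("count families have the advertised moments and zero masses", {
  set.seed(25)
  x <- sample_counts(10000, "pois", mu = 1)
  expect_lt(abs(mean(x) - 1), 0.03)
  expect_true(all(sample_counts(1000, "zip", mu = 5, pi_zero = 1) == 0))
  zf_nb <- mean(sample_counts(20000, "nb", mu = 2, dispersion = 1) == 0)
  zf_zinb <- mean(sample_counts(20000, "zinb", mu = 2, dispersion = 1,
                                pi_zero = 0.5) == 0)
  expect_gt(zf_zinb, zf_nb)
})

test_that("simulate_dataset labels, masks and determinism are correct", {
  tr <- simulate_dataset(n_genes = 300, n_spots = 500, pct_svg = 0.1,
                         seed = 26)
  expect_equal(sum(tr$is_svg), 30)
  expect_length(tr$masks, 30)
  expect_s3_class(tr$dataset, "st_dataset")
  # marked-area empirical mean exceeds background for every SVG
  X <- as.matrix(tr$dataset$counts)
  for (g in which(tr$is_svg))
    expect_gt(mean(X[g, tr$mask]), mean(X[g, !tr$mask]))

  tr2 <- simulate_dataset(n_genes = 300, n_spots = 500, pct_svg = 0.1,
                          seed = 26)
  expect_identical(as.matrix(tr2$dataset$counts), X)

  expect_false(any(simulate_dataset(n_genes = 50, n_spots = 300,
                                    pct_svg = 0, seed = 27)$is_svg))
  expect_error(simulate_dataset(pct_svg = 2), "pct_svg")
  expect_error(simulate_dataset(pattern = "nope"), "unknown pattern")
})

test_that("gaussian noise respects the relative-strength contract", {
  tr <- simulate_dataset(n_genes = 20, n_spots = 400, seed = 28)
  expect_identical(add_gaussian_noise(tr, 0)$dataset$counts,
                   tr$dataset$counts)

  # on a high-mean gene, pre-truncation variance inflates by ~ 1 + s^2
  set.seed(29)
  base <- matrix(rpois(20000, 100), nrow = 1)
  tr2 <- structure(list(dataset = grid_dataset(base), is_svg = FALSE,
                        mask = NULL, masks = list(), seed = 29, lambda = 0.5,
                        pattern = "none", family = "pois", params = list()),
                   class = "sim_truth")
  noisy <- add_gaussian_noise(tr2, 0.3, seed = 30)
  Y <- as.matrix(noisy$dataset$counts)
  expect_true(is.integer(Y[1, 1] + 0L) || all(Y == floor(Y)))
  expect_true(all(Y >= 0))
  expect_equal(var(as.numeric(Y)) / var(as.numeric(base)), 1 + 0.3^2,
               tolerance = 0.04)
})

test_that("exchange noise swaps pairwise and conserves totals", {
  tr <- simulate_dataset(pattern = "gradient_band", n_genes = 40,
                         n_spots = 600, pct_svg = 0.5, lambda = 0.7,
                         seed = 31)
  expect_identical(exchange_noise(tr, 0)$dataset$counts, tr$dataset$counts)

  sw <- exchange_noise(tr, 0.3, seed = 32)
  X0 <- as.matrix(tr$dataset$counts); X1 <- as.matrix(sw$dataset$counts)
  expect_equal(rowSums(X1), rowSums(X0))
  # non-SVG genes untouched
  expect_identical(X1[!tr$is_svg, ], X0[!tr$is_svg, ])

  # full exchange moves every marked value out: contrast collapses
  full <- exchange_noise(tr, 1, seed = 33)
  Xf <- as.matrix(full$dataset$counts)
  g <- which(tr$is_svg)[1]
  expect_lt(mean(Xf[g, tr$mask]), mean(X0[g, tr$mask]))
  expect_gt(mean(Xf[g, !tr$mask]), mean(X0[g, !tr$mask]))

  tiny <- simulate_dataset(pattern = "gradient_band", n_genes = 4,
                           n_spots = 60, pct_svg = 1, seed = 34)
  expect_error(exchange_noise(tiny, 1, seed = 35), NA)
})

test_that("mixture noise builds the four labelled gene sets correctly", {
  base <- simulate_dataset(pattern = "big_circles", n_genes = 30,
                           n_spots = 400, pct_svg = 1, seed = 36)
  mx <- mixture_noise(base, w = 0.5, seed = 37)
  expect_equal(levels(mx$gene_set),
               c("svg", "non_svg", "svg_noise", "non_svg_noise"))
  expect_equal(as.vector(table(mx$gene_set)), rep(30, 4))
  expect_identical(unname(mx$is_svg),
                   mx$gene_set %in% c("svg", "svg_noise"))

  X <- as.matrix(mx$dataset$counts)
  orig <- as.matrix(base$dataset$counts)
  # the svg block is the original; permuted blocks keep each gene's histogram
  expect_identical(unname(X[mx$gene_set == "svg", ]), unname(orig))
  perm <- X[mx$gene_set == "non_svg", ]
  for (i in 1:5) expect_identical(sort(perm[i, ]), sort(orig[i, ]))

  # w = 0 reproduces the originals in the noisy set
  mx0 <- mixture_noise(base, w = 0, seed = 38)
  expect_identical(unname(as.matrix(mx0$dataset$counts)[mx0$gene_set == "svg_noise", ]),
                   unname(orig))
  # w = 1 is exactly a permuted copy (same histogram, pattern destroyed)
  mx1 <- mixture_noise(base, w = 1, seed = 39)
  X1 <- as.matrix(mx1$dataset$counts)[mx1$gene_set == "svg_noise", ]
  for (i in 1:5) expect_identical(sort(X1[i, ]), sort(orig[i, ]))
})
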