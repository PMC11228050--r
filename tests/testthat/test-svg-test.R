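test_that("autocovariance and ACF match hand computations", {
  r <- c(1, 2, 3, 4)
  expect_equal(autocovariance(r, 0), 1.25)
  expect_equal(autocovariance(r, 1), 0.75 / 1.8, tolerance = 1e-12)
  expect_equal(autocovariance(r, 1), (0.75 - 0.25 + 0.75) / 3)
  expect_equal(autocorrelation(r, 1), 1 / 3)
  expect_equal(autocorrelation(r, 0), 1)
  expect_equal(autocovariance(rep(2, 6), 3), 0)
  expect_error(autocovariance(r, 4), "lag")
  expect_error(autocorrelation(rep(1, 5), 1), "constant")
})

test_that("ACF is invariant under series reversal", {
  set.seed(10)
  for (i in 1:20) {
    r <- rnorm(sample(8:60, 1))
    for (k in 1:3)
      expect_equal(autocorrelation(r, k), autocorrelation(rev(r), k))
  }
})

test_that("the Portmanteau test reproduces its fixture and degenerate contracts", {
  pt <- portmanteau_test(c(1, 2, 3, 4))
  expect_equal(pt$m, 1)
  expect_equal(pt$Q_m, 4 * (1 / 3)^2)
  expect_equal(pt$p, 0.5049851, tolerance = 1e-6)
  expect_equal(portmanteau_test(rep(5, 20))$p, 1)
  expect_error(portmanteau_test(c(1, 2, 3)), "too short")
  # m defaults to floor(log(T)), floored at 1 and below T
  expect_equal(portmanteau_test(rnorm(200))$m, 5)
  expect_equal(portmanteau_test(c(1, 0, 2, 1))$m, 1)
})

test_that("vectorized statistic agrees with the literal double-loop oracle", {
  set.seed(11)
  for (i in 1:100) {
    T <- sample(8:150, 1)
    r <- switch(1 + i %% 3, rnorm(T), rpois(T, 2), rnorm(T) + sin(1:T / 4))
    got <- portmanteau_test(r)
    want <- brute_portmanteau(r)
    expect_equal(got$Q_m, want$Q, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("Portmanteau null rejection on iid series is calibrated", {
  set.seed(12)
  S <- matrix(rnorm(10000 * 200), nrow = 10000)
  p <- heartsvg:::.portmanteau_matrix(S)$p
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
})

test_that("Stouffer combination matches its fixtures and clamps", {
  s <- stouffer_combine(rep(0.5, 4))
  expect_equal(s$z_stouffer, 0)
  expect_equal(s$p_combined, 0.5)
  expect_equal(stouffer_combine(rep(0.5, 4), two_sided = TRUE)$p_combined, 1)

  s2 <- stouffer_combine(rep(pnorm(2, lower.tail = FALSE), 4))
  expect_equal(s2$z_stouffer, 4, tolerance = 1e-10)
  expect_equal(s2$p_combined, 3.167124e-05, tolerance = 1e-6)

  s3 <- stouffer_combine(rep(0, 4))
  expect_true(is.finite(s3$z_stouffer))
  expect_gt(s3$p_combined, 0)

  expect_error(stouffer_combine(c(0.1, 0.2)), "four")
  expect_error(stouffer_combine(c(0.1, 0.2, 0.3, 1.5)), "\\[0, 1\\]")
})

test_that("Holm adjustment is the step-down procedure", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  set.seed(13)
  p <- runif(50)
  expect_true(all(holm_adjust(p) >= p))
})

test_that("detect_svg calls a strong SVG and not its spot-permuted controls", {
  set.seed(14)
  tr <- simulate_dataset(pattern = "hotspot", family = "zinb", n_genes = 1,
                         n_spots = 3000, pct_svg = 1, fold_change = 8,
                         seed = 15)
  x <- as.integer(tr$dataset$counts[1, ])
  n <- length(x)
  perms <- t(vapply(1:60, function(i) x[sample.int(n)], integer(n)))
  cnt <- rbind(svg = x, perms)
  rownames(cnt) <- c("svg", paste0("perm", 1:60))
  colnames(cnt) <- tr$dataset$spot_ids
  ds <- st_dataset(cnt, coords = tr$dataset$coords)
  res <- detect_svg(ds)
  expect_true(res$is_svg[res$gene_id == "svg"])
  # permuted controls: well over 95% must not be called
  expect_lte(sum(res$is_svg[res$gene_id != "svg"]), 3)
})

test_that("a dataset of constant genes yields p_combined 1 and no calls", {
  cnt <- matrix(3L, nrow = 5, ncol = 100)
  ds <- grid_dataset(cnt)
  res <- detect_svg(ds)
  expect_equal(res$p_combined, rep(1, 5), tolerance = 1e-12)
  expect_false(any(res$is_svg))
})

test_that("two-sided mode doubles the tail and flags both directions", {
  set.seed(16)
  tr <- simulate_dataset(n_genes = 50, n_spots = 500, seed = 17)
  r1 <- detect_svg(tr$dataset)
  r2 <- detect_svg(tr$dataset, two_sided = TRUE)
  expect_equal(r2$p_combined,
               pmin(1, 2 * pnorm(abs(r1$z_stouffer), lower.tail = FALSE)))
})
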