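test_that("st_dataset validates shapes, ids and counts", {
  cnt <- matrix(0:5, 2, 3, dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  co <- data.frame(spot_id = c("s1", "s2", "s3"), x = 1:3, y = c(1, 1, 2))
  ds <- st_dataset(cnt, coords = co)
  expect_identical(dim(ds), c(2L, 3L))
  expect_identical(ds$coords$spot_id, c("s1", "s2", "s3"))

  expect_error(st_dataset(cnt, gene_ids = c("a", "a"), coords = co), "duplicates")
  expect_error(st_dataset(cnt - 1, coords = co), "negative")
  expect_error(st_dataset(cnt + 0.5, coords = co), "not integers")
  expect_error(st_dataset(cnt, coords = co[1:2, ]), "one \\(x, y\\) pair")
  expect_error(st_dataset(cnt, coords = transform(co, x = c(1, NA, 3))),
               "missing")
  # coords rows may come in any order
  ds2 <- st_dataset(cnt, coords = co[c(3, 1, 2), ])
  expect_identical(ds2$coords, ds$coords)
})

test_that("matrix-market round trip is bit-exact and CSV encoding agrees", {
  set.seed(42)
  cnt <- matrix(0L, 3, 4)
  cnt[sample(12, 5)] <- as.integer(sample(1:9, 5, replace = TRUE))
  rownames(cnt) <- paste0("g", 1:3)
  colnames(cnt) <- paste0("s", 1:4)
  co <- data.frame(spot_id = colnames(cnt), x = c(0, 0, 1, 1), y = c(0, 1, 0, 1))
  ds <- st_dataset(cnt, coords = co)

  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(as.matrix(back$counts), matrix(as.double(cnt), 3, 4,
                                                  dimnames = dimnames(cnt)))
  expect_identical(back$gene_ids, ds$gene_ids)
  expect_identical(back$spot_ids, ds$spot_ids)
  expect_equal(back$coords, ds$coords)
  expect_equal(length(methods::slot(methods::as(back$counts, "CsparseMatrix"),
                                    "x")), 5)

  # dense CSV encoding of the same fixture reads back identically
  csv <- file.path(dir, "dense.csv")
  write.csv(as.data.frame(cnt), csv)
  m <- read_counts(csv)
  expect_equal(unname(as.matrix(m)), unname(matrix(as.double(cnt), 3, 4)),
               ignore_attr = TRUE)
  expect_identical(rownames(m), rownames(cnt))

  # degenerate and malformed inputs
  empty <- file.path(dir, "empty.csv")
  writeLines("", empty)
  expect_error(read_counts(empty))
  expect_error(read_counts(file.path(dir, "matrix.mtx"),
                           file.path(dir, "genes.txt"), NULL),
               "label files are required")
  badlab <- file.path(dir, "bad_genes.txt")
  writeLines(c("g1", "g2"), badlab)
  expect_error(read_counts(file.path(dir, "matrix.mtx"), badlab,
                           file.path(dir, "spots.txt")), "mismatch")
})

test_that("read_coords enforces uniqueness and completeness", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(spot_id = c("a", "b", "c", "d"),
                       x = c(1, 1, 2, 2), y = c(1, 2, 1, 2)), f,
            row.names = FALSE)
  expect_equal(nrow(read_coords(f)), 4)

  write.csv(data.frame(spot_id = c("a", "a"), x = 1:2, y = 1:2), f,
            row.names = FALSE)
  expect_error(read_coords(f), "duplicated")

  write.csv(data.frame(spot_id = c("a", "b"), x = c(1, NA), y = 1:2), f,
            row.names = FALSE)
  expect_error(read_coords(f), "missing")
})

test_that("shuffled coordinate rows give the same dataset after the id join", {
  set.seed(7)
  cnt <- matrix(rpois(40, 2), 4, 10,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  co <- data.frame(spot_id = paste0("s", 1:10), x = runif(10), y = runif(10))
  ds1 <- st_dataset(cnt, coords = co)
  ds2 <- st_dataset(cnt, coords = co[sample(10), ])
  expect_identical(ds1$coords, ds2$coords)
})

test_that("low-quality gene filter uses an inclusive 1% boundary and is idempotent", {
  n <- 1000
  cnt <- rbind(drop5 = rep(c(1L, 0L), c(5, n - 5)),
               keep10 = rep(c(1L, 0L), c(10, n - 10)),
               dense = rep(1L, n))
  colnames(cnt) <- paste0("s", seq_len(n))
  co <- data.frame(spot_id = colnames(cnt), x = runif(n), y = runif(n))
  ds <- st_dataset(cnt, coords = co)

  out <- filter_low_quality_genes(ds, min_fraction = 0.01)
  expect_identical(out$report$dropped_gene_ids, "drop5")
  expect_identical(out$dataset$gene_ids, c("keep10", "dense"))
  expect_equal(out$report$n_genes_kept + length(out$report$dropped_gene_ids),
               out$report$n_genes_in)

  again <- filter_low_quality_genes(out$dataset, min_fraction = 0.01)
  expect_identical(again$dataset$gene_ids, out$dataset$gene_ids)
  expect_length(again$report$dropped_gene_ids, 0)

  all_kept <- filter_low_quality_genes(ds, min_fraction = 0)
  expect_equal(all_kept$report$n_genes_kept, 3)
})
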