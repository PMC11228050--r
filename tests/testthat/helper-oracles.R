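# Independent brute-force oracles, written as literal double loops so they
# share no code path with the vectorized implementation.

brute_autocovariance <- function(r, k) {
  T <- length(r)
  rbar <- sum(r) / T
  s <- 0
  for (t in (k + 1):T) s <- s + (r[t] - rbar) * (r[t - k] - rbar)
  s / (T - k)
}

brute_portmanteau <- function(r) {
  T <- length(r)
  m <- max(1, floor(log(T)))
  g0 <- brute_autocovariance(r, 0)
  Q <- 0
  for (l in 1:m) Q <- Q + (brute_autocovariance(r, l) / g0)^2
  Q <- T * Q
  list(Q = Q, m = m, p = pchisq(Q, df = m, lower.tail = FALSE))
}

# small helper: dataset from an explicit count matrix on a grid
grid_dataset <- function(counts, nx = NULL, ny = NULL) {
  n <- ncol(counts)
  if (is.null(nx)) nx <- ceiling(sqrt(n))
  if (is.null(ny)) ny <- ceiling(n / nx)
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))[seq_len(n), ]
  co <- data.frame(spot_id = paste0("s", seq_len(n)), x = g$x, y = g$y)
  rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  colnames(counts) <- co$spot_id
  st_dataset(counts, coords = co)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
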