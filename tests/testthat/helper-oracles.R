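# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths.

# Box counting by explicit box enumeration (triple loop over the grid of
# boxes), anchored at the bounding box of the foreground.
brute_box_count <- function(arr, sizes) {
  idx <- which(arr, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  arr <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d <- dim(arr)
  vapply(sizes, function(s) {
    n <- 0L
    for (i in seq(1L, d[1], by = s))
      for (j in seq(1L, d[2], by = s))
        for (k in seq(1L, d[3], by = s)) {
          blk <- arr[i:min(i + s - 1L, d[1]),
                     j:min(j + s - 1L, d[2]),
                     k:min(k + s - 1L, d[3]), drop = FALSE]
          if (any(blk)) n <- n + 1L
        }
    n
  }, integer(1))
}

# Level-`level` Menger sponge occupancy by direct recursion.
brute_menger <- function(level) {
  occ <- array(TRUE, c(1, 1, 1))
  for (l in seq_len(level)) {
    g <- dim(occ)[1] * 3L
    nxt <- array(FALSE, rep(g, 3))
    for (x in 0:(g - 1)) for (y in 0:(g - 1)) for (z in 0:(g - 1)) {
      if (!occ[x %/% 3 + 1, y %/% 3 + 1, z %/% 3 + 1]) next
      ones <- (x %% 3 == 1) + (y %% 3 == 1) + (z %% 3 == 1)
      nxt[x + 1, y + 1, z + 1] <- ones <= 1
    }
    occ <- nxt
  }
  occ
}

# Benjamini-Hochberg step-up by direct definition: find the largest i with
# p_(i) <= i/m * q; adjusted p is the standard min-cummin form computed
# naively.
brute_bh_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[o[i]] <- min(vapply(i:m, function(j) m * p[o[j]] / j, numeric(1)), 1)
  }
  adj
}

# Nested-model F comparison from explicit residual sums; p-value by
# numerical integration of the F density.
brute_nested_f <- function(x1, x2, y) {
  b1 <- qr.solve(crossprod(x1), crossprod(x1, y))
  b2 <- qr.solve(crossprod(x2), crossprod(x2, y))
  rss1 <- sum((y - x1 %*% b1)^2)
  rss2 <- sum((y - x2 %*% b2)^2)
  df1 <- nrow(x1) - ncol(x1); df2 <- nrow(x2) - ncol(x2)
  q <- df1 - df2
  f <- ((rss1 - rss2) / q) / (rss2 / df2)
  dens <- function(t) stats::df(t, q, df2)
  p <- stats::integrate(dens, f, Inf, rel.tol = 1e-10)$value
  list(rss1 = rss1, rss2 = rss2, f = f, p = p)
}

# Trapezoid AUC from the empirical ROC curve.
brute_auc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(c(Inf, th), function(t) mean(scores[labels == 1] >= t), 1)
  fpr <- vapply(c(Inf, th), function(t) mean(scores[labels == 0] >= t), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Random blob mask: union of a few random balls, always non-empty.
random_blob <- function(grid = 24, n_balls = 3, seed = 1) {
  set.seed(seed)
  arr <- array(FALSE, rep(grid, 3))
  ax <- seq_len(grid)
  X <- array(ax, rep(grid, 3))
  Y <- aperm(X, c(2, 1, 3)); Z <- aperm(X, c(3, 2, 1))
  for (b in seq_len(n_balls)) {
    c0 <- stats::runif(3, grid * 0.25, grid * 0.75)
    r <- stats::runif(1, grid * 0.12, grid * 0.3)
    arr <- arr | ((X - c0[1])^2 + (Y - c0[2])^2 + (Z - c0[3])^2 <= r^2)
  }
  if (!any(arr)) arr[grid %/% 2, grid %/% 2, grid %/% 2] <- TRUE
  arr
}
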