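# Independent oracles shared across test files.

# dense PCoA oracle: own MST (Prim), truncation at 4t, double centring
pcnm_oracle <- function(xy) {
  d <- as.matrix(dist(xy))
  n <- nrow(d)
  # Prim's algorithm for the MST longest edge
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  longest <- 0
  for (step in seq_len(n - 1)) {
    j <- which(!in_tree)[which.min(best[!in_tree])]
    longest <- max(longest, best[j])
    in_tree[j] <- TRUE
    best <- pmin(best, d[j, ])
  }
  dt <- d
  dt[dt > longest] <- 4 * longest
  a <- -0.5 * dt^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  e <- eigen(g, symmetric = TRUE)
  v <- e$vectors[, order(-e$values)[1:2]]
  apply(v, 2, function(col) {
    col <- col / sqrt(sum(col^2))
    nz <- which(abs(col) > 1e-12)[1]
    if (col[nz] < 0) -col else col
  })
}
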