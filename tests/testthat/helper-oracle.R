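# Independent nearest-neighbour tricube weighted-least-squares smoother,
# written directly from the definition: for each point, take the ns nearest
# neighbours, weight by tricube of scaled distance, solve the weighted
# degree-1 least-squares problem and evaluate at the point.
lowess_oracle <- function(x, y, f = 0.6) {
  n <- length(x)
  ns <- max(2, min(n, floor(f * n + 1e-7)))
  out <- numeric(n)
  rng <- x[n] - x[1]
  for (i in seq_len(n)) {
    l <- 1
    r <- ns
    while (r < n && (x[i] - x[l]) > (x[r + 1] - x[i])) {
      l <- l + 1
      r <- r + 1
    }
    cut <- x[i]
    h <- max(cut - x[l], x[r] - cut)
    h9 <- 0.999 * h
    h1 <- 0.001 * h
    w <- numeric(n)
    for (j in l:n) {
      d <- abs(x[j] - cut)
      if (d <= h9) {
        w[j] <- if (d <= h1) 1 else (1 - (d / h)^3)^3
      } else if (x[j] > cut) {
        break
      }
    }
    w <- w / sum(w)
    xm <- sum(w * x)
    c2 <- sum(w * (x - xm)^2)
    if (sqrt(c2) > 1e-3 * rng) {
      b <- sum(w * (x - xm) * y) / c2
      out[i] <- sum(w * y) + b * (cut - xm)
    } else {
      out[i] <- sum(w * y)
    }
  }
  out
}
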