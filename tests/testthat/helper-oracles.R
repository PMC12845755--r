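# brute-force oracle: evaluate the between-class variance of every interior
# bin edge directly from the raw values
otsu_bruteforce <- function(values, bins = 256) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  # binned statistics, as in the implementation: values act via bin midpoints
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  idx[idx > bins] <- bins
  mids <- (edges[-1] + edges[-(bins + 1)]) / 2
  vb <- mids[idx]
  cand <- edges[2:bins]
  bcv <- vapply(cand, function(t) {
    lo <- vb < t
    n0 <- sum(lo)
    n1 <- sum(!lo)
    if (n0 == 0 || n1 == 0) return(-Inf)
    n0 * n1 * (mean(vb[lo]) - mean(vb[!lo]))^2
  }, 0)
  cand[which.max(bcv)]
}

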