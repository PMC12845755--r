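#' Otsu histogram thresholding
#'
#' Computes the threshold that maximizes the between-class variance of a
#' two-class split of a binned histogram (Otsu's method). The returned value
#' is an interior bin edge; observations strictly below it fall in the lower
#' class. Ties are broken toward the lowest qualifying threshold, which makes
#' the result deterministic.
#'
#' `multi_otsu_thresholds()` is the two-threshold (three-class) extension,
#' found by exhaustive search over all pairs of bin edges; it is the
#' recommended way to binarize three-phase images (e.g. pore / cell-wall
#' matrix / cell in high-resolution parenchyma scans), where a single Otsu
#' split can only isolate one phase.
#'
#' @param values numeric vector with at least two distinct values.
#' @param bins number of histogram bins (default 256).
#' @return `otsu_threshold()`: a single numeric threshold.
#'   `multi_otsu_thresholds()`: an increasing numeric vector of two
#'   thresholds.
#' @examples
#' x <- c(rnorm(500, 0, 1), rnorm(500, 10, 1))
#' otsu_threshold(x)
#' @export
otsu_threshold <- function(values, bins = 256) {
  h <- otsu_histogram(values, bins)
  # cumulative class 0 = bins 1..t (values below edge t+1)
  w  <- cumsum(h$counts)
  mu <- cumsum(h$counts * h$mids)
  n  <- w[length(w)]
  muT <- mu[length(mu)]
  t_idx <- seq_len(length(h$counts) - 1L)   # split after bin t
  w0 <- w[t_idx]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, length(t_idx))
  m0 <- mu[t_idx] / w0
  m1 <- (muT - mu[t_idx]) / w1
  bcv[valid] <- (w0 * w1)[valid] * (m0 - m1)[valid]^2
  best <- which.max(bcv)                    # which.max takes the first max
  h$edges[best + 1L]
}

#' @rdname otsu_threshold
#' @export
multi_otsu_thresholds <- function(values, bins = 256) {
  h <- otsu_histogram(values, bins)
  w  <- c(0, cumsum(h$counts))
  mu <- c(0, cumsum(h$counts * h$mids))
  n  <- w[length(w)]
  nb <- length(h$counts)
  best <- c(-Inf, NA_integer_, NA_integer_)
  # classes: bins 1..a, a+1..b, b+1..nb
  for (a in 1L:(nb - 2L)) {
    w0 <- w[a + 1L]
    if (w0 == 0) next
    m0 <- mu[a + 1L] / w0
    b <- (a + 1L):(nb - 1L)
    w1 <- w[b + 1L] - w0
    w2 <- n - w[b + 1L]
    ok <- w1 > 0 & w2 > 0
    if (!any(ok)) next
    m1 <- (mu[b + 1L] - mu[a + 1L]) / w1
    m2 <- (mu[nb + 1L] - mu[b + 1L]) / w2
    mT <- mu[nb + 1L] / n
    bcv <- w0 * (m0 - mT)^2 + w1 * (m1 - mT)^2 + w2 * (m2 - mT)^2
    bcv[!ok] <- -Inf
    i <- which.max(bcv)
    if (bcv[i] > best[1]) best <- c(bcv[i], a, b[i])
  }
  if (!is.finite(best[1])) abort("degenerate histogram")
  sort(h$edges[c(best[2] + 1L, best[3] + 1L)])
}

otsu_histogram <- function(values, bins) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 2L || length(unique(values)) < 2L) {
    abort("degenerate histogram: need at least 2 distinct values")
  }
  if (bins < 2L) abort("`bins` must be >= 2")
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  mids <- (edges[-1L] + edges[-(bins + 1L)]) / 2
  # right-open bins except the last, matching findInterval semantics
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > bins] <- bins
  counts <- as.numeric(tabulate(idx, nbins = bins))
  list(edges = edges, mids = mids, counts = counts)
}
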