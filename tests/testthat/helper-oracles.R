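# Independent brute-force oracles used to validate the vectorized
# implementations on small inputs.

# Naive descriptor image: explicit per-pixel loop, explicit mirror patch
# extraction, explicit histogram accumulation. Shares no code with the
# package's sliding/box/offset engines.
naive_descriptor <- function(image, l, bins, kind, weights = NULL,
                             bandwidth = NULL) {
  px <- unclass(image)
  n <- attr(image, "bit_depth")
  nr <- nrow(px)
  nc <- ncol(px)
  f <- switch(kind,
    m1 = function(p) ifelse(p > 0, -p * log(p), 0),
    m2 = function(p) ifelse(p > 0, -p * log(p), 0) +
      ifelse(p < 1, -(1 - p) * log(1 - p), 0),
    m3 = function(p) p * exp(1 - p) + (1 - p) * exp(p) - 1,
    m4 = function(p) p / (1 + p) - p / 2
  )
  refl <- function(i, m) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > m, 2 * m + 1 - i, i)
  }
  k <- (l - 1) / 2
  if (is.null(weights)) weights <- matrix(1, l, l)
  D <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      h <- numeric(bins)
      for (dr in -k:k) {
        for (dc in -k:k) {
          v <- px[refl(r + dr, nr), refl(cc + dc, nc)]
          b <- floor(v * bins / 2^n) + 1
          h[b] <- h[b] + weights[dr + k + 1, dc + k + 1]
        }
      }
      p <- h / sum(h)
      if (!is.null(bandwidth)) {
        # discrete Gaussian smoothing along bins, reflected at edges
        R <- max(1, min(ceiling(4 * bandwidth), bins - 1))
        g <- dnorm(-R:R, sd = bandwidth)
        g <- g / sum(g)
        ps <- numeric(bins)
        for (b in seq_len(bins)) {
          t <- refl(seq(b - R, b + R), bins)
          for (j in seq_along(t)) ps[t[j]] <- ps[t[j]] + g[j] * p[b]
        }
        p <- ps / sum(ps)
      }
      D[r, cc] <- sum(f(p))
    }
  }
  D
}

# Random probability vector over r bins (Dirichlet(1,...,1) via
# exponential spacings).
random_prob_vector <- function(r) {
  e <- rexp(r)
  e / sum(e)
}

# Small deterministic random image.
random_image <- function(nr, nc, n, seed) {
  withr::with_seed(seed,
    intensity_image(matrix(sample(0:(2^n - 1), nr * nc, replace = TRUE),
                           nr, nc), n))
}
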