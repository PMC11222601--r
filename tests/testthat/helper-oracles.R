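# Independent oracles used by the test suite; each re-derives the expected
# quantity by a route different from the package implementation.

# Exact two-sided signed-rank p-value by brute-force enumeration of all
# 2^n sign assignments, written with plain loops over a subset matrix.
oracle_signed_rank_p <- function(x, y) {
  d <- y - x
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- apply(signs, 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Direct (quadruple-loop) 2D Gaussian convolution with replicate padding,
# matching the kernel construction of the implementation but not its code
# path (EBImage filter2 works in the Fourier domain).
oracle_gauss_conv <- function(img, sigma) {
  rad <- ceiling(3 * sigma)
  side <- 2L * rad + 1L
  g <- outer(-rad:rad, -rad:rad,
             function(i, j) exp(-(i^2 + j^2) / (2 * sigma^2)))
  g <- g / sum(g)
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    acc <- 0
    for (i in -rad:rad) for (j in -rad:rad) {
      rr <- min(max(r + i, 1L), h)
      cj <- min(max(cc + j, 1L), w)
      acc <- acc + g[i + rad + 1L, j + rad + 1L] * img[rr, cj]
    }
    out[r, cc] <- acc
  }
  out
}

# Analytic derivative of the bolus curve written from the closed form,
# independent of the package's internal derivative helper.
oracle_bolus_deriv <- function(t, a1, a2, a3, t0) {
  E <- exp(-a2 * t)
  L <- plogis(a3 * (t - t0))
  a1 * (-a2 * E * L + E * L * (1 - L) * a3)
}
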