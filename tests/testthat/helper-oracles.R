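# Brute-force transcription of the Weir & Cockerham (1984) variance
# components for one biallelic locus and r populations, written scalar
# and independent of the vectorized implementation under test.
wc_oracle <- function(n, p, h) {
  r <- length(n)
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
    ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Full enumeration of the hypergeometric upper tail P(X >= k), using
# only binomial coefficients.
hyper_tail_oracle <- function(k, K, N, n) {
  js <- seq(from = k, to = min(n, K))
  if (!length(js) || k < 0) return(1)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
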