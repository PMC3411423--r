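# Internal helpers shared across modules.

# Half-up rounding to match the printed-table style (R's round() is
# round-half-even, which would turn 38.25 into 38.2).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Multivariate normal log-density via Cholesky (small p, used by the EM
# observed-data log-likelihood).
logdmvnorm <- function(x, mu, sigma) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  p <- ncol(x)
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(x) - mu)
  -0.5 * p * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

# Derive a stream of child seeds from one master seed without touching the
# global RNG state ordering downstream (keeps everything below 2^31).
child_seeds <- function(seed, n) {
  (as.integer(seed) + 1000003L * seq_len(n)) %% 2147483562L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
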