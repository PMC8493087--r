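# independent oracles used across tests

# complex matrix exponential by scaling-and-squaring Taylor series; the
# brute-force cross-check for the eigenbasis phase update
expm_complex <- function(M, order = 20) {
  n <- nrow(M)
  s <- max(0, ceiling(log2(max(1e-300, max(Mod(M))))) + 2)
  A <- M / 2^s
  E <- diag(n) + 0i
  term <- diag(n) + 0i
  for (k in seq_len(order)) {
    term <- term %*% A / k
    E <- E + term
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# azimuth of samples in the frame of mu (for radial-symmetry checks)
vmf_azimuths <- function(x, mu) {
  ref <- if (abs(mu[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * mu) * mu
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
          mu[3] * e1[1] - mu[1] * e1[3],
          mu[1] * e1[2] - mu[2] * e1[1])
  atan2(x %*% e2, x %*% e1)
}
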