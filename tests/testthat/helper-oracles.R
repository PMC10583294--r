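# Independent oracles used across the suite.  These deliberately avoid
# the package's simulator internals: the build-up oracle iterates the
# pre-pulse geometric recurrence, the decay oracle is the closed form.

# Pre-pulse recurrence: P_{n+1} = P* + (P_n - P*) r with
# r = cos(theta) exp(-TR/tau) and P* the pre-pulse fixed point.
oracle_pulsed_buildup <- function(P0, tau, theta, TR, n, P_init = 0) {
  ct <- cos(theta * pi / 180)
  e <- exp(-TR / tau)
  r <- ct * e
  Pstar <- P0 * (1 - e) / (1 - r)
  out <- numeric(n)
  # first pre-pulse sample: free evolution from P_init over one TR
  p <- P0 + (P_init - P0) * e
  for (i in seq_len(n)) {
    out[i] <- p
    p <- Pstar + (p - Pstar) * r
  }
  out
}

# Closed-form pulsed decay samples at t_n = n TR (first pulse at TR).
oracle_pulsed_decay <- function(P_init, kR, theta, TR, n) {
  ct <- cos(theta * pi / 180)
  i <- seq_len(n)
  P_init * ct^(i - 1) * exp(-kR * i * TR)
}

# Apparent decay time constant of pre-pulse samples.
oracle_apparent_decay_tau <- function(kR, theta, TR) {
  -TR / log(cos(theta * pi / 180) * exp(-kR * TR))
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
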