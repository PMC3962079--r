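# Independent oracles and small utilities shared across tests. These are
# deliberately naive re-implementations (literal loops, closed forms)
# kept separate from the package's engines.

# Literal triple-loop Debye sum: for each q, loop over all (i, j) pairs.
# fmat is nq x N.
oracle_debye <- function(xyz, fmat, q) {
  n <- nrow(xyz)
  out <- numeric(length(q))
  for (k in seq_along(q)) {
    acc <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        x <- q[k] * r
        s <- if (x < 1e-9) 1 else sin(x) / x
        acc <- acc + fmat[k, i] * fmat[k, j] * s
      }
    }
    out[k] <- acc
  }
  out
}

# Literal transcription of the chi formula.
oracle_chi <- function(i_exp, i_calc, sigma, scale) {
  m <- length(i_exp)
  sqrt(sum(((i_exp - scale * i_calc) / sigma)^2) / m)
}

# Rotation matrix about an arbitrary axis.
rot3 <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  outer(a, a) * (1 - c) + diag(3) * c +
    matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3) * s
}

# A small carbon toy with volumes and zero SASA, common to many tests.
toy_coil <- function(n, seed = 1) make_toy("random_coil", n_atoms = n,
                                           seed = seed)
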