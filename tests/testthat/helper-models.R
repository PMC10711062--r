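# Generators used across the test files.

# A "realistic" unrotated loading matrix: independent-clusters base with
# uniform noise, guaranteed well-conditioned for moderate noise.
rand_loadings <- function(p, q, noise = 0.12, seed = 1) {
  set.seed(seed)
  tgt <- build_icm_target(p, q)
  sal <- runif(p, 0.45, 0.75)
  lam <- unclass(tgt * sal) + matrix(runif(p * q, -noise, noise), p, q)
  attr(lam, "construction") <- NULL
  dimnames(lam) <- dimnames(tgt)
  lam
}

# random orthogonal q x q matrix
rand_orthogonal <- function(q, seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(q * q), q, q)))
}

upper_offdiag <- function(m) m[upper.tri(m)]
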