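# Shared fixtures: small simulated populations and random SPD matrices.

# Random symmetric positive-definite matrix via A'A + ridge.
random_spd <- function(n) {
  A <- matrix(rnorm(n * n), n, n)
  crossprod(A) + diag(0.5, n)
}

# A small two-trait covariance pair used across files.
toy_pair <- function() {
  list(
    P = matrix(c(1, 0.3, 0.3, 1), 2, 2),
    G = matrix(c(0.2, -0.1, -0.1, 0.5), 2, 2),
    d = c(0.5, -0.5)
  )
}

# Dense-inverse oracle for the index equation: explicit matrix inversions,
# independent of the linear-solve path used by dg_weights().
oracle_weights <- function(G, P, d) {
  Pi <- solve(P)
  as.numeric(Pi %*% G %*% solve(G %*% Pi %*% G) %*% d)
}

# Small wheat-like study: simulated reference and candidate populations.
small_study <- function(m_ref = 600, m_cand = 500, seed = 42) {
  params <- wheat_params(m_ref = m_ref, m_cand = m_cand)
  list(
    params = params,
    G = genetic_covariance(params),
    ref = simulate_gebv(params, m = m_ref, seed = seed)$gebv,
    cand = simulate_gebv(params, m = m_cand, seed = seed + 1)$gebv
  )
}
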