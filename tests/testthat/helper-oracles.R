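# Independent oracles used across the suite. These deliberately avoid the
# package's own vectorised code paths: plain loops and textbook formulas.

# explicit-loop Euler integration for a force-controlled point of unit mass
# (velocity before position, matching the documented scheme)
oracle_euler_C <- function(x0, v0, forces, dt) {
  x <- x0; v <- v0
  for (i in seq_len(nrow(forces))) {
    v <- v + forces[i, ] * dt
    x <- x + v * dt
  }
  list(position = x, velocity = v)
}

# plain nested-loop forward pass of the three-layer ELU network
oracle_forward <- function(params, s) {
  elu1 <- function(x) if (x > 0) x else exp(x) - 1
  lin <- function(W, b, h) {
    out <- numeric(nrow(W))
    for (r in seq_len(nrow(W))) out[r] <- sum(W[r, ] * h) + b[r]
    out
  }
  h1 <- vapply(lin(params$W1, params$b1, s), elu1, numeric(1))
  h2 <- vapply(lin(params$W2, params$b2, h1), elu1, numeric(1))
  list(mu = lin(params$W3_mu, params$b3_mu, h2),
       sigma = exp(lin(params$W3_sig, params$b3_sig, h2)))
}

# explicit-loop discounted sum
oracle_discounted <- function(r, gamma) {
  acc <- 0
  for (kk in seq_along(r)) acc <- acc + gamma^(kk - 1) * r[kk]
  acc
}

# textbook bivariate normal log-density (independent components)
oracle_logp <- function(mu, sigma, a) {
  log(stats::dnorm(a[1], mu[1], sigma[1])) +
    log(stats::dnorm(a[2], mu[2], sigma[2]))
}

# numeric quadrature of the stretched-exponential density
stretched_density <- function(f, f0, beta)
  (1 / f0) * (beta / gamma(1 / beta)) * exp(-(f / f0)^beta)

stretched_cdf <- function(q, f0, beta)
  vapply(q, function(x)
    stats::integrate(stretched_density, 0, x, f0 = f0, beta = beta,
                     rel.tol = 1e-10)$value, numeric(1))

# small deterministic policy for tests that need a fixed network
tiny_policy <- function(d_s, seed = 42L) policy_init(d_s, seed = seed, hidden = 8L)

# dense brute-force solve of the common-velocity problem built directly
# from pair blocks (independent of mobility_matrix assembly order)
oracle_common_velocity <- function(positions, v, p) {
  N <- nrow(positions)
  Z <- matrix(0, 2 * N, 2 * N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    B <- if (i == j) pair_block(NULL, p) else
      pair_block(positions[i, ] - positions[j, ], p, warn = FALSE)
    Z[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)] <- B
  }
  Fa <- solve(Z, rep(v, N))
  list(forces = matrix(Fa, N, 2, byrow = TRUE),
       power = sum(Fa^2) / (6 * pi * p$eta_fluid * p$a))
}
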