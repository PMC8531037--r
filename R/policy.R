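# Stochastic Gaussian action policy pi_theta(a | s).
#
# Architecture: three fully connected layers, hidden width 128, ELU
# activations after the first two layers; the output layer splits into a
# linear mean head mu(s) and a sigma head passed through exp() so the
# standard deviation is strictly positive:
#
#   h1 = ELU(W1 s + b1)          (128 x d_s)
#   h2 = ELU(W2 h1 + b2)         (128 x 128)
#   mu    = W3_mu    h2 + b3_mu  (2 x 128)
#   sigma = exp(W3_sig h2 + b3_sig)
#
# Actions are sampled from N(mu, diag(sigma^2)) and then norm-clipped to the
# physical bound; the log-density used by the gradient estimator is always
# evaluated at the raw (pre-clip) Gaussian draw, which keeps the REINFORCE
# estimator unbiased for the pre-clip distribution.

# branchless forms (hot path: matrices with millions of elements).
# Note ELU'(x) = 1 for x > 0 and ELU(x) + 1 otherwise, so the derivative is
# recovered from the activation value without a second exp().
elu <- function(x) exp(pmin(x, 0)) - 1 + pmax(x, 0)
elu_prime <- function(x) pmin(elu(x) + 1, 1)
elu_prime_from_h <- function(h) pmin(h + 1, 1)

# numerical guard rails for the exp() sigma head: an unbounded head can
# collapse (sigma -> 0 makes the score function explode) or blow up during
# training. The pre-activation is hard-clamped and the corresponding
# gradient zeroed at the rails.
SIG_LOG_MIN <- log(0.02)
SIG_LOG_MAX <- log(50)

#' Initialise policy parameters
#'
#' Every weight and bias is drawn uniformly on
#' `[-1/sqrt(fan_in), +1/sqrt(fan_in)]`, so a fresh policy has mean near 0
#' and standard deviation near 1 in every state: a broad exploratory policy.
#'
#' @param d_s observation dimension.
#' @param seed integer RNG seed (`NULL` to use the current RNG state).
#' @param hidden hidden-layer width (default 128).
#' @return an object of class `policy_params`: a named list of matrices
#'   `W1, b1, W2, b2, W3_mu, b3_mu, W3_sig, b3_sig`.
#' @export
policy_init <- function(d_s, seed = NULL, hidden = 128L) {
  stopifnot(d_s >= 1L, hidden >= 1L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  u <- function(nr, nc, fan_in) {
    w <- 1 / sqrt(fan_in)
    matrix(stats::runif(nr * nc, -w, w), nr, nc)
  }
  p <- list(
    W1 = u(hidden, d_s, d_s),      b1 = u(hidden, 1, d_s),
    W2 = u(hidden, hidden, hidden), b2 = u(hidden, 1, hidden),
    W3_mu = u(2, hidden, hidden),   b3_mu = u(2, 1, hidden),
    W3_sig = u(2, hidden, hidden),  b3_sig = u(2, 1, hidden))
  attr(p, "d_s") <- as.integer(d_s)
  class(p) <- "policy_params"
  p
}

#' Forward pass of the policy network
#'
#' Evaluates the action distribution for a batch of observations.
#'
#' @param params a [policy_init()] parameter set.
#' @param S observation matrix `d_s x m` (a single observation vector is
#'   promoted to one column).
#' @param cache logical; keep pre-activations for backpropagation.
#' @return list with `mu` and `sigma` (`2 x m` matrices, `sigma > 0`), and
#'   the hidden quantities when `cache = TRUE`.
#' @export
policy_forward <- function(params, S, cache = FALSE) {
  if (!is.matrix(S)) S <- matrix(S, ncol = 1)
  if (nrow(S) != attr(params, "d_s"))
    stop(sprintf("observation dim %d does not match policy d_s %d",
                 nrow(S), attr(params, "d_s")), call. = FALSE)
  # length-vector addition recycles down columns: broadcast of the biases
  Z1 <- params$W1 %*% S + as.vector(params$b1)
  H1 <- elu(Z1)
  Z2 <- params$W2 %*% H1 + as.vector(params$b2)
  H2 <- elu(Z2)
  mu <- params$W3_mu %*% H2 + as.vector(params$b3_mu)
  zs <- params$W3_sig %*% H2 + as.vector(params$b3_sig)
  sigma <- exp(pmin(pmax(zs, SIG_LOG_MIN), SIG_LOG_MAX))
  out <- list(mu = mu, sigma = sigma)
  if (cache) out[c("S", "H1", "H2")] <- list(S, H1, H2)
  out
}

#' Sample actions from the policy
#'
#' Draws `a ~ N(mu, diag(sigma^2))` column-wise, then norm-clips to `bound`.
#' The raw draw is returned alongside because the log-density in the
#' gradient estimator is evaluated at the raw value.
#'
#' @param dist output of [policy_forward()].
#' @param bound positive norm bound (`Inf` for unbounded).
#' @return list with `raw` and `action` (`2 x m` matrices).
#' @export
policy_sample <- function(dist, bound = Inf) {
  m <- ncol(dist$mu)
  raw <- dist$mu + dist$sigma * matrix(stats::rnorm(2 * m), 2, m)
  a <- raw
  if (is.finite(bound)) {
    n <- sqrt(colSums(a^2))
    over <- n > bound
    if (any(over)) a[, over] <- a[, over, drop = FALSE] *
        rep(bound / n[over], each = 2)
  }
  list(raw = raw, action = a)
}

#' Gaussian log-density of actions
#'
#' Sum over the two action components of the normal log-pdf, evaluated at
#' the raw (pre-clip) draws.
#'
#' @param dist output of [policy_forward()].
#' @param A `2 x m` matrix of raw actions.
#' @return numeric vector of length m.
#' @export
policy_logp <- function(dist, A) {
  if (!is.matrix(A)) A <- matrix(A, ncol = 1)
  z <- (A - dist$mu) / dist$sigma
  colSums(-0.5 * log(2 * pi) - log(dist$sigma) - 0.5 * z^2)
}

#' Weighted score-function gradient
#'
#' Computes `grad_theta sum_j w_j log pi_theta(a_j | s_j)` by
#' backpropagation over the whole batch at once. This is the core of the
#' EPISODIC REINFORCE estimator: with `w_j` the discounted reward-to-go
#' (minus baseline) of transition j, the result divided by the number of
#' episodes is the policy-gradient estimate.
#'
#' @param params policy parameters.
#' @param S `d_s x m` observation matrix.
#' @param A `2 x m` matrix of raw actions.
#' @param w numeric length-m weights.
#' @return a gradient with the same shapes as `params`.
#' @export
policy_grad <- function(params, S, A, w) {
  if (!is.matrix(S)) S <- matrix(S, ncol = 1)
  if (!is.matrix(A)) A <- matrix(A, ncol = 1)
  fw <- policy_forward(params, S, cache = TRUE)
  m <- ncol(S)
  W <- matrix(w, 2, m, byrow = TRUE)
  Zn <- (A - fw$mu) / fw$sigma
  G_mu <- W * Zn / fw$sigma             # d logp / d mu
  G_zs <- W * (Zn^2 - 1)                # d logp / d (log sigma)
  # zero the sigma-head gradient where the clamp rails are active
  G_zs[fw$sigma <= exp(SIG_LOG_MIN) | fw$sigma >= exp(SIG_LOG_MAX)] <- 0
  g <- list(
    W3_mu = tcrossprod(G_mu, fw$H2), b3_mu = matrix(rowSums(G_mu), 2, 1),
    W3_sig = tcrossprod(G_zs, fw$H2), b3_sig = matrix(rowSums(G_zs), 2, 1))
  GH2 <- crossprod(params$W3_mu, G_mu) + crossprod(params$W3_sig, G_zs)
  GZ2 <- GH2 * elu_prime_from_h(fw$H2)
  g$W2 <- tcrossprod(GZ2, fw$H1); g$b2 <- matrix(rowSums(GZ2), ncol = 1)
  GH1 <- crossprod(params$W2, GZ2)
  GZ1 <- GH1 * elu_prime_from_h(fw$H1)
  g$W1 <- tcrossprod(GZ1, fw$S); g$b1 <- matrix(rowSums(GZ1), ncol = 1)
  g[names(params)]
}

#' Flatten / restore policy parameters
#'
#' @param params policy parameters.
#' @return numeric vector of all parameters in a fixed order.
#' @export
policy_flatten <- function(params) unlist(lapply(params, as.numeric), use.names = FALSE)

#' @rdname policy_flatten
#' @param template a `policy_params` object supplying shapes and class.
#' @param x numeric vector from [policy_flatten()].
#' @return a `policy_params` object.
#' @export
policy_unflatten <- function(template, x) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    k <- length(template[[nm]])
    out[[nm]] <- matrix(x[pos + seq_len(k)], nrow(template[[nm]]),
                        ncol(template[[nm]]))
    pos <- pos + k
  }
  stopifnot(pos == length(x))
  out
}

#' Save / load a policy snapshot as plain text
#'
#' The flattened parameter vector is written as CSV next to a JSON manifest
#' recording the shapes, observation dimension and any metadata supplied --
#' enough to restore the policy bit-for-bit.
#'
#' @param params policy parameters.
#' @param path file stem; writes `<path>.csv` and `<path>.json`.
#' @param meta named list of extra manifest entries (seed, config hash, ...).
#' @return invisibly, the manifest list.
#' @export
policy_save <- function(params, path, meta = list()) {
  vals <- policy_flatten(params)
  utils::write.csv(data.frame(value = vals), paste0(path, ".csv"),
                   row.names = FALSE)
  manifest <- c(list(
    d_s = attr(params, "d_s"),
    shapes = lapply(params, dim),
    n_params = length(vals)), meta)
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' @rdname policy_save
#' @export
policy_load <- function(path) {
  manifest <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- utils::read.csv(paste0(path, ".csv"))$value
  template <- policy_init(manifest$d_s, seed = 0L,
                          hidden = manifest$shapes$W2[1])
  policy_unflatten(template, vals)
}
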