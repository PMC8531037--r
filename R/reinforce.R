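# EPISODIC REINFORCE: discounted returns, the score-function gradient
# estimate averaged over a batch of episodes, and plain gradient ascent
# theta_{k+1} = theta_k + lr * grad <R>_k.

#' Discounted return
#'
#' `sum_k gamma^k r_k` of a reward sequence (gamma = 0.9 by default
#' throughout the package).
#'
#' @param rewards numeric reward sequence (possibly empty -> 0).
#' @param gamma discount factor in (0,1).
#' @return scalar.
#' @export
discounted_return <- function(rewards, gamma) {
  stopifnot(gamma > 0, gamma < 1)
  if (length(rewards) == 0L) return(0)
  sum(gamma^(seq_along(rewards) - 1) * rewards)
}

#' Discounted reward-to-go
#'
#' `G_t = sum_{k >= t} gamma^(k-t) r_k` for every t, computed by a backward
#' recursion.
#'
#' @inheritParams discounted_return
#' @return numeric vector of the same length as `rewards`.
#' @export
reward_to_go <- function(rewards, gamma) {
  stopifnot(gamma > 0, gamma < 1)
  T_len <- length(rewards)
  if (T_len == 0L) return(numeric(0))
  G <- numeric(T_len)
  acc <- 0
  for (t in T_len:1) {
    acc <- rewards[t] + gamma * acc
    G[t] <- acc
  }
  G
}

#' Advantage weights for a batch of equal-length episodes
#'
#' Reward-to-go per episode; with `baseline = TRUE` the per-time-step mean
#' of `G_t` across the episodes of the batch is subtracted (a control
#' variate: it changes the variance of the estimator, not its mean).
#'
#' @param reward_mat `T x n_ep` matrix of rewards (column = episode).
#' @param gamma discount factor.
#' @param baseline subtract the across-episode mean of `G_t`?
#' @return `T x n_ep` matrix of weights.
#' @export
advantages <- function(reward_mat, gamma, baseline = TRUE) {
  G <- apply(reward_mat, 2, reward_to_go, gamma = gamma)
  if (!is.matrix(G)) G <- matrix(G, nrow = 1)
  if (baseline && ncol(G) > 1L) G <- G - rowMeans(G)
  G
}

#' Gradient-ascent parameter update
#'
#' @param params policy parameters.
#' @param grad gradient with matching shapes.
#' @param lr learning rate (> 0).
#' @param max_norm optional global gradient-norm cap: when the Euclidean
#'   norm of the full gradient exceeds it, the gradient is rescaled
#'   (direction preserved). `Inf` (default) disables the cap; the training
#'   loops use a finite cap as a divergence guard.
#' @return updated parameters.
#' @export
policy_update <- function(params, grad, lr, max_norm = Inf) {
  stopifnot(lr > 0)
  if (is.finite(max_norm)) {
    gn <- sqrt(sum(vapply(grad, function(m) sum(m^2), numeric(1))))
    if (is.finite(gn) && gn > max_norm)
      grad <- lapply(grad, function(m) m * (max_norm / gn))
  }
  for (nm in names(params)) {
    g <- grad[[nm]]
    if (!all(is.finite(g)))
      stop(sprintf("non-finite gradient in '%s'; training diverged", nm),
           call. = FALSE)
    params[[nm]] <- params[[nm]] + lr * g
  }
  params
}

#' Train a policy by EPISODIC REINFORCE
#'
#' Generic training loop: per update, `rollout(params, n)` collects a batch
#' of `n` equal-length episodes; the discounted reward-to-go forms the
#' weights of the score-function gradient, which is averaged over episodes
#' and applied by plain gradient ascent.
#'
#' @param rollout function `(params, n) -> list(S, A, R)` where `S` is
#'   `d_s x (T*n)`, `A` is `2 x (T*n)` (raw pre-clip draws) and `R` is a
#'   `T x n` reward matrix; transitions are ordered episode-major
#'   (episode 1 steps 1..T, then episode 2, ...).
#' @param params initial policy parameters.
#' @param updates number of gradient updates.
#' @param n episodes per update.
#' @param lr learning rate.
#' @param gamma discount factor.
#' @param baseline use the mean reward-to-go baseline?
#' @param max_grad_norm global gradient-norm cap passed to [policy_update()].
#' @param optimizer `"sgd"` (plain ascent, default) or `"adam"`; see
#'   [make_optimizer()].
#' @param verbose print progress every 50 updates?
#' @return list with `params` and `metrics` (data.frame: update,
#'   mean_return, mean_sigma).
#' @export
reinforce_train <- function(rollout, params, updates = 200L, n = 16L,
                            lr = 1e-3, gamma = 0.9, baseline = TRUE,
                            max_grad_norm = 10, optimizer = "sgd",
                            verbose = FALSE) {
  step <- make_optimizer(optimizer, lr = lr, max_norm = max_grad_norm)
  ostate <- NULL
  metrics <- data.frame(update = integer(0), mean_return = numeric(0),
                        mean_sigma = numeric(0))
  for (k in seq_len(updates)) {
    batch <- rollout(params, n)
    n_ep <- ncol(batch$R)
    W <- advantages(batch$R, gamma, baseline = baseline)
    # transitions are step-major (all episodes at t, then t+1, ...): the
    # T x n weight matrix must be transposed before flattening
    g <- policy_grad(params, batch$S, batch$A, as.numeric(t(W)) / n_ep)
    stp <- step(params, g, ostate)
    params <- stp$params; ostate <- stp$state
    mret <- mean(apply(batch$R, 2, discounted_return, gamma = gamma))
    msig <- mean(policy_forward(params, batch$S[, 1, drop = FALSE])$sigma)
    metrics[k, ] <- list(k, mret, msig)
    if (!is.finite(mret)) stop("mean return diverged", call. = FALSE)
    if (verbose && k %% 50L == 0L)
      message(sprintf("update %d: mean return %.4f", k, mret))
  }
  list(params = params, metrics = metrics)
}

#' Gaussian-bandit rollout factory (diagnostic task)
#'
#' One-step episodes with a fixed state and reward `-||a||^2`; the optimal
#' policy mean is the origin, which makes this a closed-form check of the
#' whole estimator/update pipeline.
#'
#' @param d_s state dimension; the fixed state is `(1, 0, ..., 0)`.
#' @param bound action norm bound (`Inf` by default: rewards use the raw
#'   draw so the analytic optimum is exact).
#' @return a rollout function usable with [reinforce_train()].
#' @export
bandit_rollout <- function(d_s = 2L, bound = Inf) {
  s <- c(1, rep(0, d_s - 1L))
  function(params, n) {
    S <- matrix(s, d_s, n)
    dist <- policy_forward(params, S)
    smp <- policy_sample(dist, bound)
    r <- -colSums(smp$action^2)
    list(S = S, A = smp$raw, R = matrix(r, 1, n))
  }
}
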