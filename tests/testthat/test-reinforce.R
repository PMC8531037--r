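test_that("discounted return and reward-to-go match the loop oracle", {
  expect_equal(discounted_return(c(1, 1, 1), 0.9), 2.71)
  expect_equal(discounted_return(numeric(0), 0.9), 0)
  expect_equal(discounted_return(rep(0, 10), 0.9), 0)
  set.seed(29)
  for (i in 1:10) {
    r <- rnorm(sample(1:30, 1))
    g <- runif(1, 0.05, 0.99)
    expect_equal(discounted_return(r, g), oracle_discounted(r, g),
                 tolerance = 1e-12)
    G <- reward_to_go(r, g)
    expect_equal(G[1], oracle_discounted(r, g), tolerance = 1e-12)
    # suffix property: G_t = r_t + gamma * G_{t+1}
    if (length(r) > 1)
      expect_equal(G[-length(r)], r[-length(r)] + g * G[-1],
                   tolerance = 1e-12)
  }
})

test_that("update rule is plain element-wise ascent", {
  p <- tiny_policy(3)
  zero <- lapply(p, function(m) m * 0)
  expect_equal(policy_update(p, zero, 1), p)
  g <- lapply(p, function(m) matrix(1, nrow(m), ncol(m)))
  p1 <- policy_update(p, g, 1)
  expect_equal(p1$W2, p$W2 + 1)
  # two half-steps equal one full step for a constant gradient
  p_half <- policy_update(policy_update(p, g, 0.5), g, 0.5)
  expect_equal(policy_flatten(p_half), policy_flatten(p1), tolerance = 1e-12)
  bad <- g; bad$W1[1, 1] <- NaN
  expect_error(policy_update(p, bad, 1), "non-finite")
})

# state-independent policy: all weights zero, so mu = b3_mu, sigma = exp(b3_sig)
flat_policy <- function(mu, sigma) {
  p <- tiny_policy(2)
  p <- policy_unflatten(p, rep(0, length(policy_flatten(p))))
  p$b3_mu <- matrix(mu)
  p$b3_sig <- matrix(log(sigma))
  p
}

test_that("REINFORCE estimate matches the analytic bandit gradient", {
  # r(a) = -||a||^2, a ~ N(mu, sigma^2 I): <R> = -(||mu||^2 + 2 sigma^2)
  # => d<R>/d mu = -2 mu, reachable through b3_mu since mu = b3_mu here.
  mu <- c(1, 0.5); sigma <- 0.05
  p <- flat_policy(mu, sigma)
  nchunk <- 50L; m <- 400L
  est <- matrix(0, nchunk, 2)
  set.seed(37)
  for (ch in seq_len(nchunk)) {
    S <- matrix(c(1, 0), 2, m)
    dist <- policy_forward(p, S)
    smp <- policy_sample(dist, Inf)
    r <- -colSums(smp$raw^2)
    g <- policy_grad(p, S, smp$raw, r / m) # baseline off
    est[ch, ] <- as.numeric(g$b3_mu)
  }
  se <- apply(est, 2, sd) / sqrt(nchunk)
  expect_lt(abs(mean(est[, 1]) - (-2 * mu[1])), 3 * se[1])
  expect_lt(abs(mean(est[, 2]) - (-2 * mu[2])), 3 * se[2])
})

test_that("constant rewards with baseline give a vanishing gradient", {
  p <- tiny_policy(2)
  set.seed(41)
  S <- matrix(rnorm(2 * 8), 2, 8)
  dist <- policy_forward(p, S)
  smp <- policy_sample(dist, Inf)
  R <- matrix(5, 1, 8) # one-step episodes, identical rewards
  W <- advantages(R, 0.9, baseline = TRUE)
  expect_equal(max(abs(W)), 0)
  g <- policy_grad(p, S, smp$raw, as.numeric(W) / 8)
  expect_equal(max(abs(policy_flatten(g))), 0)
})

test_that("estimator mean matches finite differences on a 2-step MDP", {
  # MDP: s0 fixed; s1 = sin(a0); r0 = -||a0||^2 / 4; r1 = -||a1 - s1||^2.
  gamma <- 0.9
  s0 <- c(0.5, -0.3)
  p <- policy_init(2, seed = 43, hidden = 8)
  run_batch <- function(params, m) {
    S0 <- matrix(s0, 2, m)
    d0 <- policy_forward(params, S0)
    a0 <- policy_sample(d0, Inf)$raw
    S1 <- sin(a0)
    d1 <- policy_forward(params, S1)
    a1 <- policy_sample(d1, Inf)$raw
    r0 <- -colSums(a0^2) / 4
    r1 <- -colSums((a1 - S1)^2)
    # step-major transition layout, weights = reward-to-go
    list(S = cbind(S0, S1), A = cbind(a0, a1),
         w = c(r0 + gamma * r1, gamma * r1), ret = r0 + gamma * r1)
  }
  # REINFORCE estimate over chunks -> mean and SE per coordinate
  nchunk <- 60L; m <- 300L
  coords <- c(1, 5, 40, 90, 101, 120) # spread across W1/b1/W2 blocks
  set.seed(47)
  est <- matrix(0, nchunk, length(coords))
  for (ch in seq_len(nchunk)) {
    b <- run_batch(p, m)
    g <- policy_flatten(policy_grad(p, b$S, b$A, b$w / m))
    est[ch, ] <- g[coords]
  }
  gbar <- colMeans(est)
  se <- apply(est, 2, sd) / sqrt(nchunk)
  # finite-difference oracle with common random numbers
  mfd <- 40000L
  set.seed(53)
  Z0 <- matrix(rnorm(2 * mfd), 2, mfd)
  Z1 <- matrix(rnorm(2 * mfd), 2, mfd)
  mean_return <- function(params) {
    S0 <- matrix(s0, 2, mfd)
    d0 <- policy_forward(params, S0)
    a0 <- d0$mu + d0$sigma * Z0
    S1 <- sin(a0)
    d1 <- policy_forward(params, S1)
    a1 <- d1$mu + d1$sigma * Z1
    mean(-colSums(a0^2) / 4 + gamma * (-colSums((a1 - S1)^2)))
  }
  x0 <- policy_flatten(p)
  h <- 1e-4
  for (j in seq_along(coords)) {
    xp <- x0; xp[coords[j]] <- xp[coords[j]] + h
    xm <- x0; xm[coords[j]] <- xm[coords[j]] - h
    fd <- (mean_return(policy_unflatten(p, xp)) -
             mean_return(policy_unflatten(p, xm))) / (2 * h)
    expect_lt(abs(gbar[j] - fd), 3 * se[j] + 0.02)
  }
})

test_that("baseline changes variance but not the estimator mean", {
  mu <- c(0.6, -0.4); sigma <- 0.5
  p <- flat_policy(mu, sigma)
  nchunk <- 80L; m <- 200L
  est_b <- matrix(0, nchunk, 2); est_n <- matrix(0, nchunk, 2)
  set.seed(59)
  for (ch in seq_len(nchunk)) {
    S <- matrix(c(1, 0), 2, m)
    smp <- policy_sample(policy_forward(p, S), Inf)
    R <- matrix(-colSums(smp$raw^2), 1, m)
    for (bl in c(TRUE, FALSE)) {
      W <- advantages(R, 0.9, baseline = bl)
      g <- policy_grad(p, S, smp$raw, as.numeric(W) / m)
      if (bl) est_b[ch, ] <- as.numeric(g$b3_mu) else
        est_n[ch, ] <- as.numeric(g$b3_mu)
    }
  }
  for (j in 1:2) {
    se <- sqrt(var(est_b[, j]) / nchunk + var(est_n[, j]) / nchunk)
    expect_lt(abs(mean(est_b[, j]) - mean(est_n[, j])), 4 * se)
  }
})

test_that("training recovers the bandit optimum and is seed-deterministic", {
  set.seed(61)
  p <- policy_init(2)
  fit <- reinforce_train(bandit_rollout(2), p, updates = 200, n = 64,
                         lr = 2e-3, gamma = 0.9)
  mu <- policy_forward(fit$params, c(1, 0))$mu
  expect_lt(sqrt(sum(mu^2)), 0.1)
  # moving-average of the return is non-decreasing from start to end
  ma <- stats::filter(fit$metrics$mean_return, rep(1 / 25, 25), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_gt(tail(ma, 1), ma[1])
  # determinism: the whole learning curve reproduces bit-for-bit
  set.seed(61)
  p2 <- policy_init(2)
  fit2 <- reinforce_train(bandit_rollout(2), p2, updates = 20, n = 16,
                          lr = 2e-3, gamma = 0.9)
  set.seed(61)
  p3 <- policy_init(2)
  fit3 <- reinforce_train(bandit_rollout(2), p3, updates = 20, n = 16,
                          lr = 2e-3, gamma = 0.9)
  expect_identical(fit2$metrics, fit3$metrics)
  expect_identical(policy_flatten(fit2$params), policy_flatten(fit3$params))
})

test_that("escort training improves on the untrained policy (paired seeds)", {
  cfg <- env_config(T_steps = 120L, d_t = 1, e_t = 0.3, v_max = 1, v0 = 0.3,
                    init_radius = 1.5)
  path <- leader_path("circle", R = 2, speed = 0.4)
  fit <- train_escort(path, cfg, mode = "A", updates = 60, n = 8, lr = 2e-3,
                      seed = 5)
  set.seed(1005)
  untrained <- policy_init(obs_dim("escort"))
  eval_mean <- function(params) {
    mean(vapply(1:4, function(s)
      attr(run_escort_episode(params, path, cfg, mode = "A", seed = 300 + s),
           "mean_reward"), numeric(1)))
  }
  expect_gt(eval_mean(fit$params), eval_mean(untrained))
  # the learning curve itself should rise
  expect_gt(mean(tail(fit$metrics$mean_return, 10)),
            mean(head(fit$metrics$mean_return, 10)))
})

test_that("optimizers: sgd equals the printed rule, adam is stateful ascent", {
  p <- tiny_policy(3)
  g <- lapply(p, function(m) matrix(0.1, nrow(m), ncol(m)))
  sgd <- make_optimizer("sgd", lr = 0.5, max_norm = Inf)
  expect_equal(policy_flatten(sgd(p, g)$params),
               policy_flatten(policy_update(p, g, 0.5)))
  adam <- make_optimizer("adam", lr = 0.01, max_norm = Inf)
  zero <- lapply(p, function(m) m * 0)
  s1 <- adam(p, zero)
  expect_equal(policy_flatten(s1$params), policy_flatten(p)) # no move
  # constant positive gradient: every coordinate moves up, twice
  s2 <- adam(p, g)
  expect_true(all(policy_flatten(s2$params) > policy_flatten(p)))
  s3 <- adam(s2$params, g, s2$state)
  expect_true(all(policy_flatten(s3$params) > policy_flatten(s2$params)))
  expect_equal(s3$state$t, 2L)
  # the norm cap rescales without changing direction
  capped <- make_optimizer("sgd", lr = 1, max_norm = 1e-3)
  moved <- policy_flatten(capped(p, g)$params) - policy_flatten(p)
  expect_equal(sqrt(sum(moved^2)), 1e-3, tolerance = 1e-10)
})
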