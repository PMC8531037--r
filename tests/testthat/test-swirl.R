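test_that("angular velocity obeys the rigid-body and invariance identities", {
  # 4 agents on the unit circle in rigid counterclockwise rotation, w = 0.5
  th <- c(0, pi / 2, pi, 3 * pi / 2)
  P <- cbind(cos(th), sin(th))
  w <- 0.5
  V <- w * cbind(-sin(th), cos(th))
  # documented operand order: counterclockwise rotation gives Omega = -w
  expect_equal(angular_velocity(P, V), -w, tolerance = 1e-14)
  expect_equal(abs(angular_velocity(P, V)), w)
  # rigid translation: exactly zero
  Vt <- matrix(c(1.3, -0.4), 4, 2, byrow = TRUE)
  expect_equal(angular_velocity(P, Vt), 0)
  # Galilean invariance: adding a constant velocity changes nothing
  expect_equal(angular_velocity(P, V + Vt), angular_velocity(P, V),
               tolerance = 1e-14)
  # parity: mirror reflection flips the sign
  set.seed(31)
  for (i in 1:10) {
    Pr <- matrix(rnorm(12), 6, 2)
    Vr <- matrix(rnorm(12), 6, 2)
    Pm <- Pr; Pm[, 1] <- -Pm[, 1]
    Vm <- Vr; Vm[, 1] <- -Vm[, 1]
    expect_equal(angular_velocity(Pm, Vm), -angular_velocity(Pr, Vr),
                 tolerance = 1e-12)
  }
  # an agent exactly at the group centre is excluded with a warning
  Pz <- rbind(c(0, 0), c(2, 0), c(-2, 0), c(0, 2), c(0, -2))
  expect_warning(om <- angular_velocity(Pz, matrix(rnorm(10), 5, 2)))
  expect_true(is.finite(om))
})

test_that("an untrained swarm disintegrates with Omega at the noise floor", {
  cfg <- env_config(N = 10L, T_steps = 120L, seed = 1)
  set.seed(71)
  un <- policy_init(obs_dim("swarm"))
  ep <- run_swarm_episode(un, cfg, seed = 7)
  expect_length(ep$omega, 120L)
  expect_true(all(is.finite(ep$omega)))
  # spatial extent grows well beyond the initial disk
  expect_gt(tail(ep$extent, 1), 2 * ep$extent[1])
  # time-averaged signed Omega over the last quarter is at the noise floor
  expect_lt(abs(mean(ep$omega[91:120])), 0.15)
  # group-centre track is returned alongside
  expect_equal(dim(ep$x_gc), c(120L, 2L))
})

test_that("swarm training is reproducible and per-agent learning is isolated", {
  cfg <- env_config(N = 3L, T_steps = 30L, d_cz = 0.3, seed = 1)
  # bitwise-reproducible learning curve under a fixed seed
  f1 <- train_swarm(cfg, updates = 3, n = 2, seed = 9)
  f2 <- train_swarm(cfg, updates = 3, n = 2, seed = 9)
  expect_identical(f1$metrics, f2$metrics)
  expect_identical(policy_flatten(f1$policies), policy_flatten(f2$policies))
  # per-agent mode: agents hold distinct networks, updated only from their
  # own rewards -- zeroing agent j's rewards leaves the other gradients
  # untouched
  set.seed(11)
  policies <- replicate(3, policy_init(obs_dim("swarm")), simplify = FALSE)
  roll <- swirlkit:::swarm_rollout(cfg, shared = FALSE)
  set.seed(12)
  batch <- roll(policies, 2L)
  N <- 3L; n <- 2L; T_steps <- cfg$T_steps
  grad_agent <- function(i, R) {
    idx <- as.vector(outer((seq_len(T_steps) - 1L) * N * n,
                           (seq_len(n) - 1L) * N, "+") + i)
    Wi <- advantages(R[, i + (seq_len(n) - 1L) * N, drop = FALSE], cfg$gamma)
    policy_flatten(policy_grad(policies[[i]], batch$S[, idx, drop = FALSE],
                               batch$A[, idx, drop = FALSE],
                               as.numeric(Wi) / n))
  }
  R0 <- batch$R
  Rz <- batch$R
  Rz[, c(2, 2 + N)] <- 0 # zero agent 2's rewards in both episodes
  expect_identical(grad_agent(1, R0), grad_agent(1, Rz))
  expect_identical(grad_agent(3, R0), grad_agent(3, Rz))
  expect_false(identical(grad_agent(2, R0), grad_agent(2, Rz)))
})

test_that("per-agent training runs and improves at smoke scale", {
  cfg <- env_config(N = 2L, T_steps = 40L, d_cz = 0.3, init_radius = 1.5,
                    seed = 1)
  fit <- train_swarm(cfg, updates = 10, n = 4, lr = 2e-3, shared = FALSE,
                     seed = 21)
  expect_length(fit$policies, 2L)
  expect_false(identical(policy_flatten(fit$policies[[1]]),
                         policy_flatten(fit$policies[[2]])))
  expect_true(all(is.finite(fit$metrics$mean_return)))
})

test_that("a perception radius smaller than spacing blinds the agents", {
  cfg <- env_config(N = 4L, T_steps = 10L, R_p = 0.01, seed = 1)
  set.seed(77)
  un <- policy_init(obs_dim("swarm"))
  ep <- run_swarm_episode(un, cfg, seed = 3)
  # no neighbour is ever perceivable at this radius, and each agent is its
  # own perceived group (always at its centre): rewards are r_target + 0
  expect_true(all(ep$rewards == reward_constants()$r_target))
})

test_that("sigma_lr_scale damps only the sigma-head update", {
  cfg <- env_config(N = 2L, T_steps = 20L, seed = 1)
  # one update from identical rollouts: only the sigma head may differ
  f1 <- train_swarm(cfg, updates = 1, n = 2, seed = 13, sigma_lr_scale = 0.3)
  f2 <- train_swarm(cfg, updates = 1, n = 2, seed = 13, sigma_lr_scale = 1)
  expect_equal(f1$metrics$mean_return, f2$metrics$mean_return)
  expect_identical(f1$policies$W1, f2$policies$W1)
  expect_identical(f1$policies$W3_mu, f2$policies$W3_mu)
  expect_false(identical(f1$policies$W3_sig, f2$policies$W3_sig))
})
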