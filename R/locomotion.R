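# RL locomotion task: a leader translating at fixed velocity through
# viscous fluid plus followers that choose their propulsion forces. The
# followers are rewarded for staying in the leader's target zone while
# keeping out of each other's comfort zones, and pay an energy penalty for
# their effort once settled -- which drives the group to the
# dissipation-minimal formation.

#' Default environment configuration for the locomotion task
#'
#' Geometry scaled to the agent radius `a = 1`: comfort zone `d_cz = 2.5a`
#' (agents keep clear of the far-field validity limit `2a`), leader target
#' zone `d_t = 6a` (large enough to hold the optimal formation of a small
#' group), force bound `F_max = 2` (four times the solo Stokes drag at the
#' default leader speed 0.5).
#'
#' @param N total group size including the leader.
#' @param ... overrides passed to [env_config()].
#' @return an [env_config()].
#' @export
locomotion_config <- function(N = 3L, ...) {
  defaults <- list(N = as.integer(N), d_t = 6, d_cz = 2.5, F_max = 2,
                   v0 = 0.2, dt = 0.1, T_steps = 300L, init_radius = 5)
  args <- utils::modifyList(defaults, list(...))
  do.call(env_config, args)
}

# initial follower placement: random in a disk around the leader with
# pairwise separations of at least 2a (rejection sampling)
init_locomotion_positions <- function(N, radius, min_sep) {
  pos <- matrix(0, N, 2) # leader at origin
  for (i in 2:N) {
    for (try in 1:200) {
      th <- stats::runif(1, 0, 2 * pi)
      rr <- radius * sqrt(stats::runif(1))
      cand <- c(rr * cos(th), rr * sin(th))
      d <- sqrt(rowSums((pos[seq_len(i - 1), , drop = FALSE] -
                           matrix(cand, i - 1, 2, byrow = TRUE))^2))
      if (all(d >= min_sep)) break
    }
    pos[i, ] <- cand
  }
  pos
}

# batched rollout; transition columns step-major, follower-major within
# episode: index (t-1)*Nf*n + (e-1)*Nf + (i-1), followers i = 2..N
locomotion_rollout <- function(cfg, p = hydro_params(),
                               k = reward_constants(), shared = TRUE,
                               record = FALSE) {
  N <- cfg$N
  Nf <- N - 1L
  stopifnot(N >= 2L)
  T_steps <- cfg$T_steps
  d_s <- obs_dim("locomotion", N)

  function(policies, n) {
    X <- array(0, c(N, 2, n)); V <- array(0, c(N, 2, n))
    Fc <- array(0, c(N, 2, n))
    for (e in seq_len(n)) {
      X[, , e] <- init_locomotion_positions(N, cfg$init_radius, 2 * p$a)
      V[1, , e] <- p$v_lead
    }
    d_nn_prev <- matrix(NA_real_, N, n)
    ncol_t <- Nf * n
    S_all <- matrix(0, d_s, T_steps * ncol_t)
    A_all <- matrix(0, 2, T_steps * ncol_t)
    R <- matrix(0, T_steps, ncol_t)
    if (record) {
      traj <- array(0, c(T_steps, N, 4L, n))
      powers <- array(0, c(T_steps, N, n))
    }

    for (t in seq_len(T_steps)) {
      S_t <- matrix(0, d_s, ncol_t)
      ind <- matrix(0, 3, ncol_t) # S_cz, S_ca, S_d per follower
      for (e in seq_len(n)) {
        P <- X[, , e]
        prev <- list(d_nn = d_nn_prev[, e])
        for (i in 2:N) {
          col <- (e - 1L) * Nf + (i - 1L)
          S_t[, col] <- encode_locomotion(i, P, V[, , e], Fc[, , e],
                                          prev, cfg)
          ind[, col] <- S_t[(d_s - 2L):d_s, col]
        }
        # refresh previous nearest-neighbour distances
        for (i in 2:N) {
          j <- nearest_neighbor(i, P, Inf)
          d_nn_prev[i, e] <- sqrt(sum((P[i, ] - P[j, ])^2))
        }
      }
      idx <- (t - 1L) * ncol_t + seq_len(ncol_t)
      S_all[, idx] <- S_t

      if (shared) {
        dist <- policy_forward(policies, S_t)
        smp <- policy_sample(dist, cfg$F_max)
      } else {
        smp <- list(raw = matrix(0, 2, ncol_t), action = matrix(0, 2, ncol_t))
        for (i in seq_len(Nf)) {
          ci <- i + (seq_len(n) - 1L) * Nf
          di <- policy_forward(policies[[i]], S_t[, ci, drop = FALSE])
          si <- policy_sample(di, cfg$F_max)
          smp$raw[, ci] <- si$raw; smp$action[, ci] <- si$action
        }
      }
      A_all[, idx] <- smp$raw

      for (e in seq_len(n)) {
        cols <- (e - 1L) * Nf + seq_len(Nf)
        Ff <- t(smp$action[, cols, drop = FALSE]) # Nf x 2
        st <- locomotion_env_step(X[, , e], Ff, p, cfg$dt)
        X[, , e] <- st$positions
        V[, , e] <- st$velocities
        Fc[2:N, , e] <- Ff
        for (i in seq_len(Nf)) {
          col <- cols[i]
          R[t, col] <- reward_locomotion(ind[1, col], ind[2, col],
                                         ind[3, col], Ff[i, ], k)
        }
        if (record) {
          traj[t, , , e] <- cbind(st$positions, st$velocities)
          powers[t, , e] <- st$powers
        }
      }
    }
    out <- list(S = S_all, A = A_all, R = R)
    if (record) out[c("traj", "powers")] <- list(traj, powers)
    out
  }
}

#' Train the locomotion task
#'
#' @param cfg a [locomotion_config()] (`N` counts the leader).
#' @param p a [hydro_params()].
#' @param k a [reward_constants()].
#' @param shared one shared policy for all followers (default) or a list of
#'   per-follower policies.
#' @param updates,n,lr,baseline,max_grad_norm training hyper-parameters;
#'   see [reinforce_train()].
#' @param optimizer `"sgd"` (default) or `"adam"`; see [make_optimizer()].
#' @param seed integer seed.
#' @param verbose print progress?
#' @return list with `policies`, `metrics`, `cfg`, `p`, `shared`.
#' @export
train_locomotion <- function(cfg = locomotion_config(), p = hydro_params(),
                             k = reward_constants(), shared = TRUE,
                             updates = 200L, n = 4L, lr = 1e-3,
                             baseline = TRUE, max_grad_norm = 10,
                             optimizer = "sgd", seed = 1L,
                             verbose = FALSE) {
  set.seed(as.integer(seed))
  N <- cfg$N; Nf <- N - 1L
  d_s <- obs_dim("locomotion", N)
  policies <- if (shared) policy_init(d_s) else
    replicate(Nf, policy_init(d_s), simplify = FALSE)
  roll <- locomotion_rollout(cfg, p, k, shared)
  step <- make_optimizer(optimizer, lr = lr, max_norm = max_grad_norm)
  ostate <- if (shared) NULL else vector("list", Nf)
  metrics <- data.frame(update = integer(0), mean_return = numeric(0))
  T_steps <- cfg$T_steps
  for (kk in seq_len(updates)) {
    batch <- roll(policies, n)
    if (shared) {
      W <- advantages(batch$R, cfg$gamma, baseline = baseline)
      g <- policy_grad(policies, batch$S, batch$A,
                       as.numeric(t(W)) / (Nf * n))
      stp <- step(policies, g, ostate)
      policies <- stp$params; ostate <- stp$state
    } else {
      for (i in seq_len(Nf)) {
        idx <- as.vector(outer((seq_len(T_steps) - 1L) * Nf * n,
                               (seq_len(n) - 1L) * Nf, "+") + i)
        Ri <- batch$R[, i + (seq_len(n) - 1L) * Nf, drop = FALSE]
        Wi <- advantages(Ri, cfg$gamma, baseline = baseline)
        gi <- policy_grad(policies[[i]], batch$S[, idx, drop = FALSE],
                          batch$A[, idx, drop = FALSE],
                          as.numeric(Wi) / n)
        stp <- step(policies[[i]], gi, ostate[[i]])
        policies[[i]] <- stp$params; ostate[i] <- list(stp$state)
      }
    }
    mret <- mean(apply(batch$R, 2, discounted_return, gamma = cfg$gamma))
    if (!is.finite(mret)) stop("mean return diverged", call. = FALSE)
    metrics[kk, ] <- list(kk, mret)
    if (verbose && kk %% 50L == 0L)
      message(sprintf("locomotion update %d: mean return %.4f", kk, mret))
  }
  list(policies = policies, metrics = metrics, cfg = cfg, p = p,
       shared = shared)
}

#' Roll out one recorded locomotion episode and summarise the formation
#'
#' The steady formation is the per-agent mean position relative to the
#' leader over the last quarter of the episode.
#'
#' @param policies policies as returned by [train_locomotion()].
#' @param cfg,p,k,shared as in [train_locomotion()].
#' @param seed episode seed.
#' @return list: `formation` (N x 2, leader at origin), `specific`
#'   (specific power of the time-averaged formation at the leader
#'   velocity), `traj`, `powers`, `rewards`.
#' @export
run_locomotion_episode <- function(policies, cfg, p = hydro_params(),
                                   k = reward_constants(), shared = TRUE,
                                   seed = 1L) {
  set.seed(as.integer(seed))
  roll <- locomotion_rollout(cfg, p, k, shared, record = TRUE)
  b <- roll(policies, 1L)
  T_steps <- cfg$T_steps
  win <- seq.int(floor(3 * T_steps / 4) + 1L, T_steps)
  lead_mean <- colMeans(matrix(b$traj[win, 1, 1:2, 1], length(win), 2))
  formation <- t(vapply(seq_len(cfg$N), function(i)
    colMeans(matrix(b$traj[win, i, 1:2, 1], length(win), 2)) - lead_mean,
    numeric(2)))
  list(formation = formation,
       specific = formation_specific_power(formation, p, p$v_lead),
       traj = b$traj[, , , 1], powers = b$powers[, , 1], rewards = b$R)
}
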