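# One-to-one escort: a follower holds a band of distances around an
# independently moving leader, under one of three information/control
# regimes (scenarios A, B, C). Episode batches are simulated with all n
# episodes advanced in lockstep (vectorised across episodes), which is
# exactly equivalent to running them one by one with per-episode RNG draws.

#' Rollout factory for the escort task
#'
#' Returns a `rollout(params, n)` function for [reinforce_train()]. Episodes
#' share the deterministic leader trajectory but draw random follower
#' initial conditions: position uniform in a disk of radius
#' `cfg$init_radius` around the leader start, speed uniform on
#' `[0, cfg$v0]` with uniform direction.
#'
#' @param path a [leader_path()].
#' @param cfg an [env_config()].
#' @param mode scenario `"A"`, `"B"` or `"C"`.
#' @param k a [reward_constants()].
#' @param record keep full trajectories (used by [run_escort_episode()])?
#' @return a rollout closure.
#' @export
escort_rollout <- function(path, cfg, mode = c("C", "A", "B"),
                           k = reward_constants(), record = FALSE) {
  mode <- match.arg(mode)
  T_steps <- cfg$T_steps
  dt <- cfg$dt
  tgrid <- (0:T_steps) * dt
  LP <- vapply(tgrid, function(t) leader_position(path, t), numeric(2))
  LV <- (LP[, -1, drop = FALSE] - LP[, -ncol(LP), drop = FALSE]) / dt
  bound <- switch(mode, A = cfg$v_max, B = cfg$v_max, C = cfg$F_max)

  function(params, n) {
    # follower initial conditions
    th <- stats::runif(n, 0, 2 * pi)
    rr <- cfg$init_radius * sqrt(stats::runif(n))
    X <- LP[, 1] + rbind(rr * cos(th), rr * sin(th))
    phv <- stats::runif(n, 0, 2 * pi)
    sp <- stats::runif(n, 0, cfg$v0)
    V <- rbind(sp * cos(phv), sp * sin(phv))
    Fc <- matrix(0, 2, n)
    d_prev <- rep(NA_real_, n)

    S_all <- matrix(0, 8L, T_steps * n)
    A_all <- matrix(0, 2L, T_steps * n)
    R <- matrix(0, T_steps, n)
    traj <- if (record) array(0, dim = c(T_steps, 6L, n)) else NULL

    for (t in seq_len(T_steps)) {
      dx <- LP[, t] - X
      d <- sqrt(colSums(dx^2))
      S_d <- band_indicator(d, cfg$d_t, cfg$e_t)
      S_a <- ifelse(is.na(d_prev), 0, as.numeric(d < d_prev))
      vl_hat <- unit_dir(LV[, t])
      spd <- sqrt(colSums(V^2))
      Vh <- V
      nz <- spd > 1e-12
      Vh[, nz] <- V[, nz, drop = FALSE] * rep(1 / spd[nz], each = 2)
      Vh[, !nz] <- 0
      S <- rbind(S_d, S_a, matrix(vl_hat, 2, n), Vh, Fc)
      idx <- (t - 1L) * n + seq_len(n)
      S_all[, idx] <- S

      dist <- policy_forward(params, S)
      smp <- policy_sample(dist, bound)
      A_all[, idx] <- smp$raw

      # vectorised step (matches step_agent on each column)
      act <- smp$action
      if (mode == "A") {
        V <- act
      } else if (mode == "B") {
        dv <- act - V
        ndv <- sqrt(colSums(dv^2))
        cap <- cfg$a_max * dt
        ov <- ndv > cap
        if (any(ov)) dv[, ov] <- dv[, ov, drop = FALSE] *
            rep(cap / ndv[ov], each = 2)
        V <- V + dv
      } else {
        V <- V + act * dt
        Fc <- act
      }
      X <- X + V * dt
      R[t, ] <- ifelse(S_d == 1, k$r_target,
                ifelse(S_a == 1, k$r_pursuit, k$r_recede))
      d_prev <- d
      if (record) traj[t, , ] <- rbind(X, V, matrix(LP[, t], 2, n))
    }
    out <- list(S = S_all, A = A_all, R = R)
    if (record) out$traj <- traj
    out
  }
}

#' Train an escort policy
#'
#' @param path a [leader_path()].
#' @param cfg an [env_config()].
#' @param mode scenario `"A"`, `"B"` or `"C"`.
#' @param updates,n,lr,baseline training hyper-parameters, see
#'   [reinforce_train()].
#' @param seed integer seed; fixes initialisation and all rollouts.
#' @param verbose print progress?
#' @return list with `params`, `metrics`, and the `cfg`/`mode` used.
#' @export
train_escort <- function(path, cfg, mode = c("C", "A", "B"), updates = 200L,
                         n = 16L, lr = 1e-3, baseline = TRUE, seed = 1L,
                         verbose = FALSE) {
  mode <- match.arg(mode)
  set.seed(as.integer(seed))
  params <- policy_init(obs_dim("escort"))
  roll <- escort_rollout(path, cfg, mode)
  fit <- reinforce_train(roll, params, updates = updates, n = n, lr = lr,
                         gamma = cfg$gamma, baseline = baseline,
                         verbose = verbose)
  c(fit, list(cfg = cfg, mode = mode, path = path))
}

#' Roll out one escort episode with full trajectories
#'
#' @param params trained (or fresh) policy parameters.
#' @param path,cfg,mode as in [train_escort()].
#' @param seed integer seed for the episode.
#' @return data.frame `(t, x, y, vx, vy, lx, ly, reward)` plus the mean
#'   undiscounted reward as attribute `"mean_reward"`.
#' @export
run_escort_episode <- function(params, path, cfg, mode = c("C", "A", "B"),
                               seed = 1L) {
  mode <- match.arg(mode)
  set.seed(as.integer(seed))
  roll <- escort_rollout(path, cfg, mode, record = TRUE)
  b <- roll(params, 1L)
  df <- data.frame(t = seq_len(cfg$T_steps) * cfg$dt,
                   x = b$traj[, 1, 1], y = b$traj[, 2, 1],
                   vx = b$traj[, 3, 1], vy = b$traj[, 4, 1],
                   lx = b$traj[, 5, 1], ly = b$traj[, 6, 1],
                   reward = b$R[, 1])
  attr(df, "mean_reward") <- mean(b$R[, 1])
  df
}
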