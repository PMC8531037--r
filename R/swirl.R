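# Multi-agent swarm: N force-controlled (scenario C) agents, each rewarded
# individually for escorting the group centre, with an optional external
# force field. Swirling is quantified by the mean angular velocity Omega.

#' Mean angular velocity of a swarm
#'
#' `Omega = (1/N) sum_i (v_i - v_gc) x (x_i - x_gc) / ||x_i - x_gc||^2`
#' with the 2D scalar cross product `a x b = a_x b_y - a_y b_x`. Zero for
#' rigid translation and Galilean-invariant; under this operand order a
#' counterclockwise rigid rotation at rate `w` gives `Omega = -w`, so the
#' magnitude `|Omega|` is the reported swirl strength. Agents closer than
#' `eps` to the centre are excluded from the average (with a warning).
#'
#' @param positions,velocities N x 2 matrices.
#' @param eps exclusion radius around the group centre.
#' @return signed scalar Omega.
#' @export
angular_velocity <- function(positions, velocities, eps = 1e-9) {
  stopifnot(is.matrix(positions), nrow(positions) >= 2L)
  x_gc <- colMeans(positions)
  v_gc <- colMeans(velocities)
  dx <- positions[, 1] - x_gc[1]
  dy <- positions[, 2] - x_gc[2]
  r2 <- dx^2 + dy^2
  keep <- r2 > eps^2
  if (!all(keep)) warning("agent(s) at the group centre excluded from Omega")
  if (!any(keep)) return(NA_real_)
  dvx <- velocities[, 1] - v_gc[1]
  dvy <- velocities[, 2] - v_gc[2]
  cross <- dvx * dy - dvy * dx
  mean(cross[keep] / r2[keep])
}

unit_rows <- function(M, eps = 1e-12) {
  n <- sqrt(rowSums(M^2))
  out <- M / pmax(n, eps)
  out[n <= eps, ] <- 0
  out
}

#' External force field with stretched-exponential magnitudes
#'
#' The force direction is drawn uniformly on the circle once per episode;
#' the magnitude is re-drawn from the stretched-exponential distribution
#' every `modulation_period` steps.
#'
#' @param f0 scale factor (> 0, or 0 for no force).
#' @param beta stretching exponent (> 0); `beta = 1` is the exponential
#'   distribution with mean `f0`.
#' @param modulation_period steps between magnitude re-draws.
#' @return an object of class `force_field`.
#' @export
force_field <- function(f0, beta = 1, modulation_period = 50L) {
  stopifnot(f0 >= 0, beta > 0, modulation_period >= 1L)
  ff <- list(f0 = f0, beta = beta,
             modulation_period = as.integer(modulation_period))
  class(ff) <- "force_field"
  ff
}

#' Sample stretched-exponential force magnitudes
#'
#' Exact sampler for the density
#' `P(f | f0, beta) = (1/f0) * beta / Gamma(1/beta) * exp(-(f/f0)^beta)`
#' on `[0, Inf)`, via the gamma transform `f = f0 * G^(1/beta)` with
#' `G ~ Gamma(shape = 1/beta, scale = 1)`.
#'
#' @param n number of draws.
#' @param f0 scale factor (> 0).
#' @param beta stretching exponent (> 0).
#' @return numeric vector of n non-negative magnitudes.
#' @export
sample_force_magnitude <- function(n, f0, beta = 1) {
  stopifnot(f0 > 0, beta > 0)
  f0 * stats::rgamma(n, shape = 1 / beta, scale = 1)^(1 / beta)
}

# ---- internal batched swarm simulator ----
# Advances n episodes of N agents in lockstep. Transition columns are
# ordered step-major: index (t-1)*N*n + (e-1)*N + i.
swarm_rollout <- function(cfg, k = reward_constants(), field = NULL,
                          shared = TRUE, record = FALSE) {
  N <- cfg$N
  T_steps <- cfg$T_steps
  dt <- cfg$dt
  stopifnot(N >= 2L)

  function(policies, n) {
    X <- array(0, c(N, 2, n)); V <- array(0, c(N, 2, n))
    Fc <- array(0, c(N, 2, n))
    for (e in seq_len(n)) {
      th <- stats::runif(N, 0, 2 * pi)
      rr <- cfg$init_radius * sqrt(stats::runif(N))
      X[, , e] <- cbind(rr * cos(th), rr * sin(th))
      phv <- stats::runif(N, 0, 2 * pi)
      sp <- stats::runif(N, 0, cfg$v0)
      V[, , e] <- cbind(sp * cos(phv), sp * sin(phv))
    }
    # external field: fixed direction per episode, modulated magnitude
    if (!is.null(field) && field$f0 > 0) {
      fth <- stats::runif(n, 0, 2 * pi)
      fdir <- rbind(cos(fth), sin(fth))
      fmag <- sample_force_magnitude(n, field$f0, field$beta)
    }
    d_nn_prev <- matrix(NA_real_, N, n)
    d_gc_prev <- matrix(NA_real_, N, n)

    ncol_t <- N * n
    S_all <- matrix(0, 12L, T_steps * ncol_t)
    A_all <- matrix(0, 2L, T_steps * ncol_t)
    R <- matrix(0, T_steps, ncol_t)
    if (record) {
      traj <- array(0, c(T_steps, N, 4L, n))
      omega <- matrix(NA_real_, T_steps, n)
      xgc_tr <- array(0, c(T_steps, 2L, n))
    }

    for (t in seq_len(T_steps)) {
      S_t <- matrix(0, 12L, ncol_t)
      for (e in seq_len(n)) {
        P <- X[, , e]; W <- V[, , e]
        dxm <- outer(P[, 1], P[, 1], "-")
        dym <- outer(P[, 2], P[, 2], "-")
        D <- sqrt(dxm^2 + dym^2)
        diag(D) <- Inf
        nn <- max.col(-D, ties.method = "first")
        d_nn <- D[cbind(seq_len(N), nn)]
        seen <- d_nn <= cfg$R_p
        if (is.finite(cfg$R_p)) {
          M <- D <= cfg$R_p
          diag(M) <- TRUE
          cnt <- rowSums(M)
          Xg <- (M %*% P) / cnt
          Vg <- (M %*% W) / cnt
        } else {
          Xg <- matrix(colMeans(P), N, 2, byrow = TRUE)
          Vg <- matrix(colMeans(W), N, 2, byrow = TRUE)
        }
        d_gc <- sqrt(rowSums((P - Xg)^2))
        S_cz <- as.numeric(seen & d_nn <= cfg$d_cz)
        S_ca <- ifelse(seen & !is.na(d_nn_prev[, e]),
                       as.numeric(d_nn < d_nn_prev[, e]), 0)
        S_gc <- as.numeric(d_gc <= cfg$d_t)
        S_ga <- ifelse(is.na(d_gc_prev[, e]), 0,
                       as.numeric(d_gc < d_gc_prev[, e]))
        v_c <- unit_rows(W[nn, , drop = FALSE])
        v_c[!seen, ] <- 0
        obs <- cbind(S_cz, S_ca, S_gc, S_ga, v_c, unit_rows(W),
                     Fc[, , e], unit_rows(Vg))
        cols <- (e - 1L) * N + seq_len(N)
        S_t[, cols] <- t(obs)
        base <- ifelse(S_gc == 1, k$r_target,
                ifelse(S_ga == 1, k$r_pursuit, k$r_recede))
        R[t, cols] <- base + ifelse(S_cz == 1, k$r_intrude, 0)
        d_nn_prev[, e] <- ifelse(seen, d_nn, NA_real_)
        d_gc_prev[, e] <- d_gc
        if (record) {
          omega[t, e] <- angular_velocity(P, W)
          xgc_tr[t, , e] <- colMeans(P)
          traj[t, , , e] <- cbind(P, W)
        }
      }
      idx <- (t - 1L) * ncol_t + seq_len(ncol_t)
      S_all[, idx] <- S_t

      if (shared) {
        dist <- policy_forward(policies, S_t)
        smp <- policy_sample(dist, cfg$F_max)
        A_t <- smp$raw; act <- smp$action
      } else {
        A_t <- matrix(0, 2, ncol_t); act <- matrix(0, 2, ncol_t)
        for (i in seq_len(N)) {
          ci <- i + (seq_len(n) - 1L) * N
          dist <- policy_forward(policies[[i]], S_t[, ci, drop = FALSE])
          smp <- policy_sample(dist, cfg$F_max)
          A_t[, ci] <- smp$raw; act[, ci] <- smp$action
        }
      }
      A_all[, idx] <- A_t

      # synchronous scenario-C step for every agent in every episode
      for (e in seq_len(n)) {
        cols <- (e - 1L) * N + seq_len(N)
        Fe <- t(act[, cols, drop = FALSE])        # N x 2 clipped forces
        Ftot <- Fe
        if (!is.null(field) && field$f0 > 0) {
          if (t %% field$modulation_period == 0L)
            fmag[e] <- sample_force_magnitude(1L, field$f0, field$beta)
          Ftot <- Fe + matrix(fmag[e] * fdir[, e], N, 2, byrow = TRUE)
        }
        V[, , e] <- V[, , e] + Ftot * dt
        X[, , e] <- X[, , e] + V[, , e] * dt
        Fc[, , e] <- Fe
      }
    }
    out <- list(S = S_all, A = A_all, R = R)
    if (record) {
      out[c("traj", "omega", "x_gc")] <- list(traj, omega, xgc_tr)
      if (!is.null(field) && field$f0 > 0) out$f_dir <- fdir
    }
    out
  }
}

#' Train a swarm of force-controlled agents
#'
#' N agents learn simultaneously; each receives only its own reward. With
#' `shared = TRUE` (default here) all agents follow one policy network
#' updated from every agent's transitions -- the "identical animals follow
#' the same action policy" reading; with `shared = FALSE` each agent owns an
#' independent network updated from its own transitions only.
#'
#' @param cfg an [env_config()] with `N >= 2`.
#' @param k a [reward_constants()].
#' @param field optional [force_field()] active during training (direction
#'   re-drawn each episode).
#' @param shared one shared policy (TRUE) or per-agent policies (FALSE).
#' @param updates,n,lr,baseline,max_grad_norm training hyper-parameters;
#'   see [reinforce_train()].
#' @param seed integer seed.
#' @param optimizer `"sgd"` (default) or `"adam"`; see [make_optimizer()].
#' @param sigma_lr_scale separate learning-rate multiplier for the
#'   sigma-head parameters (default 1). Values below 1 slow the annealing
#'   of the exploration noise, which guards against premature convergence
#'   onto a poor policy at short training budgets.
#' @param init_policies optional warm start: policies from a previous
#'   [train_swarm()] run (shapes must match `shared`).
#' @param verbose print progress every 50 updates?
#' @return list with `policies` (a `policy_params` or a list of N of them),
#'   `metrics` (update, mean_return, mean_sigma), `shared`, `cfg`.
#' @export
train_swarm <- function(cfg, k = reward_constants(), field = NULL,
                        shared = TRUE, updates = 200L, n = 4L, lr = 1e-3,
                        baseline = TRUE, max_grad_norm = 10,
                        optimizer = "sgd", sigma_lr_scale = 1, seed = 1L,
                        init_policies = NULL, verbose = FALSE) {
  stopifnot(cfg$N >= 2L)
  set.seed(as.integer(seed))
  d_s <- obs_dim("swarm")
  policies <- if (!is.null(init_policies)) init_policies else
    if (shared) policy_init(d_s) else
    replicate(cfg$N, policy_init(d_s), simplify = FALSE)
  roll <- swarm_rollout(cfg, k, field, shared)
  step <- make_optimizer(optimizer, lr = lr, max_norm = max_grad_norm)
  ostate <- if (shared) NULL else vector("list", cfg$N)
  N <- cfg$N
  T_steps <- cfg$T_steps
  metrics <- data.frame(update = integer(0), mean_return = numeric(0),
                        mean_sigma = numeric(0))
  for (kk in seq_len(updates)) {
    batch <- roll(policies, n)
    if (shared) {
      W <- advantages(batch$R, cfg$gamma, baseline = baseline)
      w <- as.numeric(t(W)) / (N * n)   # align with step-major columns
      g <- policy_grad(policies, batch$S, batch$A, w)
      g <- scale_sigma_head(g, sigma_lr_scale)
      stp <- step(policies, g, ostate)
      policies <- stp$params; ostate <- stp$state
      sig <- mean(policy_forward(policies,
                                 batch$S[, 1, drop = FALSE])$sigma)
    } else {
      for (i in seq_len(N)) {
        idx <- as.vector(outer((seq_len(T_steps) - 1L) * N * n,
                               (seq_len(n) - 1L) * N, "+") + i)
        Ri <- batch$R[, i + (seq_len(n) - 1L) * N, drop = FALSE]
        Wi <- advantages(Ri, cfg$gamma, baseline = baseline)
        # idx and as.numeric(Wi) are both ordered t-fastest within episode
        gi <- policy_grad(policies[[i]], batch$S[, idx, drop = FALSE],
                          batch$A[, idx, drop = FALSE],
                          as.numeric(Wi) / n)
        gi <- scale_sigma_head(gi, sigma_lr_scale)
        stp <- step(policies[[i]], gi, ostate[[i]])
        policies[[i]] <- stp$params; ostate[i] <- list(stp$state)
      }
      sig <- mean(policy_forward(policies[[1]],
                                 batch$S[, 1, drop = FALSE])$sigma)
    }
    mret <- mean(apply(batch$R, 2, discounted_return, gamma = cfg$gamma))
    if (!is.finite(mret)) stop("mean return diverged", call. = FALSE)
    metrics[kk, ] <- list(kk, mret, sig)
    if (verbose && kk %% 50L == 0L)
      message(sprintf("swarm update %d: mean return %.4f", kk, mret))
  }
  list(policies = policies, metrics = metrics, shared = shared, cfg = cfg)
}

#' Roll out one recorded swarm episode
#'
#' @param policies a shared `policy_params` or a list of N of them.
#' @param cfg an [env_config()].
#' @param k a [reward_constants()].
#' @param field optional [force_field()].
#' @param shared does `policies` hold one shared network?
#' @param seed integer episode seed.
#' @return list with `omega` (length-T signed Omega series), `x_gc`
#'   (T x 2 group-centre track), `traj` (T x N x 4 positions+velocities),
#'   `rewards` (T x N), and `extent` (T, root-mean-square agent distance
#'   from the centre).
#' @export
run_swarm_episode <- function(policies, cfg, k = reward_constants(),
                              field = NULL, shared = TRUE, seed = 1L) {
  set.seed(as.integer(seed))
  roll <- swarm_rollout(cfg, k, field, shared, record = TRUE)
  b <- roll(policies, 1L)
  extent <- apply(b$traj[, , 1:2, 1, drop = FALSE], 1, function(P) {
    P <- matrix(P, cfg$N, 2)
    sqrt(mean(rowSums((P - matrix(colMeans(P), cfg$N, 2, byrow = TRUE))^2)))
  })
  out <- list(omega = b$omega[, 1], x_gc = b$x_gc[, , 1],
              traj = b$traj[, , , 1], rewards = b$R, extent = extent)
  if (!is.null(b$f_dir)) out$f_dir <- b$f_dir[, 1]
  out
}
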