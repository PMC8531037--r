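# Low-Reynolds-number group locomotion. Spherical agents of radius `a` in a
# fluid of viscosity `eta` interact through the Rotne-Prager mobility
# tensor; motion is overdamped, so velocities are instantaneous linear
# responses to the applied forces:
#
#   v_i = -sum_j zeta_ij F^e_j ,   F^a = -F^e,
#   zeta_ij = (6 pi eta a)^-1 [ (3a/4x)(I + xx^T) + 1/2 (a/x)^3 (I - 3 xx^T) ],
#   zeta_ii = (6 pi eta a)^-1 I,
#
# and the total dissipated power is P = (6 pi eta a)^-1 sum_i ||F^a_i||^2.
# Agents move in the plane, so the in-plane 2x2 restriction of the tensors
# is used throughout.

#' Hydrodynamic parameters
#'
#' Defaults chosen so that `6 pi eta a = 1`: forces and velocities then
#' share one scale (Stokes drag coefficient 1).
#'
#' @param a agent radius (> 0).
#' @param eta_fluid fluid viscosity (> 0). Named to avoid any collision
#'   with the learning rate.
#' @param v_lead leader velocity (length-2), used by the locomotion task.
#' @return an object of class `hydro_params`.
#' @export
hydro_params <- function(a = 1, eta_fluid = 1 / (6 * pi), v_lead = c(0.5, 0)) {
  stopifnot(a > 0, eta_fluid > 0, length(v_lead) == 2L)
  p <- list(a = a, eta_fluid = eta_fluid, v_lead = as.numeric(v_lead),
            drag = 6 * pi * eta_fluid * a)
  class(p) <- "hydro_params"
  p
}

#' Rotne-Prager pair mobility block
#'
#' The in-plane 2x2 friction tensor between two agents separated by `x_ij`,
#' or the self block (`I / (6 pi eta a)`) when `x_ij` is `NULL`. The
#' far-field form is valid for separations of at least `2a`; smaller
#' separations trigger a warning (suppressable via `warn`).
#'
#' @param x_ij numeric length-2 separation vector, or `NULL` for the self
#'   block.
#' @param p a [hydro_params()].
#' @param warn warn when `||x_ij|| < 2a`?
#' @return a 2x2 matrix.
#' @export
pair_block <- function(x_ij, p, warn = TRUE) {
  pref <- 1 / p$drag
  if (is.null(x_ij)) return(pref * diag(2))
  x <- sqrt(sum(x_ij^2))
  if (x < 1e-12) stop("coincident agents: pair separation is zero", call. = FALSE)
  if (warn && x < 2 * p$a)
    warning(sprintf("pair separation %.3g below 2a = %.3g: Rotne-Prager far field invalid", x, 2 * p$a))
  xh <- x_ij / x
  Pm <- outer(xh, xh)
  pref * ((3 * p$a / (4 * x)) * (diag(2) + Pm) +
            0.5 * (p$a / x)^3 * (diag(2) - 3 * Pm))
}

#' Assembled 2N x 2N mobility matrix
#'
#' Block `(i, j)` is [pair_block()] of `x_i - x_j`; symmetric and positive
#' definite for all pairwise separations of at least `2a`.
#'
#' @param positions N x 2 matrix.
#' @param p a [hydro_params()].
#' @param warn warn on sub-`2a` separations?
#' @param clamp_min_sep if non-`NULL`, separations are clamped from below
#'   at this value inside the tensors (near-field regularisation used by
#'   the RL environment; the direction is preserved).
#' @return a `2N x 2N` matrix.
#' @export
mobility_matrix <- function(positions, p, warn = TRUE,
                            clamp_min_sep = NULL) {
  N <- nrow(positions)
  Z <- matrix(0, 2 * N, 2 * N)
  for (i in seq_len(N)) {
    ii <- (2 * i - 1):(2 * i)
    Z[ii, ii] <- pair_block(NULL, p)
    if (i < N) for (j in (i + 1):N) {
      xij <- positions[i, ] - positions[j, ]
      if (!is.null(clamp_min_sep)) {
        x <- sqrt(sum(xij^2))
        if (x < clamp_min_sep) xij <- xij * (clamp_min_sep / max(x, 1e-12))
      }
      B <- pair_block(xij, p, warn = warn)
      jj <- (2 * j - 1):(2 * j)
      Z[ii, jj] <- B
      Z[jj, ii] <- B # even in x_ij: symmetric under i <-> j
    }
  }
  Z
}

#' Power dissipated by a solely moving agent
#'
#' `P_1 = 6 pi eta a ||v||^2` (Stokes drag); the normalisation unit for all
#' specific dissipations.
#'
#' @param p a [hydro_params()].
#' @param v velocity (length-2).
#' @return scalar power.
#' @export
solo_power <- function(p, v) p$drag * sum(v^2)

#' Forces and power for a rigidly translating swarm
#'
#' Solves the linear system of the mobility relation for the environment
#' forces that make every agent move at the common velocity `v`, and
#' evaluates the dissipated power.
#'
#' @param positions N x 2 matrix (pairwise separations should be >= 2a).
#' @param v common velocity (length-2).
#' @param p a [hydro_params()].
#' @param warn warn on sub-`2a` separations?
#' @return list: `forces` (N x 2 matrix of agent forces `F^a`), `power`
#'   (total P), `specific` (P / (N * P_1), dimensionless).
#' @export
solve_common_velocity <- function(positions, v, p, warn = TRUE) {
  N <- nrow(positions)
  Z <- mobility_matrix(positions, p, warn = warn)
  vrep <- rep(as.numeric(v), N)
  Fe <- tryCatch(solve(Z, -vrep),
                 error = function(e) stop("singular mobility matrix (overlapping agents?)", call. = FALSE))
  Fa <- -Fe
  P <- sum(Fa^2) / p$drag
  list(forces = matrix(Fa, N, 2, byrow = TRUE), power = P,
       specific = P / (N * solo_power(p, v)))
}

# objective for the configuration optimiser: specific power + smooth
# quadratic penalty for separations below min_sep
config_objective <- function(theta, N, p, v, min_sep, kpen) {
  pos <- rbind(c(0, 0), matrix(theta, N - 1, 2, byrow = TRUE))
  pen <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) {
    d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    if (d < 1e-6) return(1e8)
    if (d < min_sep) pen <- pen + (min_sep - d)^2
  }
  sol <- suppressWarnings(solve_common_velocity(pos, v, p, warn = FALSE))
  sol$specific + kpen * pen
}

#' Dissipation-minimal swarm configurations by direct optimisation
#'
#' Multi-start local minimisation of the specific dissipated power over the
#' agent positions (one agent pinned at the origin to remove translational
#' degeneracy), with a quadratic penalty keeping pairwise separations at or
#' above `min_sep`. All minima whose specific power lies within `tol` of
#' the best are clustered modulo translation and agent relabelling; mirror
#' realisations about the motion axis are deliberately counted as distinct.
#'
#' @param N number of agents (>= 2).
#' @param p a [hydro_params()].
#' @param v common swarm velocity (default unit x).
#' @param min_sep minimum allowed separation (default `2a`).
#' @param restarts number of random starts (default 64).
#' @param tol relative specific-power tolerance for "global" clustering.
#' @param seed integer RNG seed for the starts.
#' @return list: `best` (N x 2 centred configuration), `specific` (best
#'   P / (N P_1)), `minima` (list of distinct global configurations),
#'   `n_global` (their count), `all_specific` (per-restart values).
#' @export
optimize_configuration <- function(N, p = hydro_params(), v = c(1, 0),
                                   min_sep = 2 * p$a, restarts = 64L,
                                   tol = 1e-4, seed = 1L) {
  stopifnot(N >= 2L)
  if (N == 1L) stop("N must be >= 2")
  set.seed(as.integer(seed))
  span <- min_sep * (1 + N / 2)
  sols <- vector("list", restarts)
  vals <- rep(NA_real_, restarts)
  obj <- function(kpen) function(theta)
    config_objective(theta, N, p, v, min_sep, kpen)
  for (r in seq_len(restarts)) {
    th0 <- stats::runif(2 * (N - 1), -span, span)
    fit <- stats::optim(th0, obj(1e3), method = "BFGS",
                        control = list(maxit = 500))
    fit <- stats::optim(fit$par, obj(1e5), method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-14))
    # derivative-free polish: robust to the finite-difference noise of the
    # stiff penalty
    fit <- stats::optim(fit$par, obj(1e7), method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
    pos <- rbind(c(0, 0), matrix(fit$par, N - 1, 2, byrow = TRUE))
    pos <- pos - matrix(colMeans(pos), N, 2, byrow = TRUE)
    sols[[r]] <- pos
    vals[r] <- suppressWarnings(
      solve_common_velocity(pos, v, p, warn = FALSE))$specific
  }
  best <- which.min(vals)
  near <- which(vals <= vals[best] * (1 + tol))
  canon <- function(pos) pos[order(pos[, 1], pos[, 2]), , drop = FALSE]
  reps <- list(); keep <- integer(0)
  for (i in near) {
    ci <- canon(sols[[i]])
    dup <- any(vapply(reps, function(rp)
      max(abs(rp - ci)) < 0.05 * min_sep, logical(1)))
    if (!dup) {
      reps[[length(reps) + 1L]] <- ci
      keep <- c(keep, i)
    }
  }
  list(best = sols[[best]], specific = vals[best], minima = sols[keep],
       n_global = length(keep), all_specific = vals)
}

#' One overdamped step of the locomotion environment
#'
#' The leader (row 1) moves at exactly `p$v_lead`: its force is solved
#' jointly with the follower velocities from the mobility relation, given
#' the followers' action forces. Velocities are instantaneous; positions
#' advance by one Euler step.
#'
#' @param positions N x 2 matrix, leader in row 1.
#' @param forces (N-1) x 2 matrix of follower action forces `F^a`.
#' @param p a [hydro_params()].
#' @param dt time step.
#' @param clamp_min_sep near-field clamp passed to [mobility_matrix()]
#'   (default `2a`; set `NULL` for the bare far-field tensors).
#' @return list: `positions` (advanced), `velocities` (N x 2), `powers`
#'   (length-N per-agent dissipation `||F^a_i||^2 / (6 pi eta a)`),
#'   `leader_force` (length-2).
#' @export
locomotion_env_step <- function(positions, forces, p, dt,
                                clamp_min_sep = 2 * p$a) {
  N <- nrow(positions)
  stopifnot(nrow(forces) == N - 1L)
  Z <- mobility_matrix(positions, p, warn = FALSE,
                       clamp_min_sep = clamp_min_sep)
  Fa <- rbind(c(0, 0), forces)
  # leader force from v_lead = sum_j Z_1j Fa_j  (v = Z Fa since Fe = -Fa)
  Z11 <- Z[1:2, 1:2]
  rest <- if (N > 1L) Z[1:2, -(1:2), drop = FALSE] %*% as.numeric(t(forces)) else c(0, 0)
  F1 <- solve(Z11, p$v_lead - as.numeric(rest))
  Fa[1, ] <- F1
  vvec <- Z %*% as.numeric(t(Fa))
  Vel <- matrix(vvec, N, 2, byrow = TRUE)
  list(positions = positions + Vel * dt, velocities = Vel,
       powers = rowSums(Fa^2) / p$drag, leader_force = F1)
}

#' Specific dissipation of a formation
#'
#' Convenience wrapper: `P / (N P_1)` for a rigidly translating formation.
#'
#' @param positions N x 2 matrix.
#' @param p a [hydro_params()].
#' @param v common velocity.
#' @return scalar specific power (1 for a single far-field agent).
#' @export
formation_specific_power <- function(positions, p = hydro_params(),
                                     v = c(1, 0)) {
  suppressWarnings(solve_common_velocity(positions, v, p, warn = FALSE))$specific
}
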