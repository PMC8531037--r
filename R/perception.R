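# Limited-perception observation encodings.
#
# Agents never see coordinates or distances as numbers: space is perceived
# only through binary in/out indicators (Heaviside functions of distances)
# plus unit direction vectors and the agent's own last action force.
# Convention used throughout: H(0) = 1, i.e. a band/zone boundary counts as
# inside.

heaviside <- function(x) as.numeric(x >= 0)

#' Distance-band indicator S_d
#'
#' `H(e_t - |d_t - distance|)`: 1 when `distance` lies within `e_t` of the
#' target distance `d_t` (boundary inclusive), else 0. This is the follower's
#' only knowledge of its range to the leader.
#'
#' @param distance non-negative distance.
#' @param d_t target distance.
#' @param e_t half-width of the acceptable band (> 0).
#' @return 0 or 1.
#' @export
band_indicator <- function(distance, d_t, e_t) {
  stopifnot(e_t > 0, all(distance >= 0))
  heaviside(e_t - abs(d_t - distance))
}

#' Radius indicator
#'
#' `H(d_t - distance)`: 1 inside (or on) the radius, 0 outside. Used for the
#' swarm group-centre zone (S_gc), the pairwise comfort zone (S_cz with
#' `d_cz`) and the locomotion leader zone (S_d).
#'
#' @param distance non-negative distance.
#' @param d_t zone radius.
#' @return 0 or 1.
#' @export
radius_indicator <- function(distance, d_t) {
  stopifnot(all(distance >= 0))
  heaviside(d_t - distance)
}

#' Approach indicator
#'
#' Discretised `H(-d/dt ||.||)`: 1 iff the distance strictly decreased over
#' the last time step. At the first step of an episode (no previous distance)
#' it is defined as 0; an unchanged distance also gives 0.
#'
#' @param dist_now,dist_prev non-negative distances; `dist_prev` may be `NA`
#'   at the first step.
#' @return 0 or 1.
#' @export
approach_indicator <- function(dist_now, dist_prev) {
  if (is.null(dist_prev) || any(is.na(dist_prev))) return(0)
  as.numeric(dist_now < dist_prev)
}

#' Unit direction of a 2D vector
#'
#' `v / ||v||`, with the zero vector mapped to the `(0, 0)` sentinel (an
#' agent at rest has no direction of motion; the sentinel keeps the encoding
#' deterministic).
#'
#' @param v numeric length-2 vector.
#' @param eps norm threshold below which the direction is undefined.
#' @return numeric length-2 unit vector or `c(0, 0)`.
#' @export
unit_dir <- function(v, eps = 1e-12) {
  n <- vnorm(v)
  if (n > eps) v / n else c(0, 0)
}

#' Index of the nearest perceived neighbour
#'
#' `argmin_{j != i} ||x_i - x_j||` restricted to agents within the perception
#' radius `R_p`. Ties are broken toward the lowest index; `NA` if no other
#' agent is perceivable.
#'
#' @param i agent index (1-based).
#' @param positions N x 2 matrix of agent positions.
#' @param R_p perception radius (`Inf` for unlimited).
#' @return integer index or `NA_integer_`.
#' @export
nearest_neighbor <- function(i, positions, R_p = Inf) {
  stopifnot(is.matrix(positions), ncol(positions) == 2L)
  N <- nrow(positions)
  if (N < 2L) stop("nearest_neighbor requires at least 2 agents", call. = FALSE)
  d <- sqrt(colSums((t(positions) - positions[i, ])^2))
  d[i] <- Inf
  j <- which.min(d) # which.min returns the first (lowest-index) minimiser
  if (d[j] > R_p) NA_integer_ else as.integer(j)
}

#' Perceived group centre and mean velocity
#'
#' Arithmetic means of the supplied positions and velocities. Under a finite
#' perception radius the caller supplies the perceived subset: the perceiving
#' agent itself plus all agents within `R_p` of it, so with `R_p = Inf` this
#' is the true swarm centre of mass.
#'
#' @param positions,velocities m x 2 matrices (m >= 1).
#' @return list with `x_gc` and `v_gc`, each length-2.
#' @export
group_stats <- function(positions, velocities) {
  stopifnot(is.matrix(positions), nrow(positions) >= 1L)
  list(x_gc = colMeans(positions), v_gc = colMeans(velocities))
}

perceived_idx <- function(i, positions, R_p) {
  if (!is.finite(R_p)) return(seq_len(nrow(positions)))
  d <- sqrt(colSums((t(positions) - positions[i, ])^2))
  which(d <= R_p) # always includes i (d[i] = 0)
}

#' Encode the escort observation (8 components)
#'
#' Layout: `(S_d, S_a, v_hat_l, v_hat_f, F_f)` -- the distance-band
#' indicator, the approach indicator, the leader and follower velocity
#' directions and the follower's last action force.
#'
#' @param leader_pos,leader_vel leader position and velocity.
#' @param kin follower [agent_kin()].
#' @param dist_prev leader-follower distance at the previous step (`NA` at
#'   episode start).
#' @param cfg an [env_config()].
#' @return numeric length-8 observation.
#' @export
encode_escort <- function(leader_pos, leader_vel, kin, dist_prev, cfg) {
  d <- vnorm(leader_pos - kin$position)
  c(band_indicator(d, cfg$d_t, cfg$e_t),
    approach_indicator(d, dist_prev),
    unit_dir(leader_vel),
    unit_dir(kin$velocity),
    kin$last_force)
}

#' Encode the swarm observation (12 components)
#'
#' Layout: `(S_cz, S_ca, S_gc, S_ga, v_hat_c, v_hat_i, F_i, v_hat_gc)` --
#' comfort-zone and neighbour-approach indicators, group-centre zone and
#' group-approach indicators, then the unit velocity of the nearest
#' neighbour, of the agent itself, the agent's last force, and the unit mean
#' velocity of the perceived group. With no perceivable neighbour, S_cz and
#' S_ca are 0 and the neighbour direction is the zero sentinel.
#'
#' @param i agent index.
#' @param positions,velocities N x 2 state matrices.
#' @param last_forces N x 2 matrix of last action forces.
#' @param prev list with `d_nn` and `d_gc`: previous-step nearest-neighbour
#'   and group-centre distances per agent (`NA` at episode start).
#' @param cfg an [env_config()].
#' @return numeric length-12 observation.
#' @export
encode_swarm <- function(i, positions, velocities, last_forces, prev, cfg) {
  idx <- perceived_idx(i, positions, cfg$R_p)
  gs <- group_stats(positions[idx, , drop = FALSE],
                    velocities[idx, , drop = FALSE])
  d_gc <- vnorm(positions[i, ] - gs$x_gc)
  j <- nearest_neighbor(i, positions, cfg$R_p)
  if (is.na(j)) {
    s_cz <- 0; s_ca <- 0; v_c <- c(0, 0); d_nn <- NA_real_
  } else {
    d_nn <- vnorm(positions[i, ] - positions[j, ])
    s_cz <- radius_indicator(d_nn, cfg$d_cz)
    s_ca <- approach_indicator(d_nn, prev$d_nn[i])
    v_c <- unit_dir(velocities[j, ])
  }
  c(s_cz, s_ca,
    radius_indicator(d_gc, cfg$d_t),
    approach_indicator(d_gc, prev$d_gc[i]),
    v_c,
    unit_dir(velocities[i, ]),
    last_forces[i, ],
    unit_dir(gs$v_gc))
}

#' Encode the locomotion observation
#'
#' The locomotion task assumes rich perception. For a group of one leader
#' (index 1) and `N - 1` followers, follower `i` observes, in fixed agent
#' order: its position relative to the leader and to every other follower
#' (2(N-1) numbers), its own lab-frame velocity (2), its velocity relative to
#' the leader and to every other follower (2(N-1)), its last action force
#' (2), and the indicators `(S_cz, S_ca, S_d)`. Total length `4(N-1) + 7`.
#'
#' @param i follower index (2..N in the full group including the leader).
#' @param positions,velocities N x 2 matrices, leader in row 1.
#' @param last_forces N x 2 matrix (row 1 unused).
#' @param prev list with per-agent previous nearest-neighbour distance
#'   `d_nn` (`NA` at episode start).
#' @param cfg an [env_config()]; `d_t` is the leader-zone radius.
#' @return numeric observation of length `4 * (N - 1) + 7`.
#' @export
encode_locomotion <- function(i, positions, velocities, last_forces, prev, cfg) {
  N <- nrow(positions)
  stopifnot(i >= 2L, i <= N)
  others <- setdiff(seq_len(N), i) # leader first, then followers in order
  rel_pos <- as.vector(t(positions[others, , drop = FALSE] -
                           matrix(positions[i, ], length(others), 2, byrow = TRUE)))
  rel_vel <- as.vector(t(velocities[others, , drop = FALSE] -
                           matrix(velocities[i, ], length(others), 2, byrow = TRUE)))
  j <- nearest_neighbor(i, positions, Inf)
  d_nn <- vnorm(positions[i, ] - positions[j, ])
  d_l <- vnorm(positions[i, ] - positions[1, ])
  c(rel_pos,
    velocities[i, ],
    rel_vel,
    last_forces[i, ],
    radius_indicator(d_nn, cfg$d_cz),
    approach_indicator(d_nn, prev$d_nn[i]),
    radius_indicator(d_l, cfg$d_t))
}

#' Observation dimensions
#'
#' @param task `"escort"`, `"swarm"` or `"locomotion"`.
#' @param N group size (locomotion only).
#' @return integer observation length.
#' @export
obs_dim <- function(task = c("escort", "swarm", "locomotion"), N = NULL) {
  task <- match.arg(task)
  switch(task,
    escort = 8L,
    swarm = 12L,
    locomotion = {
      stopifnot(!is.null(N), N >= 2L)
      as.integer(4L * (N - 1L) + 7L)
    })
}
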