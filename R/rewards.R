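# Immediate rewards. The printed rules fix only the structure and the
# ordering r_target > r_pursuit > 0 > r_recede, r_intrude < 0; the default
# magnitudes below are package choices and are fully configurable.

#' Reward constants
#'
#' @param r_target reward for residing in the target zone/band (> 0).
#' @param r_pursuit reward for approaching the target when outside (> 0,
#'   smaller than `r_target`).
#' @param r_recede penalty for receding while outside (< 0).
#' @param r_intrude additive penalty when the nearest neighbour intrudes the
#'   comfort zone (< 0).
#' @param c_energy energy-penalty coefficient per squared force (>= 0),
#'   locomotion only.
#' @return an object of class `reward_constants`.
#' @export
reward_constants <- function(r_target = 1.0, r_pursuit = 0.1,
                             r_recede = -0.1, r_intrude = -0.5,
                             c_energy = 0.1) {
  stopifnot(r_target > r_pursuit, r_pursuit > 0, r_recede < 0,
            r_intrude < 0, c_energy >= 0)
  k <- list(r_target = r_target, r_pursuit = r_pursuit, r_recede = r_recede,
            r_intrude = r_intrude, c_energy = c_energy)
  class(k) <- "reward_constants"
  k
}

#' Escort reward
#'
#' Pure function of the two indicators: in the band -> `r_target`;
#' otherwise approaching -> `r_pursuit`; otherwise -> `r_recede`.
#'
#' @param S_d,S_a binary indicators (band membership, approach).
#' @param k a [reward_constants()].
#' @return scalar reward.
#' @export
reward_escort <- function(S_d, S_a, k = reward_constants()) {
  if (S_d == 1) k$r_target else if (S_a == 1) k$r_pursuit else k$r_recede
}

#' Swarm reward
#'
#' Base term as in the escort reward but with the group-centre indicators
#' (`S_gc` in the role of the band, `S_ga` as approach); additively,
#' a comfort-zone intrusion (`S_cz = 1`) contributes `r_intrude`.
#'
#' @param S_cz,S_ga,S_gc binary indicators (intrusion, group approach,
#'   group-centre zone).
#' @param k a [reward_constants()].
#' @return scalar reward.
#' @export
reward_swarm <- function(S_cz, S_ga, S_gc, k = reward_constants()) {
  base <- if (S_gc == 1) k$r_target else if (S_ga == 1) k$r_pursuit else k$r_recede
  base + if (S_cz == 1) k$r_intrude else 0
}

#' Locomotion reward
#'
#' As the swarm reward with the leader-zone indicator `S_d` in the role of
#' `S_gc`, and `S_ca` (approach of the nearest neighbour... here the
#' approach-to-leader role) as the pursuit indicator. When the agent is
#' settled (`S_d = 1` and no intrusion) it additionally pays
#' `c_energy * ||F||^2` for its own effort -- this is the term that drives
#' the group toward the dissipation-minimal formation.
#'
#' @param S_cz,S_ca,S_d binary indicators.
#' @param force numeric length-2 last action force.
#' @param k a [reward_constants()].
#' @return scalar reward.
#' @export
reward_locomotion <- function(S_cz, S_ca, S_d, force, k = reward_constants()) {
  base <- if (S_d == 1) k$r_target else if (S_ca == 1) k$r_pursuit else k$r_recede
  pen <- if (S_cz == 1) k$r_intrude else 0
  energy <- if (S_d == 1 && S_cz == 0) -k$c_energy * sum(force^2) else 0
  base + pen + energy
}
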