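# ---- small 2D vector helpers (agents live in the plane) ----

vec2 <- function(x, y) c(x = as.numeric(x), y = as.numeric(y))

vnorm <- function(v) sqrt(sum(v * v))

stopifnot_finite <- function(x, what = "value") {
  if (!all(is.finite(x))) stop(sprintf("non-finite %s encountered", what), call. = FALSE)
}

#' Clip a 2D action vector to a norm bound
#'
#' Forces (or requested velocities) are physically limited: any action whose
#' Euclidean norm exceeds `bound` is rescaled onto the bounding circle,
#' preserving its direction.
#'
#' @param a numeric length-2 action vector.
#' @param bound positive scalar norm bound.
#' @return numeric length-2 vector with norm at most `bound`.
#' @export
#' @examples
#' clip_action(c(6, 8), 5) # c(3, 4)
clip_action <- function(a, bound) {
  stopifnot(length(a) == 2L, is.finite(bound), bound > 0)
  stopifnot_finite(a, "action")
  n <- vnorm(a)
  if (n <= bound) a else a * (bound / n)
}

#' Environment configuration
#'
#' Collects the kinematic and perceptual parameters shared by the escort and
#' swarm tasks. All lengths are in the same (dimensionless) unit; agents have
#' unit mass so force and acceleration coincide.
#'
#' @param dt integration time step (default 0.1).
#' @param T_steps episode length in steps (default 500).
#' @param F_max force/acceleration bound for force-controlled motion.
#' @param v_max speed bound (escort scenarios A and B).
#' @param a_max acceleration bound (escort scenario B).
#' @param gamma reward discount factor in (0,1); default 0.9.
#' @param d_t target distance (band centre for escort; radius for the swarm
#'   group-centre zone and the locomotion leader zone).
#' @param e_t half-width of the acceptable escort distance band (> 0).
#' @param d_cz comfort-zone radius around each agent.
#' @param R_p perception radius; `Inf` means every agent perceives all others.
#' @param N number of agents.
#' @param v0 upper bound of the uniform initial speed distribution.
#' @param init_radius agents start uniformly in a disk of this radius
#'   (default `2 * d_t`).
#' @param seed integer RNG seed.
#' @return an object of class `env_config` (a validated list).
#' @export
env_config <- function(dt = 0.1, T_steps = 500L, F_max = 1, v_max = 1,
                       a_max = 1, gamma = 0.9, d_t = 1, e_t = 0.2,
                       d_cz = 0.15, R_p = Inf, N = 20L, v0 = 0.5,
                       init_radius = NULL, seed = 1L) {
  cfg <- list(dt = dt, T_steps = as.integer(T_steps), F_max = F_max,
              v_max = v_max, a_max = a_max, gamma = gamma, d_t = d_t,
              e_t = e_t, d_cz = d_cz, R_p = R_p, N = as.integer(N),
              v0 = v0,
              init_radius = if (is.null(init_radius) || is.na(init_radius))
                2 * d_t else init_radius,
              seed = as.integer(seed))
  validate_env_config(cfg)
  class(cfg) <- "env_config"
  cfg
}

validate_env_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid config field '%s': %s", field, msg), call. = FALSE)
  }
  chk(cfg$dt > 0, "dt", "must be > 0")
  chk(cfg$T_steps >= 1L, "T_steps", "must be >= 1")
  chk(cfg$gamma > 0 && cfg$gamma < 1, "gamma", "must lie in (0,1)")
  chk(cfg$e_t > 0, "e_t", "must be > 0")
  chk(cfg$d_cz > 0, "d_cz", "must be > 0")
  chk(cfg$F_max > 0, "F_max", "must be > 0")
  chk(cfg$v_max > 0, "v_max", "must be > 0")
  chk(cfg$a_max > 0, "a_max", "must be > 0")
  chk(cfg$d_t > 0, "d_t", "must be > 0")
  chk(cfg$R_p > 0, "R_p", "must be > 0 (Inf allowed)")
  chk(cfg$N >= 1L, "N", "must be >= 1")
  chk(cfg$v0 >= 0, "v0", "must be >= 0")
  invisible(cfg)
}

#' Agent kinematic state
#'
#' Position, velocity and the most recently applied action force of one agent.
#' `last_force` is part of the observable state in force-controlled motion and
#' is zero at the start of an episode.
#'
#' @param position,velocity,last_force numeric length-2 vectors.
#' @return an object of class `agent_kin`.
#' @export
agent_kin <- function(position = c(0, 0), velocity = c(0, 0),
                      last_force = c(0, 0)) {
  k <- list(position = as.numeric(position), velocity = as.numeric(velocity),
            last_force = as.numeric(last_force))
  stopifnot(lengths(k) == 2L)
  class(k) <- "agent_kin"
  k
}

#' Leader trajectory
#'
#' The leader moves independently of the follower at constant speed along one
#' of five parametric curves. The triangle is piecewise-linear, hence its
#' velocity direction is discontinuous at the vertices -- deliberately
#' non-smooth.
#'
#' @param kind one of `"circle"`, `"ellipse"`, `"eight"`, `"spiral"`,
#'   `"triangle"`.
#' @param R radius (circle/eight lobe) or semi-major axis scale.
#' @param b semi-minor axis (ellipse only).
#' @param speed arc-length speed of the leader.
#' @param pitch radial growth per revolution (spiral only).
#' @param vertices 3x2 matrix of triangle vertices (triangle only).
#' @return an object of class `leader_path`.
#' @export
leader_path <- function(kind = c("circle", "ellipse", "eight", "spiral",
                                 "triangle"),
                        R = 2, b = 1, speed = 0.5, pitch = 0.2,
                        vertices = rbind(c(2, 0), c(-1, 1.5), c(-1, -1.5))) {
  kind <- match.arg(kind)
  p <- list(kind = kind, R = R, b = b, speed = speed, pitch = pitch,
            vertices = vertices)
  class(p) <- "leader_path"
  p
}

#' Position of the leader at time t
#'
#' Constant-speed parametrisation of the declared curve. Phase convention:
#' the circle starts at `(R, 0)` and runs counterclockwise. For the
#' non-circular curves the parameter is advanced at a rate that keeps the
#' arc-length speed approximately constant (exactly constant for circle and
#' triangle).
#'
#' @param path a [leader_path()].
#' @param t time (scalar, >= 0).
#' @return numeric length-2 position.
#' @export
leader_position <- function(path, t) {
  stopifnot(inherits(path, "leader_path"), t >= 0)
  switch(path$kind,
    circle = {
      phi <- path$speed * t / path$R
      path$R * c(cos(phi), sin(phi))
    },
    ellipse = {
      # mean-radius parametrisation: parameter rate chosen so the average
      # speed over a period equals `speed`
      rm <- (path$R + path$b) / 2
      phi <- path$speed * t / rm
      c(path$R * cos(phi), path$b * sin(phi))
    },
    eight = {
      # Gerono lemniscate scaled to lobe radius R
      rm <- path$R
      phi <- path$speed * t / rm
      c(path$R * sin(phi), path$R * sin(phi) * cos(phi))
    },
    spiral = {
      # Archimedean spiral r = R + pitch * phi / (2 pi), constant-speed in phi
      # rate referenced to the starting radius
      phi <- path$speed * t / path$R
      r <- path$R + path$pitch * phi / (2 * pi)
      r * c(cos(phi), sin(phi))
    },
    triangle = triangle_position(path, t),
    stop(sprintf("unknown leader path kind '%s'", path$kind), call. = FALSE)
  )
}

triangle_position <- function(path, t) {
  V <- path$vertices
  stopifnot(is.matrix(V), nrow(V) == 3L, ncol(V) == 2L)
  edges <- rbind(V[2, ] - V[1, ], V[3, ] - V[2, ], V[1, ] - V[3, ])
  len <- sqrt(rowSums(edges^2))
  per <- sum(len)
  s <- (path$speed * t) %% per
  cum <- c(0, cumsum(len))
  e <- findInterval(s, cum, rightmost.closed = TRUE)
  e <- min(e, 3L)
  frac <- (s - cum[e]) / len[e]
  V[e, ] + frac * edges[e, ]
}

#' Advance one agent by one Euler step
#'
#' Three control regimes of the escort problem, shared with the swarm tasks:
#' \describe{
#'   \item{A}{the action is a requested velocity, clipped to `v_max`.}
#'   \item{B}{as A, but the velocity change per unit time is additionally
#'     capped at `a_max`.}
#'   \item{C}{the action is a force, clipped to `F_max`; with unit mass the
#'     velocity integrates the total (action + external) force. This is the
#'     regime used for swarm motion.}
#' }
#' Semi-implicit Euler: the velocity is updated first, then the position is
#' advanced with the new velocity.
#'
#' @param kin an [agent_kin()].
#' @param action numeric length-2 requested velocity (A/B) or force (C).
#' @param mode `"A"`, `"B"` or `"C"`.
#' @param cfg an [env_config()].
#' @param external_force numeric length-2 force added in mode C (default 0).
#' @return the updated [agent_kin()].
#' @export
step_agent <- function(kin, action, mode = c("C", "A", "B"), cfg,
                       external_force = c(0, 0)) {
  mode <- match.arg(mode)
  stopifnot_finite(action, "action")
  stopifnot_finite(external_force, "external force")
  dt <- cfg$dt
  if (mode == "A") {
    v <- clip_action(action, cfg$v_max)
    kin$velocity <- v
  } else if (mode == "B") {
    v_req <- clip_action(action, cfg$v_max)
    dv <- v_req - kin$velocity
    ndv <- vnorm(dv)
    cap <- cfg$a_max * dt
    if (ndv > cap) dv <- dv * (cap / ndv)
    kin$velocity <- kin$velocity + dv
  } else {
    f <- clip_action(action, cfg$F_max)
    kin$velocity <- kin$velocity + (f + external_force) * dt
    kin$last_force <- f
  }
  kin$position <- kin$position + kin$velocity * dt
  kin
}
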