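# Run configuration: a YAML file with blocks `env`, `reward`, `training`,
# `leader`, `field`, `hydro` plus a top-level `seed`. Unknown keys are
# rejected; all numeric ranges are validated before any run.

config_defaults <- function() {
  list(
    seed = 1L,
    env = list(dt = 0.1, T_steps = 500L, F_max = 1, v_max = 1, a_max = 1,
               gamma = 0.9, d_t = 1, e_t = 0.2, d_cz = 0.15, R_p = Inf,
               N = 20L, v0 = 0.5, init_radius = NA),
    reward = list(r_target = 1.0, r_pursuit = 0.1, r_recede = -0.1,
                  r_intrude = -0.5, c_energy = 0.1),
    training = list(n = 16L, lr = 1e-3, updates = 2000L, baseline = TRUE,
                    shared = TRUE),
    leader = list(kind = "circle", R = 2, b = 1, speed = 0.5, pitch = 0.2),
    field = list(f0 = 0, beta = 1, modulation_period = 50L),
    hydro = list(a = 1, eta_fluid = 1 / (6 * pi), v_lead = c(0.5, 0))
  )
}

merge_block <- function(defaults, user, block) {
  if (is.null(user)) return(defaults)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra) > 0L)
    stop(sprintf("unknown key(s) in '%s': %s", block,
                 paste(extra, collapse = ", ")), call. = FALSE)
  utils::modifyList(defaults, user)
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, fills in the documented defaults for every missing
#' key, rejects unknown keys, and validates all numeric ranges. A minimal
#' file containing only `seed: 7` is valid.
#'
#' @param path path to a YAML file, or a named list (already parsed).
#' @return an object of class `run_config`: validated nested list with a
#'   `hash` attribute identifying the configuration content.
#' @export
load_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(user)) user <- list()
  d <- config_defaults()
  extra <- setdiff(names(user), names(d))
  if (length(extra) > 0L)
    stop(sprintf("unknown top-level key(s): %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  cfg <- list(seed = if (!is.null(user$seed)) as.integer(user$seed) else d$seed)
  for (b in c("env", "reward", "training", "leader", "field", "hydro"))
    cfg[[b]] <- merge_block(d[[b]], user[[b]], b)
  # range validation through the constructors
  env <- do.call(env_config, c(cfg$env, list(seed = cfg$seed)))
  do.call(reward_constants, cfg$reward)
  if (cfg$training$lr <= 0) stop("invalid config field 'training$lr': must be > 0", call. = FALSE)
  if (cfg$training$n < 1) stop("invalid config field 'training$n': must be >= 1", call. = FALSE)
  if (cfg$field$f0 < 0) stop("invalid config field 'field$f0': must be >= 0", call. = FALSE)
  if (cfg$field$beta <= 0) stop("invalid config field 'field$beta': must be > 0", call. = FALSE)
  if (cfg$hydro$a <= 0) stop("invalid config field 'hydro$a': must be > 0", call. = FALSE)
  if (cfg$hydro$eta_fluid <= 0) stop("invalid config field 'hydro$eta_fluid': must be > 0", call. = FALSE)
  attr(cfg, "hash") <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname load_config
#' @param cfg a `run_config`.
#' @param path output file path.
#' @export
dump_config <- function(cfg, path) {
  x <- unclass(cfg)
  attr(x, "hash") <- NULL
  yaml::write_yaml(x, path, precision = 12L)
  invisible(path)
}

config_hash <- function(cfg) {
  x <- unclass(cfg)
  attr(x, "hash") <- NULL
  # dependency-free content hash: sum of char codes of the serialised text,
  # split over two moduli (collision-resistant enough for provenance tags)
  # round to 10 significant digits so the hash survives a YAML round trip
  x <- rapply(x, function(v) if (is.numeric(v)) signif(v, 10) else v,
              how = "replace")
  s <- paste(utils::capture.output(utils::str(x, digits.d = 12)), collapse = "\n")
  v <- utf8ToInt(s)
  sprintf("%08x%08x", sum(v * (seq_along(v) %% 251)) %% 2^31,
          sum(v * (seq_along(v) %% 509)) %% 2^31)
}

#' Helper objects from a run configuration
#'
#' @param cfg a `run_config` from [load_config()].
#' @return `cfg_env`: an [env_config()]; `cfg_rewards`: a
#'   [reward_constants()]; `cfg_leader`: a [leader_path()]; `cfg_field`: a
#'   [force_field()] or `NULL`; `cfg_hydro`: a [hydro_params()].
#' @export
cfg_env <- function(cfg) do.call(env_config, c(cfg$env, list(seed = cfg$seed)))

#' @rdname cfg_env
#' @export
cfg_rewards <- function(cfg) do.call(reward_constants, cfg$reward)

#' @rdname cfg_env
#' @export
cfg_leader <- function(cfg) do.call(leader_path, cfg$leader)

#' @rdname cfg_env
#' @export
cfg_field <- function(cfg)
  if (cfg$field$f0 > 0) do.call(force_field, cfg$field) else NULL

#' @rdname cfg_env
#' @export
cfg_hydro <- function(cfg) do.call(hydro_params, cfg$hydro)

#' Write run artifacts to a directory
#'
#' Emits whatever the run produced -- trajectory table, metrics table,
#' order-parameter / resistance tables, policy snapshots -- as RFC-4180 CSV
#' plus a JSON manifest recording the seed, configuration hash and package
#' version needed to reproduce the run.
#'
#' @param artifacts named list; data.frames are written as
#'   `<name>.csv`, `policy_params` objects via [policy_save()], everything
#'   else into the manifest.
#' @param out_dir output directory (created if missing).
#' @param cfg optional `run_config` for the manifest.
#' @return invisibly, the manifest path.
#' @export
write_outputs <- function(artifacts, out_dir, cfg = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "swirlkit",
                   version = as.character(utils::packageVersion("swirlkit")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(cfg)) {
    manifest$seed <- cfg$seed
    manifest$config_hash <- attr(cfg, "hash")
    dump_config(cfg, file.path(out_dir, "config.yaml"))
  }
  for (nm in names(artifacts)) {
    x <- artifacts[[nm]]
    if (is.data.frame(x)) {
      utils::write.csv(x, file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
      manifest$files <- c(manifest$files, paste0(nm, ".csv"))
    } else if (inherits(x, "policy_params")) {
      policy_save(x, file.path(out_dir, nm),
                  meta = list(seed = manifest$seed))
      manifest$files <- c(manifest$files, paste0(nm, ".csv"),
                          paste0(nm, ".json"))
    } else {
      manifest$extra[[nm]] <- x
    }
  }
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Trajectory data.frame from a recorded swarm episode
#'
#' Long format `(t, agent_id, x, y, vx, vy)` -- one row per agent per step.
#'
#' @param ep result of [run_swarm_episode()].
#' @param dt time step used.
#' @return data.frame with `T * N` rows.
#' @export
trajectory_table <- function(ep, dt) {
  T_steps <- dim(ep$traj)[1]
  N <- dim(ep$traj)[2]
  data.frame(
    t = rep(seq_len(T_steps) * dt, each = N),
    agent_id = rep(seq_len(N), T_steps),
    x = as.numeric(t(ep$traj[, , 1])),
    y = as.numeric(t(ep$traj[, , 2])),
    vx = as.numeric(t(ep$traj[, , 3])),
    vy = as.numeric(t(ep$traj[, , 4])))
}
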