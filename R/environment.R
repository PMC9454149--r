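#' @name environment
#' @title The episodic docking environment
#'
#' @description
#' A maze-like episodic simulator: the protein environment is fixed, the
#' ligand is a rigid body that translates by \code{step_translation}
#' Angstrom along one axis per step (and, for multi-atom ligands,
#' additionally rotates by \code{step_rotation} degrees about one axis
#' through its centroid). The immediate reward is
#' \deqn{R_t = e^{-RMSD(s_0, s_{t+1})/18} - e^{-RMSD(s_0, s_t)/18}}
#' doubled when negative, which pushes the agent toward the true pose
#' \eqn{s_0}. An episode ends when the step counter reaches \code{T_MAX}
#' or any ligand atom leaves the box.
NULL

#' Environment configuration
#'
#' @param T_MAX Maximum steps per episode.
#' @param step_translation Translation step in Angstrom.
#' @param step_rotation Rotation step in degrees (multi-atom ligands).
#' @param reward_scale Denominator of the exponential reward, Angstrom.
#' @param penalty_factor Multiplier applied to negative raw rewards.
#' @return An \code{env_config} object.
#' @export
env_config <- function(T_MAX = 600L, step_translation = 0.1,
                       step_rotation = 1, reward_scale = 18,
                       penalty_factor = 2) {
  stopifnot(T_MAX >= 1, step_translation > 0, step_rotation > 0,
            reward_scale > 0, penalty_factor > 0)
  structure(list(T_MAX = as.integer(T_MAX),
                 step_translation = step_translation,
                 step_rotation = step_rotation,
                 reward_scale = reward_scale,
                 penalty_factor = penalty_factor),
            class = "env_config")
}

#' The discrete action space
#'
#' Six unit translations (+x, -x, +y, -y, +z, -z); for multi-atom ligands
#' each step is a (translation, rotation) pair with six unit rotations
#' (+1 degree and -1 degree about each axis, through the ligand centroid).
#'
#' @param multi_atom TRUE for the joint translation+rotation space.
#' @return A list with \code{n_translations} (6), \code{n_rotations}
#'   (0 or 6) and \code{joint} flag.
#' @export
action_space <- function(multi_atom = FALSE) {
  list(n_translations = 6L,
       n_rotations = if (multi_atom) 6L else 0L,
       joint = multi_atom)
}

# action encoding: translations 1..6 = +x,-x,+y,-y,+z,-z;
# rotations 1..6 = +x,-x,+y,-y,+z,-z (sign = direction of rotation angle)
.action_axis <- c(1L, 1L, 2L, 2L, 3L, 3L)
.action_sign <- c(1, -1, 1, -1, 1, -1)

#' Apply a discrete action to a pose
#'
#' @param pose A \code{ligand_pose}.
#' @param action Integer in 1..6 (translation) for single-atom ligands, or
#'   a list/vector \code{c(trans, rot)} with both in 1..6 for multi-atom
#'   ligands.
#' @param config An \code{env_config}.
#' @return The transformed \code{ligand_pose} (rigid: interatomic
#'   distances preserved).
#' @export
apply_action <- function(pose, action, config = env_config()) {
  action <- unlist(action)
  tr <- as.integer(action[1])
  stopifnot(tr >= 1, tr <= 6)
  co <- unclass(pose)
  shift <- numeric(3)
  shift[.action_axis[tr]] <- .action_sign[tr] * config$step_translation
  co <- sweep(co, 2, shift, "+")
  if (length(action) >= 2 && !is.na(action[2]) && nrow(co) > 1) {
    rot <- as.integer(action[2])
    stopifnot(rot >= 1, rot <= 6)
    ang <- .action_sign[rot] * config$step_rotation * pi / 180
    R <- axis_rotation(.action_axis[rot], ang)
    ctr <- colMeans(co)
    co <- sweep(sweep(co, 2, ctr) %*% t(R), 2, ctr, "+")
  }
  pose_update(pose, co)
}

#' Immediate reward of a transition
#'
#' \code{exp(-RMSD(s0, s_next)/scale) - exp(-RMSD(s0, s_t)/scale)}; if the
#' raw value is negative it is multiplied by \code{penalty_factor} (2), a
#' penalty that forces the ligand to walk in a better direction.
#'
#' @param s_t,s_next,s_0 Poses with equal atom counts (current, successor,
#'   true).
#' @param config An \code{env_config}.
#' @return Scalar reward in \code{(-penalty_factor, 1)}.
#' @export
immediate_reward <- function(s_t, s_next, s_0, config = env_config()) {
  if (nrow(s_t) != nrow(s_0) || nrow(s_next) != nrow(s_0)) {
    stop("invalid comparison: atom counts differ")
  }
  sc <- config$reward_scale
  raw <- exp(-rmsd(s_0, s_next) / sc) - exp(-rmsd(s_0, s_t) / sc)
  if (raw < 0) raw * config$penalty_factor else raw
}

#' Initialize an episode
#'
#' @param box A \code{grid_box}.
#' @param start_pose Start \code{ligand_pose} (all atoms inside the box).
#' @param config An \code{env_config}.
#' @return An immutable environment state: list with the cached
#'   protein-channel grid, current pose, step counter and termination
#'   fields. Advance it with \code{\link{env_step}}.
#' @export
env_init <- function(box, start_pose, config = env_config()) {
  protein_grid <- render_grid(box, pose = NULL)
  structure(list(box = box, config = config,
                 protein_grid = protein_grid,
                 pose = start_pose, step = 0L,
                 done = FALSE, reason = "running",
                 multi_atom = nrow(start_pose) > 1),
            class = "docking_env")
}

#' Advance the environment one step
#'
#' Applies the action, computes the immediate reward against the true
#' pose, and flags termination: \code{out_of_box} when any ligand atom
#' leaves the box (the pose rolls back to the last in-box pose),
#' \code{max_steps} when the counter reaches \code{T_MAX}.
#'
#' @param env State from \code{\link{env_init}} / a previous step.
#' @param action Action as in \code{\link{apply_action}}.
#' @return List with \code{env} (new state), \code{reward}, \code{done},
#'   \code{reason} (\code{"running"}, \code{"out_of_box"} or
#'   \code{"max_steps"}).
#' @export
env_step <- function(env, action) {
  if (env$done) stop("step on finished episode")
  cfg <- env$config
  new_pose <- apply_action(env$pose, action, cfg)
  co <- unclass(new_pose)
  out <- any(co <= 0) || any(co >= env$box$spec$edge)
  reward <- immediate_reward(env$pose, new_pose, env$box$true_pose, cfg)
  env$step <- env$step + 1L
  if (out) {
    env$done <- TRUE; env$reason <- "out_of_box"
    # the last in-box pose remains the episode's final pose
  } else {
    env$pose <- new_pose
    if (env$step >= cfg$T_MAX) { env$done <- TRUE; env$reason <- "max_steps" }
  }
  list(env = env, reward = reward, done = env$done, reason = env$reason)
}

#' Render the current environment state
#'
#' @param env A \code{docking_env} state.
#' @return The \code{(nx,ny,nz,N)} density grid: cached protein channels
#'   plus freshly rendered ligand channels for the current pose.
#' @export
env_render <- function(env) {
  render_ligand(env$protein_grid, env$box, env$pose)
}
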