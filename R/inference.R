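#' @name inference
#' @title Greedy docking with the critic-convergence stopping rule
#'
#' @description
#' At test time the true pose is unknown, so the search cannot be scored.
#' Instead the critic's raw outputs are monitored: once the ligand has
#' moved at least \code{T_MIN} steps, and the range (max - min) of the
#' last \code{delta} critic outputs falls below \code{threshold}, the
#' search stops ("critic converged"). Out-of-box and \code{T_MAX} also
#' terminate. The stopping decision never reads the true pose.
NULL

#' Inference configuration
#'
#' @param T_MAX Maximum steps (default 600, as in training).
#' @param T_MIN Minimum steps before the critic rule may fire (300).
#' @param delta Window length of critic outputs inspected (50).
#' @param threshold Maximum range of the windowed critic outputs (0.3).
#' @param action_mode \code{"greedy"} (argmax, ties to the lowest action
#'   index) or \code{"sampled"}.
#' @return An \code{infer_config}.
#' @export
infer_config <- function(T_MAX = 600L, T_MIN = 300L, delta = 50L,
                         threshold = 0.3,
                         action_mode = c("greedy", "sampled")) {
  action_mode <- match.arg(action_mode)
  stopifnot(T_MIN <= T_MAX, delta >= 1, threshold > 0)
  structure(list(T_MAX = as.integer(T_MAX), T_MIN = as.integer(T_MIN),
                 delta = as.integer(delta), threshold = threshold,
                 action_mode = action_mode),
            class = "infer_config")
}

#' Critic-convergence stopping rule
#'
#' @param critic_history Numeric vector of all critic outputs so far (one
#'   per visited state, including the start state).
#' @param step Number of steps taken so far.
#' @param config An \code{infer_config}.
#' @return TRUE iff \code{step >= T_MIN}, at least \code{delta} outputs
#'   exist, and the range of the last \code{delta} outputs is strictly
#'   below \code{threshold}.
#' @export
should_stop <- function(critic_history, step, config = infer_config()) {
  if (step < config$T_MIN) return(FALSE)
  n <- length(critic_history)
  if (n < config$delta) return(FALSE)
  win <- critic_history[(n - config$delta + 1L):n]
  (max(win) - min(win)) < config$threshold
}

# networks may be replaced by plain functions grid -> list(probs=, value=)
.actor_out <- function(actor, grid) {
  if (is.function(actor)) actor(grid) else net_forward(actor, grid)
}
.critic_out <- function(critic, grid) {
  if (is.function(critic)) {
    out <- critic(grid)
    if (is.list(out)) out$value else out
  } else net_forward(critic, grid)$value
}

#' A uniform-random policy (baseline)
#'
#' @param multi_atom TRUE for the joint translation+rotation space.
#' @return A function usable in place of a trained actor.
#' @export
uniform_actor <- function(multi_atom = FALSE) {
  function(grid) {
    out <- list(probs = rep(1 / 6, 6))
    if (multi_atom) out$probs_rot <- rep(1 / 6, 6)
    out
  }
}

.select_action <- function(fa, multi_atom, mode) {
  pick <- function(p) {
    if (mode == "greedy") which.max(p) else sample.int(6L, 1L, prob = p)
  }
  a <- pick(fa$probs)
  if (multi_atom) c(a, pick(fa$probs_rot)) else a
}

#' Dock one complex
#'
#' Builds a box with a random start, walks the ligand with the actor
#' (greedy by default), records the critic output of every visited state,
#' and terminates on critic convergence, out-of-box, or \code{T_MAX}.
#'
#' @param record An eligible \code{complex_record}.
#' @param actor,critic Trained \code{network}s (or functions taking a grid).
#' @param spec A \code{box_spec}.
#' @param env_cfg An \code{env_config}; its \code{T_MAX} is overridden by
#'   the inference \code{T_MAX}.
#' @param cfg An \code{infer_config}.
#' @param seed Integer seed (box build, start pose, sampled mode).
#' @return A \code{dock_result}: list with \code{trace}
#'   (\code{episode_trace} incl. critic outputs), \code{stop_reason}
#'   (\code{"critic_converged"}, \code{"max_steps"}, \code{"out_of_box"}),
#'   \code{steps}, \code{final_rmsd}, \code{improvement_rate}, \code{box}.
#' @export
dock <- function(record, actor, critic, spec = box_spec(),
                 env_cfg = env_config(), cfg = infer_config(), seed = 1L) {
  env_cfg$T_MAX <- cfg$T_MAX
  box <- make_box(record, spec, seed = seed)
  start <- random_start_pose(box, seed = derive_seed(seed, 1L))
  env <- env_init(box, start, env_cfg)
  poses <- list(start)
  rewards <- numeric()
  actions <- list()
  critic_hist <- .critic_out(critic, env_render(env))
  stop_reason <- "max_steps"
  with_seed_(derive_seed(seed, 2L), {
    while (!env$done) {
      grid <- env_render(env)
      fa <- .actor_out(actor, grid)
      action <- .select_action(fa, env$multi_atom, cfg$action_mode)
      out <- env_step(env, action)
      env <- out$env
      rewards <- c(rewards, out$reward)
      actions[[length(actions) + 1L]] <- action
      poses[[length(poses) + 1L]] <- env$pose
      critic_hist <- c(critic_hist, .critic_out(critic, env_render(env)))
      if (out$done) {
        stop_reason <- out$reason
        break
      }
      if (should_stop(critic_hist, env$step, cfg)) {
        stop_reason <- "critic_converged"
        break
      }
    }
  })
  # out-of-box: final pose is the last in-box pose (already env$pose);
  # drop the duplicate trailing pose the rollback produced
  if (stop_reason == "out_of_box") {
    poses[[length(poses)]] <- NULL
    critic_hist <- critic_hist[-length(critic_hist)]
    rewards_trace <- rewards[-length(rewards)]
  } else rewards_trace <- rewards
  trace <- episode_trace(poses, box$true_pose, rewards_trace, critic_hist,
                         actions)
  structure(list(trace = trace, stop_reason = stop_reason,
                 steps = env$step,
                 final_rmsd = rmsd(env$pose, box$true_pose),
                 improvement_rate = improvement_rate(trace),
                 box = box, seed = as.integer(seed)),
            class = "dock_result")
}

#' @export
print.dock_result <- function(x, ...) {
  cat(sprintf("<dock_result> %d steps (%s): final RMSD %.3f A, improvement %.1f%%\n",
              x$steps, x$stop_reason, x$final_rmsd,
              100 * x$improvement_rate))
  invisible(x)
}

#' Evaluate a dataset of complexes
#'
#' Docks every record and tabulates per-episode final distances and
#' improvement rates with mean/median aggregate rows, plus the DCC
#' success rate at the 4 Angstrom threshold (center-distance for
#' multi-atom ligands, RMSD for single atoms).
#'
#' @param records List of \code{complex_record}.
#' @param actor,critic Trained networks (or functions).
#' @param spec,env_cfg,cfg As in \code{\link{dock}}.
#' @param seed Master seed; episode i uses a derived seed.
#' @return List with \code{table} (see \code{\link{score_traces}}),
#'   \code{dcc_success_rate} and \code{results} (list of
#'   \code{dock_result}).
#' @export
evaluate <- function(records, actor, critic, spec = box_spec(),
                     env_cfg = env_config(), cfg = infer_config(),
                     seed = 1L) {
  stopifnot(length(records) >= 1)
  results <- lapply(seq_along(records), function(i) {
    dock(records[[i]], actor, critic, spec, env_cfg, cfg,
         seed = derive_seed(seed, i))
  })
  traces <- lapply(results, `[[`, "trace")
  multi <- nrow(traces[[1]]$poses[[1]]) > 1
  tab <- score_traces(traces, multi_atom = multi)
  dcc <- vapply(traces, function(tr) {
    final <- tr$poses[[length(tr$poses)]]
    if (multi) center_distance(final, tr$true_pose)
    else rmsd(final, tr$true_pose)
  }, 0)
  list(table = tab, dcc_success_rate = dcc_success_rate(dcc),
       results = results)
}
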