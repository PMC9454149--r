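#' @name training
#' @title Advantage actor-critic training over a stream of boxes
#'
#' @description
#' Each episode feeds a freshly built box (new random rotation, box centre
#' and start pose) to the learner, so the networks see a new environment
#' every episode. Workers roll out the stochastic policy, store
#' post-penalty rewards, and every \code{t_max} steps (or at episode end)
#' turn the buffer into n-step return targets, advantage actor-critic
#' gradients, and an SGD update of the shared parameters. The number of
#' gradient updates in an episode is therefore
#' \code{ceiling(steps / t_max)}. With \code{num_workers = 1} a run is
#' bit-reproducible from its seed; with more workers, concurrent episodes
#' are interleaved step-by-step and apply their updates to the shared
#' parameters in arrival order, emulating asynchronous learners.
NULL

#' Training configuration
#'
#' @param episodes Number of boxes (episodes) to train on.
#' @param gamma Discount factor (1: undiscounted, the default).
#' @param t_max Rollout length between gradient updates.
#' @param lr_actor,lr_critic Learning rates of the two SGD optimizers
#'   (defaults: the single-atom settings 5e-5 and 1e-7).
#' @param num_workers Number of interleaved learners.
#' @param entropy_coef Entropy bonus weight in the policy loss.
#' @param grad_clip Global gradient-norm clip.
#' @param optimizer \code{"rmsprop"} (the optimizer conventionally paired
#'   with this learner family; the default) or plain \code{"sgd"}.
#' @param seed Master seed; every per-episode seed derives from it.
#' @return A \code{train_config}.
#' @export
train_config <- function(episodes = 100L, gamma = 1, t_max = 10L,
                         lr_actor = 5e-5, lr_critic = 1e-7,
                         num_workers = 1L, entropy_coef = 0.01,
                         grad_clip = 40, optimizer = c("rmsprop", "sgd"),
                         seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(gamma >= 0, gamma <= 1, t_max >= 1, lr_actor > 0, lr_critic > 0,
            num_workers >= 1, episodes >= 1)
  structure(list(episodes = as.integer(episodes), gamma = gamma,
                 t_max = as.integer(t_max), lr_actor = lr_actor,
                 lr_critic = lr_critic, num_workers = as.integer(num_workers),
                 entropy_coef = entropy_coef, grad_clip = grad_clip,
                 optimizer = optimizer, seed = as.integer(seed)),
            class = "train_config")
}

#' n-step return targets
#'
#' Backward recursion \code{G_i = R_i + gamma * G_{i+1}} with
#' \code{G} beyond the buffer equal to \code{bootstrap} (0 at episode end,
#' else the critic's value of the successor state).
#'
#' @param rewards Numeric vector of buffered rewards (post-penalty).
#' @param bootstrap Scalar tail value.
#' @param gamma Discount factor.
#' @return Numeric vector of per-step return targets.
#' @export
n_step_returns <- function(rewards, bootstrap = 0, gamma = 1) {
  n <- length(rewards)
  stopifnot(n >= 1)
  G <- numeric(n)
  running <- bootstrap
  for (i in rev(seq_len(n))) {
    running <- rewards[i] + gamma * running
    G[i] <- running
  }
  G
}

# entropy of a probability vector
.entropy <- function(p) -sum(p * log(pmax(p, 1e-12)))

# gradient of (-A * log pi(a) - beta * H) w.r.t. the softmax logits
.policy_head_grad <- function(probs, action, advantage, entropy_coef) {
  onehot <- numeric(length(probs)); onehot[action] <- 1
  H <- .entropy(probs)
  -advantage * (onehot - probs) +
    entropy_coef * probs * (log(pmax(probs, 1e-12)) + H)
}

#' Advantage actor-critic losses and gradients for one rollout buffer
#'
#' Policy loss \code{-sum log pi(a_i|s_i) A_i - beta * H(pi)} with the
#' advantage \code{A_i = G_i - V(s_i)} treated as a constant; for the
#' two-head (multi-atom) policy \code{log pi = log pi_trans + log pi_rot}.
#' Value loss \code{sum (G_i - V(s_i))^2}.
#'
#' @param actor,critic \code{network} objects.
#' @param buffer List of transitions, each a list with \code{grid} and
#'   \code{action} (integer, or \code{c(trans, rot)}).
#' @param returns Return targets aligned to the buffer.
#' @param entropy_coef Entropy bonus weight.
#' @return List: \code{policy_loss}, \code{value_loss}, \code{entropy},
#'   \code{actor_grads}, \code{critic_grads}.
#' @export
compute_losses <- function(actor, critic, buffer, returns,
                           entropy_coef = 0.01) {
  stopifnot(length(buffer) == length(returns))
  ag <- NULL; cg <- NULL
  policy_loss <- 0; value_loss <- 0; entropy <- 0
  multi <- actor$config$variant == "multi"
  for (i in seq_along(buffer)) {
    tr <- buffer[[i]]
    fa <- net_forward(actor, tr$grid, keep = TRUE)
    fc <- net_forward(critic, tr$grid, keep = TRUE)
    V <- fc$value
    G <- returns[i]
    A <- G - V
    act <- unlist(tr$action)
    lp <- log(max(fa$probs[act[1]], 1e-12))
    H <- .entropy(fa$probs)
    dlog <- .policy_head_grad(fa$probs, act[1], A, entropy_coef)
    dlog_r <- NULL
    if (multi) {
      lp <- lp + log(max(fa$probs_rot[act[2]], 1e-12))
      H <- H + .entropy(fa$probs_rot)
      dlog_r <- .policy_head_grad(fa$probs_rot, act[2], A, entropy_coef)
    }
    policy_loss <- policy_loss - lp * A - entropy_coef * H
    entropy <- entropy + H
    gi <- net_backward(actor, fa$cache, dlog, dlog_r)
    ag <- if (is.null(ag)) gi else add_grads(ag, gi)

    value_loss <- value_loss + (G - V)^2
    du <- -2 * (G - V) * (1 - V^2)          # d/du of (G - tanh(u))^2
    ci <- net_backward(critic, fc$cache, du)
    cg <- if (is.null(cg)) ci else add_grads(cg, ci)
  }
  list(policy_loss = policy_loss, value_loss = value_loss, entropy = entropy,
       actor_grads = ag, critic_grads = cg)
}

# one worker-local state
.new_worker <- function(id) {
  list(id = id, active = FALSE, env = NULL, buffer = list(),
       episode = NA_integer_, start_pose = NULL,
       pl = 0, vl = 0, n_updates = 0L)
}

.start_episode <- function(worker, episode, records, spec, env_cfg, ep_seed) {
  record <- records[[(episode - 1L) %% length(records) + 1L]]
  box <- tryCatch(make_box(record, spec, seed = ep_seed),
                  error = function(e) e)
  if (inherits(box, "error")) return(NULL)
  start <- random_start_pose(box, seed = derive_seed(ep_seed, 1L))
  env <- env_init(box, start, env_cfg)
  worker$active <- TRUE
  worker$env <- env
  worker$buffer <- list()
  worker$episode <- episode
  worker$start_pose <- start
  worker$pl <- 0; worker$vl <- 0; worker$n_updates <- 0L
  worker
}

#' Train actor and critic on a dataset of complexes
#'
#' Runs the episodic advantage actor-critic loop described in the module
#' overview: fresh box per episode, stochastic action draws from the
#' policy (both heads independently for multi-atom ligands), n-step
#' updates with separate actor/critic SGD optimizers, per-episode logging
#' of the final-state RMSD and improvement rate (the learning-curve
#' series).
#'
#' @param records List of eligible \code{complex_record} objects.
#' @param actor,critic Initialized \code{network}s (shared parameters).
#' @param spec A \code{box_spec}.
#' @param env_cfg An \code{env_config}.
#' @param cfg A \code{train_config}.
#' @param verbose Print a progress line every 50 episodes.
#' @return List with the trained \code{actor} and \code{critic} and
#'   \code{log}: data.frame (episode, steps, final_rmsd, improvement_rate,
#'   policy_loss, value_loss, n_updates, reason).
#' @export
train <- function(records, actor, critic, spec = box_spec(),
                  env_cfg = env_config(), cfg = train_config(),
                  verbose = FALSE) {
  stopifnot(length(records) >= 1)
  log_rows <- vector("list", cfg$episodes)
  with_seed_(cfg$seed, {
    ep_seeds <- sample.int(2147483646L, cfg$episodes)
    workers <- lapply(seq_len(cfg$num_workers), .new_worker)
    next_episode <- 1L
    flush <- function(w) {
      rewards <- vapply(w$buffer, `[[`, 0, "reward")
      bootstrap <- if (w$env$done) 0 else {
        net_forward(critic, env_render(w$env))$value
      }
      returns <- n_step_returns(rewards, bootstrap, cfg$gamma)
      ls <- compute_losses(actor, critic, w$buffer, returns,
                           cfg$entropy_coef)
      if (cfg$optimizer == "rmsprop") {
        actor <<- rmsprop_update(actor, ls$actor_grads, cfg$lr_actor,
                                 cfg$grad_clip)
        critic <<- rmsprop_update(critic, ls$critic_grads, cfg$lr_critic,
                                  cfg$grad_clip)
      } else {
        actor <<- sgd_update(actor, ls$actor_grads, cfg$lr_actor,
                             cfg$grad_clip)
        critic <<- sgd_update(critic, ls$critic_grads, cfg$lr_critic,
                              cfg$grad_clip)
      }
      w$pl <- w$pl + ls$policy_loss
      w$vl <- w$vl + ls$value_loss
      w$n_updates <- w$n_updates + 1L
      w$buffer <- list()
      w
    }
    repeat {
      idle <- which(!vapply(workers, `[[`, TRUE, "active"))
      for (wi in idle) {
        while (next_episode <= cfg$episodes) {
          ep <- next_episode; next_episode <- next_episode + 1L
          w2 <- .start_episode(workers[[wi]], ep, records, spec, env_cfg,
                               ep_seeds[ep])
          if (is.null(w2)) {
            log_rows[[ep]] <- data.frame(episode = ep, steps = NA_integer_,
              final_rmsd = NA_real_, improvement_rate = NA_real_,
              policy_loss = NA_real_, value_loss = NA_real_,
              n_updates = 0L, reason = "box_placement_failed")
            next
          }
          workers[[wi]] <- w2
          break
        }
      }
      active <- which(vapply(workers, `[[`, TRUE, "active"))
      if (!length(active)) break
      for (wi in active) {
        w <- workers[[wi]]
        grid <- env_render(w$env)
        fa <- net_forward(actor, grid)
        a_t <- sample.int(6L, 1L, prob = fa$probs)
        action <- if (w$env$multi_atom) {
          c(a_t, sample.int(6L, 1L, prob = fa$probs_rot))
        } else a_t
        out <- env_step(w$env, action)
        w$env <- out$env
        w$buffer[[length(w$buffer) + 1L]] <-
          list(grid = grid, action = action, reward = out$reward)
        if (length(w$buffer) >= cfg$t_max || out$done) w <- flush(w)
        if (out$done) {
          tr <- episode_trace(list(w$start_pose, w$env$pose),
                              w$env$box$true_pose)
          fin <- rmsd(w$env$pose, w$env$box$true_pose)
          log_rows[[w$episode]] <- data.frame(
            episode = w$episode, steps = w$env$step,
            final_rmsd = fin, improvement_rate = improvement_rate(tr),
            policy_loss = w$pl, value_loss = w$vl,
            n_updates = w$n_updates, reason = out$reason)
          if (verbose && w$episode %% 50 == 0) {
            message(sprintf("episode %d: final RMSD %.2f", w$episode, fin))
          }
          w$active <- FALSE
        }
        workers[[wi]] <- w
      }
    }
  })
  list(actor = actor, critic = critic,
       log = do.call(rbind, log_rows[!vapply(log_rows, is.null, TRUE)]))
}
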