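#' @name metrics
#' @title Pose distances and search-path scores
#'
#' @description
#' Every quantity the framework is evaluated with: index-matched RMSD,
#' symmetry-corrected permutation-distance for sulfate, center-distance,
#' improvement rate, long-term reward \eqn{G_t}, the critic-distance
#' inversion, and the DCC success rate.
NULL

#' Root-mean-square deviation between two poses
#'
#' @param a,b Poses (\code{ligand_pose} or plain n x 3 matrices) with equal
#'   atom counts and matched atom order.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (nrow(a) != nrow(b)) stop("invalid comparison: atom counts differ")
  sqrt(mean(rowSums((a - b)^2)))
}

# all permutations of 1..n (n small), deterministic order
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' Symmetry-corrected RMSD for sulfate-like ligands
#'
#' A sulfate's four oxygens are chemically indistinguishable, so two poses
#' can be matched in 4! = 24 ways (sulfur always maps to sulfur). The
#' permutation-distance is the smallest RMSD over all 24 matchings,
#' enumerated exhaustively.
#'
#' @param a,b Sulfate poses: exactly one S and four O atoms each.
#' @return Minimum RMSD in Angstrom.
#' @export
permutation_rmsd <- function(a, b) {
  ea <- pose_elements(a); eb <- pose_elements(b)
  if (is.null(ea) || is.null(eb) ||
      sum(ea == "S") != 1 || sum(ea == "O") != 4 ||
      sum(eb == "S") != 1 || sum(eb == "O") != 4) {
    stop("permutation_rmsd requires poses with 1 S and 4 O atoms")
  }
  sa <- unclass(a)[ea == "S", , drop = FALSE]
  sb <- unclass(b)[eb == "S", , drop = FALSE]
  oa <- unclass(a)[ea == "O", , drop = FALSE]
  ob <- unclass(b)[eb == "O", , drop = FALSE]
  perms <- .permutations(4L)
  best <- Inf
  for (i in seq_len(nrow(perms))) {
    d2 <- sum((sa - sb)^2) + sum((oa - ob[perms[i, ], , drop = FALSE])^2)
    best <- min(best, d2)
  }
  sqrt(best / 5)
}

#' Center-distance of a sulfate pose
#'
#' Euclidean distance between the sulfur atoms of the two poses; the
#' oxygens are ignored.
#'
#' @param a A sulfate pose.
#' @param s_0 The true sulfate pose.
#' @return Distance in Angstrom.
#' @export
center_distance <- function(a, s_0) {
  ea <- pose_elements(a); e0 <- pose_elements(s_0)
  if (is.null(ea) || sum(ea == "S") != 1 || is.null(e0) || sum(e0 == "S") != 1)
    stop("center_distance requires poses with exactly one S atom")
  sqrt(sum((unclass(a)[ea == "S", ] - unclass(s_0)[e0 == "S", ])^2))
}

#' Episode trace
#'
#' The record of one episode: the pose sequence from start to final state,
#' the per-step rewards, and (optionally) the critic outputs.
#'
#' @param poses List of \code{ligand_pose}, length \code{steps + 1}.
#' @param true_pose The true \code{ligand_pose} \eqn{s_0}.
#' @param rewards Numeric vector, length \code{length(poses) - 1}.
#' @param critic_outputs Optional numeric vector, one per pose (or empty).
#' @param actions Optional list of the actions taken.
#' @return An \code{episode_trace}.
#' @export
episode_trace <- function(poses, true_pose, rewards = numeric(),
                          critic_outputs = numeric(), actions = list()) {
  stopifnot(length(rewards) == 0 || length(rewards) == length(poses) - 1,
            length(critic_outputs) %in% c(0L, length(poses)))
  structure(list(poses = poses, true_pose = true_pose, rewards = rewards,
                 critic_outputs = critic_outputs, actions = actions),
            class = "episode_trace")
}

#' Improvement rate of a search path
#'
#' Fractional reduction of the start-to-truth distance:
#' \code{(D(s0, s_start) - D(s0, s_end)) / D(s0, s_start)}. 1 is a perfect
#' dock, 0 no net movement, negative values mean the path ended farther
#' away than it started.
#'
#' @param trace An \code{episode_trace}.
#' @param dist_fn Distance function \code{(pose, true_pose) -> Angstrom};
#'   defaults to \code{\link{rmsd}}.
#' @return Dimensionless fraction (at most 1).
#' @export
improvement_rate <- function(trace, dist_fn = rmsd) {
  d_start <- dist_fn(trace$poses[[1]], trace$true_pose)
  if (d_start <= 0) stop("improvement rate undefined: zero start distance")
  d_end <- dist_fn(trace$poses[[length(trace$poses)]], trace$true_pose)
  (d_start - d_end) / d_start
}

#' Long-term reward of a state on a completed path
#'
#' \deqn{G_t = e^{-RMSD(s_0, s_{end})/18} - e^{-RMSD(s_0, s_t)/18}}
#' the undiscounted return the critic is trained to predict.
#'
#' @param trace An \code{episode_trace}.
#' @param t Step index of the state, 0-based (0 = start state, matching the
#'   environment's step counter).
#' @param scale Exponential scale in Angstrom (default 18, the box edge).
#' @return Dimensionless return in \code{(-1, 1)}.
#' @export
long_term_reward <- function(trace, t, scale = 18) {
  n <- length(trace$poses)
  stopifnot(t >= 0, t <= n - 1)
  s_end <- trace$poses[[n]]
  s_t <- trace$poses[[t + 1]]
  exp(-rmsd(trace$true_pose, s_end) / scale) -
    exp(-rmsd(trace$true_pose, s_t) / scale)
}

#' Critic distance: invert the long-term-reward formula
#'
#' Solves \eqn{O_t = e^{-d_{end}/18} - e^{-d_t/18}} for \eqn{d_t}:
#' \code{-18 * log(exp(-rmsd_end/18) - O_t)}. With the true \eqn{G_t} this
#' recovers \eqn{RMSD(s_0, s_t)} exactly; with the critic's output it is
#' the critic's implied distance-to-truth.
#'
#' @param O_t Critic output (or exact \eqn{G_t}).
#' @param rmsd_end Final-state RMSD to truth, Angstrom.
#' @param scale Exponential scale in Angstrom (default 18).
#' @return Implied distance in Angstrom.
#' @export
critic_distance <- function(O_t, rmsd_end, scale = 18) {
  arg <- exp(-rmsd_end / scale) - O_t
  if (any(arg <= 0)) stop("critic output out of range: log argument <= 0")
  -scale * log(arg)
}

#' DCC success rate
#'
#' Fraction of predictions whose distance-to-true-center falls strictly
#' below the threshold (4 Angstrom by convention).
#'
#' @param distances Numeric vector of final distances, Angstrom.
#' @param threshold Success cutoff in Angstrom.
#' @return Fraction in [0, 1].
#' @export
dcc_success_rate <- function(distances, threshold = 4) {
  if (!length(distances)) stop("empty distance list")
  mean(distances < threshold)
}

#' Score a batch of episode traces
#'
#' @param traces List of \code{episode_trace}.
#' @param multi_atom TRUE to report permutation- and center-distance
#'   columns (sulfate layout) instead of plain RMSD.
#' @return data.frame with one row per trace plus the per-column
#'   mean/median aggregate rows at the bottom (column \code{episode} =
#'   "mean"/"median").
#' @export
score_traces <- function(traces, multi_atom = FALSE) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    final <- tr$poses[[length(tr$poses)]]
    if (multi_atom) {
      data.frame(episode = as.character(i),
                 permutation_distance = permutation_rmsd(final, tr$true_pose),
                 center_distance = center_distance(final, tr$true_pose),
                 improvement_rate_perm = improvement_rate(tr, permutation_rmsd),
                 improvement_rate_center = improvement_rate(tr, center_distance),
                 steps = length(tr$poses) - 1L, stringsAsFactors = FALSE)
    } else {
      data.frame(episode = as.character(i),
                 rmsd = rmsd(final, tr$true_pose),
                 improvement_rate = improvement_rate(tr),
                 steps = length(tr$poses) - 1L, stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  num <- names(tab)[vapply(tab, is.numeric, TRUE)]
  agg <- rbind(
    cbind(data.frame(episode = "mean"), as.data.frame(lapply(tab[num], mean))),
    cbind(data.frame(episode = "median"), as.data.frame(lapply(tab[num], median)))
  )
  rbind(tab, agg)
}
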