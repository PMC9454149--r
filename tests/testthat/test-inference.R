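test_that("should_stop gates on T_MIN, window length and range", {
  cfg <- infer_config(T_MAX = 600, T_MIN = 300, delta = 50, threshold = 0.3)
  # before T_MIN: never
  expect_false(should_stop(rep(0.5, 200), step = 100, cfg))
  # range 0.29 within the last 50: stop
  hist <- c(runif(300, -1, 1), seq(0.0, 0.29, length.out = 50))
  expect_true(should_stop(hist, step = 350, cfg))
  # range 0.31: keep searching
  hist2 <- c(runif(300, -1, 1), seq(0.0, 0.31, length.out = 50))
  expect_false(should_stop(hist2, step = 350, cfg))
  # short history: never
  expect_false(should_stop(rep(0, 10), step = 350, cfg))
})

test_that("stop decision is monotone under in-range appends", {
  cfg <- infer_config(T_MIN = 10, delta = 5, threshold = 0.3)
  set.seed(1)
  hist <- runif(12, 0.4, 0.6)
  stopifnot(should_stop(hist, 12, cfg))
  for (i in 1:20) {
    win <- tail(hist, 5)
    hist2 <- c(hist, runif(1, min(win), max(win)))
    expect_true(should_stop(hist2, 13, cfg))
  }
})

test_that("constant critic stops greedy rollouts at exactly T_MIN", {
  fx <- make_fixture(seed = 61)
  cfg <- infer_config(T_MAX = 60, T_MIN = 25, delta = 10, threshold = 0.3)
  actor <- build_network("actor", test_net_config(), seed = 1)
  res <- dock(fx$record, actor, function(g) 0.123, test_spec(),
              env_config(step_translation = 0.05), cfg, seed = 5)
  if (res$stop_reason == "critic_converged") {
    expect_equal(res$steps, 25)
  } else {
    # tiny steps make out-of-box essentially impossible; guard anyway
    expect_equal(res$stop_reason, "out_of_box")
  }
  # oscillating critic with range > threshold never converges
  flip <- local({ i <- 0; function(g) { i <<- i + 1; 0.4 * (i %% 2) } })
  res2 <- dock(fx$record, actor, flip, test_spec(),
               env_config(step_translation = 0.05), cfg, seed = 5)
  expect_true(res2$stop_reason %in% c("max_steps", "out_of_box"))
})

test_that("greedy docking is bit-reproducible and truth-free", {
  fx <- make_fixture(seed = 62)
  actor <- build_network("actor", test_net_config(), seed = 2)
  critic <- build_network("critic", test_net_config(), seed = 3)
  cfg <- infer_config(T_MAX = 30, T_MIN = 30, delta = 30)
  r1 <- dock(fx$record, actor, critic, test_spec(), env_config(), cfg,
             seed = 11)
  r2 <- dock(fx$record, actor, critic, test_spec(), env_config(), cfg,
             seed = 11)
  expect_identical(r1$trace$poses, r2$trace$poses)
  expect_identical(r1$trace$critic_outputs, r2$trace$critic_outputs)
  expect_equal(length(r1$trace$critic_outputs), length(r1$trace$poses))
  # trace bookkeeping: |rewards| = |poses| - 1
  expect_equal(length(r1$trace$rewards), length(r1$trace$poses) - 1)
})

test_that("an oracle actor docks a straight-line fixture", {
  # constructed fixture: empty pocket, truth reachable by -x moves; the
  # "actor" is an oracle function always preferring the best greedy action
  fx <- make_fixture(pocket = "empty", seed = 63)
  spec <- test_spec(min_protein_atoms = 0)
  ecfg <- env_config(T_MAX = 300, step_translation = 0.2)
  box_probe <- make_box(fx$record, spec, seed = 9)
  oracle <- local({
    box <- box_probe
    pose_now <- NULL
    function(g) {
      # decode the ligand position from the grid's ligand channel mass
      # centroid; move along the axis with the largest error
      lig <- g[, , , box$channel_map$n_protein + 1]
      idx <- which(lig > 0, arr.ind = TRUE)
      w <- lig[lig > 0]
      pos <- colSums(idx * w) / sum(w) - 0.5
      tp <- colMeans(unclass(box$true_pose))
      d <- tp - pos
      ax <- which.max(abs(d))
      a <- (ax - 1) * 2 + if (d[ax] > 0) 1 else 2
      p <- rep(1e-6, 6); p[a] <- 1 - 5e-6
      list(probs = p)
    }
  })
  res <- dock(fx$record, oracle, function(g) 0, spec, ecfg,
              infer_config(T_MAX = 300, T_MIN = 300, delta = 300), seed = 9)
  expect_gt(res$improvement_rate, 0.8)
})

test_that("evaluate aggregates distances and the DCC rate", {
  suite <- make_suite(3, base_seed = 91)
  actor <- build_network("actor", test_net_config(), seed = 4)
  critic <- build_network("critic", test_net_config(), seed = 5)
  ev <- evaluate(suite$records, actor, critic, test_spec(),
                 env_config(T_MAX = 20), infer_config(T_MAX = 20, T_MIN = 20,
                                                      delta = 20), seed = 2)
  tab <- ev$table
  expect_true(all(c("rmsd", "improvement_rate") %in% names(tab)))
  expect_true(all(c("mean", "median") %in% tab$episode))
  per <- tab[!(tab$episode %in% c("mean", "median")), ]
  expect_equal(tab$rmsd[tab$episode == "mean"], mean(per$rmsd))
  expect_gte(ev$dcc_success_rate, 0)
  expect_lte(ev$dcc_success_rate, 1)

  # sulfate evaluation reports permutation- and center-distance columns
  ssuite <- make_suite(2, base_seed = 92, ligand = "sulfate_like")
  am <- build_network("actor", test_net_config(7L, "multi"), seed = 6)
  cm_ <- build_network("critic", test_net_config(7L, "multi"), seed = 7)
  ev2 <- evaluate(ssuite$records, am, cm_, test_spec(),
                  env_config(T_MAX = 10), infer_config(T_MAX = 10, T_MIN = 10,
                                                       delta = 10), seed = 3)
  expect_true(all(c("permutation_distance", "center_distance",
                    "improvement_rate_perm", "improvement_rate_center")
                  %in% names(ev2$table)))
})
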