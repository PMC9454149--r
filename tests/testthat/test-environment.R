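test_that("apply_action translates rigidly and inverts", {
  cfg <- env_config()
  p <- ligand_pose(matrix(c(5, 5, 5), 1, 3), "CU")
  p2 <- apply_action(p, 1L, cfg)   # +x
  expect_equal(unclass(p2) - unclass(p), matrix(c(0.1, 0, 0), 1, 3),
               ignore_attr = TRUE)
  # +x then -x restores the pose
  p3 <- apply_action(p2, 2L, cfg)
  expect_equal(unclass(p3), unclass(p), tolerance = 1e-12)

  # sulfate: rotation about the centroid preserves centroid and radii
  s <- random_sulfate(seed = 5)
  s2 <- apply_action(s, c(1L, 5L), cfg)  # +x translation, +z rotation
  expect_equal(colMeans(unclass(s2)) - colMeans(unclass(s)), c(0.1, 0, 0),
               tolerance = 1e-12)
  r_before <- sqrt(rowSums(sweep(unclass(s), 2, colMeans(unclass(s)))^2))
  r_after <- sqrt(rowSums(sweep(unclass(s2), 2, colMeans(unclass(s2)))^2))
  expect_equal(r_after, r_before, tolerance = 1e-9)
  # rigid: interatomic distances preserved
  expect_equal(dist(unclass(s2)), dist(unclass(s)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # inverse pair restores the sulfate pose too
  s3 <- apply_action(apply_action(s, c(1L, 5L), cfg), c(2L, 6L), cfg)
  expect_equal(unclass(s3), unclass(s), tolerance = 1e-12)
})

test_that("immediate_reward implements the exponential difference with doubling", {
  cfg <- env_config()
  s0 <- ligand_pose(matrix(c(0, 0, 0), 1, 3), "CU")
  # zero case
  st <- ligand_pose(matrix(c(3, 0, 0), 1, 3), "CU")
  expect_equal(immediate_reward(st, st, s0, cfg), 0)
  # RMSD(s0, s_t) = 18, s_next = s0: reward = 1 - exp(-1)
  far <- ligand_pose(matrix(c(18, 0, 0), 1, 3), "CU")
  expect_equal(immediate_reward(far, s0, s0, cfg), 1 - exp(-1),
               tolerance = 1e-12)
  # negative raw rewards are doubled
  near <- ligand_pose(matrix(c(1, 0, 0), 1, 3), "CU")
  away <- ligand_pose(matrix(c(2, 0, 0), 1, 3), "CU")
  raw <- exp(-2 / 18) - exp(-1 / 18)
  expect_equal(immediate_reward(near, away, s0, cfg), 2 * raw,
               tolerance = 1e-12)
  expect_error(immediate_reward(random_sulfate(), st, s0, cfg),
               "atom counts differ")
})

test_that("reward sign iff improvement, bounds respected", {
  cfg <- env_config()
  s0 <- ligand_pose(matrix(c(9, 9, 9), 1, 3), "CU")
  set.seed(11)
  for (i in 1:50) {
    a <- ligand_pose(matrix(9 + runif(3, -6, 6), 1, 3), "CU")
    b <- ligand_pose(matrix(9 + runif(3, -6, 6), 1, 3), "CU")
    r <- immediate_reward(a, b, s0, cfg)
    expect_gt(r, -2); expect_lt(r, 1)
    d_a <- rmsd(a, s0); d_b <- rmsd(b, s0)
    if (d_b < d_a) expect_gt(r, 0) else if (d_b > d_a) expect_lt(r, 0)
  }
})

test_that("telescoping return on monotone trajectories", {
  # straight-line approach: all raw rewards positive, sum telescopes to the
  # G_t formula at gamma = 1
  cfg <- env_config()
  fx <- make_fixture(seed = 41)
  box <- make_box(fx$record, test_spec(), seed = 1)
  s0 <- box$true_pose
  start <- ligand_pose(unclass(s0) + matrix(c(3, 0, 0), 1, 3),
                       pose_elements(s0))
  env <- env_init(box, start, cfg)
  total <- 0
  for (k in 1:15) {  # 15 steps of -x at 0.1 A approach the truth
    out <- env_step(env, 2L)
    expect_gt(out$reward, 0)
    total <- total + out$reward
    env <- out$env
  }
  expected <- exp(-rmsd(s0, env$pose) / 18) - exp(-rmsd(s0, start) / 18)
  expect_equal(total, expected, tolerance = 1e-9)
})

test_that("step terminates on max_steps and out_of_box", {
  fx <- make_fixture(seed = 42)
  box <- make_box(fx$record, test_spec(), seed = 2)
  cfg <- env_config(T_MAX = 5)
  start <- ligand_pose(matrix(c(6, 6, 6), 1, 3), "CU")
  env <- env_init(box, start, cfg)
  for (k in 1:5) out <- { e <- env_step(env, if (k %% 2) 1L else 2L); env <- e$env; e }
  expect_true(out$done)
  expect_equal(out$reason, "max_steps")
  expect_error(env_step(env, 1L), "finished episode")

  # walking +x from near the wall exits the box
  env2 <- env_init(box, ligand_pose(matrix(c(11.95, 6, 6), 1, 3), "CU"),
                   env_config(T_MAX = 100))
  out2 <- env_step(env2, 1L)
  expect_true(out2$done)
  expect_equal(out2$reason, "out_of_box")
  # final pose is the last in-box pose
  expect_equal(unclass(out2$env$pose)[1, 1], 11.95)
})

test_that("stepping never touches protein channels", {
  fx <- make_fixture(seed = 43)
  box <- make_box(fx$record, test_spec(), seed = 3)
  env <- env_init(box, ligand_pose(matrix(c(6, 6, 6), 1, 3), "CU"),
                  env_config())
  g0 <- env_render(env)
  out <- env_step(env, 3L)
  g1 <- env_render(out$env)
  pc <- seq_len(box$channel_map$n_protein)
  expect_identical(g1[, , , pc], g0[, , , pc])
  expect_false(identical(g1, g0))
})
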