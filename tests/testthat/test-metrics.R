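test_that("rmsd matches the definition", {
  a1 <- ligand_pose(matrix(c(0, 0, 0), 1, 3), "CU")
  expect_equal(rmsd(a1, a1), 0)
  # single atoms 3 A apart
  b1 <- ligand_pose(matrix(c(3, 0, 0), 1, 3), "CU")
  expect_equal(rmsd(a1, b1), 3)
  # per-atom displacements 3 and 4: sqrt((9+16)/2)
  a2 <- ligand_pose(rbind(c(0, 0, 0), c(10, 0, 0)), c("C", "C"))
  b2 <- ligand_pose(rbind(c(3, 0, 0), c(10, 4, 0)), c("C", "C"))
  expect_equal(rmsd(a2, b2), sqrt(25 / 2), tolerance = 1e-12)
  expect_error(rmsd(a1, a2), "atom counts differ")
})

test_that("permutation_rmsd absorbs oxygen relabelling and is minimal", {
  s <- random_sulfate(seed = 1)
  # cyclic relabelling of the oxygens: distance 0
  co <- unclass(s)
  relab <- ligand_pose(co[c(1, 3, 4, 5, 2), ], c("S", "O", "O", "O", "O"))
  expect_equal(permutation_rmsd(s, relab), 0, tolerance = 1e-12)
  # upper-bounded by the index-matched rmsd
  set.seed(2)
  for (i in 1:20) {
    a <- random_sulfate(center = runif(3, 3, 9))
    b <- random_sulfate(center = runif(3, 3, 9))
    expect_lte(permutation_rmsd(a, b), rmsd(a, b) + 1e-12)
  }
  expect_error(permutation_rmsd(s, ligand_pose(matrix(0, 1, 3), "CU")),
               "1 S and 4 O")
})

test_that("permutation_rmsd equals the brute-force oracle", {
  set.seed(3)
  for (i in 1:25) {
    a <- random_sulfate(center = runif(3, 3, 9))
    b <- random_sulfate(center = runif(3, 3, 9))
    expect_equal(permutation_rmsd(a, b), oracle_perm_rmsd(a, b),
                 tolerance = 1e-12)
  }
})

test_that("permutation_rmsd is a pseudo-metric on random triples", {
  set.seed(4)
  for (i in 1:15) {
    a <- random_sulfate(center = runif(3, 3, 9))
    b <- random_sulfate(center = runif(3, 3, 9))
    c_ <- random_sulfate(center = runif(3, 3, 9))
    expect_equal(permutation_rmsd(a, b), permutation_rmsd(b, a),
                 tolerance = 1e-12)
    expect_lte(permutation_rmsd(a, c_),
               permutation_rmsd(a, b) + permutation_rmsd(b, c_) + 1e-9)
  }
})

test_that("center_distance uses the sulfur atoms only", {
  a <- random_sulfate(center = c(5, 5, 5), seed = 6)
  b <- random_sulfate(center = c(9, 5, 5), seed = 7)  # S atoms 4 A apart
  expect_equal(center_distance(a, a), 0)
  expect_equal(center_distance(a, b), 4, tolerance = 1e-12)
  # equals rmsd restricted to the S pair
  sa <- ligand_pose(unclass(a)[1, , drop = FALSE], "S")
  sb <- ligand_pose(unclass(b)[1, , drop = FALSE], "S")
  expect_equal(center_distance(a, b), rmsd(sa, sb), tolerance = 1e-12)
})

test_that("improvement_rate covers perfect, null and worsening paths", {
  s0 <- ligand_pose(matrix(c(0, 0, 0), 1, 3), "CU")
  p5 <- ligand_pose(matrix(c(5, 0, 0), 1, 3), "CU")
  p10 <- ligand_pose(matrix(c(10, 0, 0), 1, 3), "CU")
  expect_equal(improvement_rate(episode_trace(list(p5, s0), s0)), 1)
  expect_equal(improvement_rate(episode_trace(list(p5, p5), s0)), 0)
  expect_equal(improvement_rate(episode_trace(list(p5, p10), s0)), -1)
  expect_error(improvement_rate(episode_trace(list(s0, p5), s0)),
               "zero start distance")
})

test_that("improvement_rate is invariant under rigid transformation", {
  set.seed(8)
  s0 <- random_sulfate(center = c(5, 5, 5))
  p1 <- random_sulfate(center = c(8, 5, 5))
  p2 <- random_sulfate(center = c(6, 6, 5))
  tr <- episode_trace(list(p1, p2), s0)
  base <- improvement_rate(tr)
  R <- random_rotation(); shift <- runif(3, -3, 3)
  move <- function(p) ligand_pose(sweep(unclass(p) %*% t(R), 2, shift, "+"),
                                  pose_elements(p))
  tr2 <- episode_trace(list(move(p1), move(p2)), move(s0))
  expect_equal(improvement_rate(tr2), base, tolerance = 1e-9)
})

test_that("long_term_reward and critic_distance invert each other", {
  s0 <- ligand_pose(matrix(c(0, 0, 0), 1, 3), "CU")
  p18 <- ligand_pose(matrix(c(18, 0, 0), 1, 3), "CU")
  # s_end = s0, RMSD(s0, s_t) = 18: G = 1 - exp(-1)
  tr <- episode_trace(list(p18, s0), s0)
  expect_equal(long_term_reward(tr, 0), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(long_term_reward(tr, 1), 0)
  # O_t = 0 recovers rmsd_end exactly
  expect_equal(critic_distance(0, 2), 2, tolerance = 1e-12)
  # direct arithmetic example
  expect_equal(critic_distance(0.3, 2), -18 * log(exp(-2 / 18) - 0.3),
               tolerance = 1e-12)
  expect_error(critic_distance(0.95, 2), "out of range")
  # inversion identity along a whole random trajectory
  set.seed(9)
  poses <- lapply(1:6, function(i)
    ligand_pose(matrix(runif(3, 0, 12), 1, 3), "CU"))
  trr <- episode_trace(poses, s0)
  d_end <- rmsd(poses[[6]], s0)
  for (t in 0:5) {
    expect_equal(critic_distance(long_term_reward(trr, t), d_end),
                 rmsd(poses[[t + 1]], s0), tolerance = 1e-9)
  }
})

test_that("dcc_success_rate counts strict sub-threshold fractions", {
  expect_equal(dcc_success_rate(c(1, 3, 5, 9), 4), 0.5)
  expect_equal(dcc_success_rate(rep(0, 5)), 1)
  expect_equal(dcc_success_rate(c(4, 6, 8)), 0)
  expect_error(dcc_success_rate(numeric()), "empty")
})

test_that("score_traces mirrors the results-table layout", {
  s0 <- ligand_pose(matrix(c(0, 0, 0), 1, 3), "CU")
  mk <- function(d_start, d_end) episode_trace(
    list(ligand_pose(matrix(c(d_start, 0, 0), 1, 3), "CU"),
         ligand_pose(matrix(c(d_end, 0, 0), 1, 3), "CU")), s0)
  tab <- score_traces(list(mk(5, 2), mk(10, 2)))
  expect_equal(tab$rmsd[tab$episode == "mean"], 2)
  expect_equal(tab$improvement_rate[tab$episode == "mean"],
               mean(c(0.6, 0.8)))
  expect_equal(tab$improvement_rate[tab$episode == "median"],
               median(c(0.6, 0.8)))
})
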