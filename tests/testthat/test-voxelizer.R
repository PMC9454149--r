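test_that("gaussian_splat covers 27 voxels with unit mass and symmetry", {
  spec <- box_spec()
  s <- gaussian_splat(c(9.3, 8.7, 9.1), r = 1.7, spec)
  expect_equal(nrow(s), 27)
  expect_equal(sum(s$w), 1, tolerance = 1e-12)

  # atom exactly at a voxel centre: neighbour classes have equal weights
  s2 <- gaussian_splat(c(9.5, 9.5, 9.5), r = 1.7, spec)
  off <- abs(cbind(s2$ix, s2$iy, s2$iz) - 10L)
  cls <- rowSums(off)  # 0 = centre, 1 = face, 2 = edge, 3 = corner
  for (k in 1:3) {
    expect_equal(length(unique(round(s2$w[cls == k], 15))), 1)
  }
  expect_equal(sum(cls == 1), 6)
  expect_equal(sum(cls == 2), 12)
  expect_equal(sum(cls == 3), 8)
})

test_that("gaussian_splat matches direct kernel evaluation (r = 1.4)", {
  # independent oracle: evaluate the printed Gaussian at all 27 offsets
  spec <- box_spec()
  p <- c(9.5, 9.5, 9.5)  # a voxel centre
  r <- 1.4
  s <- gaussian_splat(p, r, spec)
  w_exp <- numeric(27)
  i <- 0
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    i <- i + 1
    d2 <- sum((c(dx, dy, dz))^2)  # offsets in voxel units = Angstrom here
    w_exp[i] <- (2 * pi * r^2)^(-3 / 2) * exp(-d2 / (2 * r^2))
  }
  w_exp <- w_exp / sum(w_exp)
  # match by voxel offset
  key_impl <- paste(s$ix - 10L, s$iy - 10L, s$iz - 10L)
  key_orac <- as.vector(t(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)))
  ko <- apply(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1), 1,
              function(v) paste(v[["dx"]], v[["dy"]], v[["dz"]]))
  expect_equal(s$w[order(key_impl)], w_exp[order(ko)], tolerance = 1e-12)
  expect_error(gaussian_splat(c(-1, 5, 5), 1.4, spec), "outside grid")
})

test_that("make_box honours margin, determinism and grid extent", {
  rec <- make_fixture(seed = 31)$record
  spec <- box_spec(edge = 18, margin = 2, min_protein_atoms = 10)
  box <- make_box(rec, spec, seed = 5)
  expect_equal(spec$n_voxels, 18L)
  tp <- unclass(box$true_pose)
  expect_true(all(tp >= 2 - 1e-9) && all(tp <= 18 - 2 + 1e-9))
  expect_gte(nrow(box$protein), 10)
  # same record + seed: bit-identical geometry
  box2 <- make_box(rec, spec, seed = 5)
  expect_identical(box$origin, box2$origin)
  expect_identical(box$rotation, box2$rotation)
  expect_identical(unclass(box$true_pose), unclass(box2$true_pose))
  # rotation is orthonormal
  expect_equal(crossprod(box$rotation), diag(3), tolerance = 1e-9)
  # infeasible protein requirement fails loudly
  expect_error(make_box(rec, box_spec(min_protein_atoms = 10000,
                                      max_attempts = 5), seed = 1),
               "box placement failed")
})

test_that("random_start_pose is in-box and rigid", {
  fx <- make_fixture(ligand = "sulfate_like", seed = 32)
  spec <- test_spec()
  box <- make_box(fx$record, spec, seed = 3)
  for (s in 1:5) {
    sp <- random_start_pose(box, seed = s)
    co <- unclass(sp)
    expect_true(all(co > 0) && all(co < spec$edge))
    # rigid: pairwise distances preserved to 1e-9
    expect_equal(dist(co), dist(unclass(box$true_pose)), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("render sums per-channel splats with mass conservation", {
  fx <- make_fixture(seed = 33)
  spec <- test_spec()
  box <- make_box(fx$record, spec, seed = 7)
  cm <- box$channel_map
  # single ligand atom well inside: ligand channel mass 1, protein channels
  # depend only on protein atoms
  pose <- ligand_pose(matrix(c(6, 6, 6), 1, 3), "CU")
  g <- render_grid(box, pose)
  expect_equal(dim(g), c(12, 12, 12, cm$n_channels))
  expect_true(all(g >= 0))
  lig_ch <- cm$n_protein + 1L
  expect_equal(sum(g[, , , lig_ch]), 1, tolerance = 1e-12)
  # default Cu configuration: channel axis length 22
  expect_equal(channel_map("CU", "full")$n_channels, 22L)
  # interior atoms conserve mass: total protein mass equals count of atoms
  # at least 1 voxel from every face
  interior <- with(box$protein, x >= 1 & x <= 11 & y >= 1 & y <= 11 &
                                z >= 1 & z <= 11)
  prot_mass <- sum(g[, , , seq_len(cm$n_protein)])
  expect_gte(prot_mass, sum(interior) - 1e-9)
  expect_lte(prot_mass, nrow(box$protein) + 1e-9)
})

test_that("rendering is additive and protein channels cache bit-identically", {
  fx <- make_fixture(seed = 34)
  box <- make_box(fx$record, test_spec(), seed = 2)
  cm <- box$channel_map
  p1 <- ligand_pose(matrix(c(5, 5, 5), 1, 3), "CU")
  p2 <- ligand_pose(matrix(c(7, 7, 7), 1, 3), "CU")
  base <- render_grid(box, NULL)
  g1 <- render_ligand(base, box, p1)
  g2 <- render_ligand(base, box, p2)
  # moving the ligand leaves protein channels bit-identical
  pc <- seq_len(cm$n_protein)
  expect_identical(g1[, , , pc], g2[, , , pc])
  # additivity of same-channel sources: the two single-atom renders sum
  lig <- cm$n_protein + 1L
  both <- ligand_pose(rbind(c(5, 5, 5), c(7, 7, 7)), c("CU", "CU"))
  gb <- render_ligand(base, box, both)
  expect_equal(gb[, , , lig], g1[, , , lig] + g2[, , , lig],
               tolerance = 1e-12)
  expect_error(render_ligand(base, box,
                             ligand_pose(matrix(c(-1, 5, 5), 1, 3), "CU")),
               "out of box")
})
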