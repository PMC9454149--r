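# shared builders for the test suite; everything is generated in code

# a minimal hand-written PDB complex: n_protein atoms + one Cu ion
tiny_cu_pdb <- function(n_protein = 30, resolution = 1.8,
                        method = "X-RAY DIFFRACTION") {
  set.seed(99)
  xyz <- matrix(20 + runif(n_protein * 3, -5, 5), ncol = 3)
  atoms <- data.frame(
    record = "ATOM", serial = seq_len(n_protein),
    name = rep(c("N", "CA", "C", "O"), length.out = n_protein),
    altloc = " ", resname = "ALA", chain = "A",
    resseq = rep(seq_len(ceiling(n_protein / 4)), each = 4)[seq_len(n_protein)],
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1,
    element = rep(c("N", "C", "C", "O"), length.out = n_protein),
    stringsAsFactors = FALSE)
  lig <- data.frame(record = "HETATM", serial = n_protein + 1L, name = "CU",
                    altloc = " ", resname = "CU", chain = "B", resseq = 900L,
                    x = 20, y = 20, z = 20, occupancy = 1, element = "CU",
                    stringsAsFactors = FALSE)
  write_pdb(rbind(atoms, lig),
            list(method = method, resolution = resolution))
}

# a random sulfate-like pose (1 S + 4 O, regular tetrahedron, S-O 1.49 A)
random_sulfate <- function(center = c(6, 6, 6), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tet <- matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1), ncol = 3,
                byrow = TRUE) / sqrt(3)
  R <- rldock::random_rotation()
  ligand_pose(rbind(center, sweep(1.49 * tet %*% t(R), 2, center, "+")),
              c("S", "O", "O", "O", "O"))
}

# small box/env/network configuration used across tests
test_spec <- function(edge = 12, min_protein_atoms = 10) {
  box_spec(edge = edge, margin = 2, min_protein_atoms = min_protein_atoms)
}

test_net_config <- function(n_channels = 6L, variant = "single",
                            grid_dim = 12L, pool = 3L) {
  net_config(grid_dim, n_channels, variant,
             filters = c(2L, 3L, 3L), dense_units = 32L, pool = pool)
}

# independent brute-force oracle for the sulfate permutation distance:
# enumerates the 24 oxygen orderings by recursive insertion (distinct code
# path from the implementation's .permutations)
oracle_perm_rmsd <- function(a, b) {
  ea <- attr(a, "elements"); eb <- attr(b, "elements")
  sa <- unclass(a)[ea == "S", , drop = FALSE]
  sb <- unclass(b)[eb == "S", , drop = FALSE]
  oa <- unclass(a)[ea == "O", , drop = FALSE]
  ob <- unclass(b)[eb == "O", , drop = FALSE]
  insert_all <- function(x, v) {
    lapply(seq_len(length(v) + 1), function(i) append(v, x, after = i - 1))
  }
  perms <- list(integer())
  for (k in 1:4) perms <- unlist(lapply(perms, insert_all, x = k),
                                 recursive = FALSE)
  best <- Inf
  for (p in perms) {
    d2 <- sum((sa - sb)^2)
    for (i in 1:4) d2 <- d2 + sum((oa[i, ] - ob[p[i], ])^2)
    best <- min(best, sqrt(d2 / 5))
  }
  best
}
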