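#' @name voxelizer
#' @title Cubic grid boxes and Gaussian-smoothed atom densities
#'
#' @description
#' A grid box is an \code{edge x edge x edge} Angstrom cube, voxelized at
#' \code{voxel} Angstrom (default 18 and 1: an 18x18x18 grid). Each atom
#' deposits a Gaussian density over its own voxel and the 26 neighbours
#' (3x3x3 - 1), normalized to unit mass over those 27 voxels before
#' boundary clipping; per-channel sums over atoms give the
#' \code{18x18x18xN} input tensor. Box coordinates are box-frame: the cube
#' occupies \code{[0, edge)} on every axis and voxel \code{(i,j,k)} (1-based)
#' has its centre at \code{(i-0.5, j-0.5, k-0.5) * voxel}.
NULL

#' Box geometry specification
#'
#' @param edge Cube edge length in Angstrom.
#' @param voxel Voxel size in Angstrom; \code{edge} must be a multiple.
#' @param margin Minimum distance (Angstrom) from every true-pose ligand
#'   atom to every box face when sampling the box centre.
#' @param min_protein_atoms Minimum number of protein atoms that must fall
#'   inside a candidate box.
#' @param max_attempts Rejection-sampling budget for box placement.
#' @return A \code{box_spec} object.
#' @export
box_spec <- function(edge = 18, voxel = 1, margin = 2,
                     min_protein_atoms = 30, max_attempts = 200) {
  stopifnot(edge > 0, voxel > 0, abs(edge / voxel - round(edge / voxel)) < 1e-9)
  structure(list(edge = edge, voxel = voxel, margin = margin,
                 min_protein_atoms = min_protein_atoms,
                 max_attempts = max_attempts,
                 n_voxels = as.integer(round(edge / voxel))),
            class = "box_spec")
}

#' Ligand pose
#'
#' A pose is the full rigid placement of the ligand: an n x 3 matrix of
#' box-frame coordinates with the atom elements attached.
#'
#' @param coords n x 3 numeric matrix (Angstrom).
#' @param elements Character vector of n element symbols.
#' @return A \code{ligand_pose} (matrix with attributes).
#' @export
ligand_pose <- function(coords, elements) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) == length(elements))
  structure(coords, elements = toupper(elements), class = c("ligand_pose", "matrix"))
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat("<ligand_pose> ", nrow(x), " atom(s): ",
      paste(attr(x, "elements"), collapse = " "), "\n", sep = "")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

pose_elements <- function(pose) attr(pose, "elements")

# carry pose attributes across coordinate updates
pose_update <- function(pose, coords) {
  ligand_pose(coords, pose_elements(pose))
}

#' Uniform random rotation matrix
#'
#' Drawn uniformly from SO(3) via a random unit quaternion (Shoemake).
#' @param n Ignored; present for API symmetry.
#' @return 3 x 3 orthonormal rotation matrix (det +1).
#' @export
random_rotation <- function(n = 1) {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  quat_to_matrix(q)
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# rotation by angle (radians) about a coordinate axis (1, 2 or 3)
axis_rotation <- function(axis, angle) {
  c_ <- cos(angle); s_ <- sin(angle)
  R <- diag(3)
  i <- c(2, 3, 1)[axis]; j <- c(3, 1, 2)[axis]
  R[i, i] <- c_; R[j, j] <- c_; R[i, j] <- -s_; R[j, i] <- s_
  R
}

#' Gaussian density splat of one atom
#'
#' Evaluates the smoothing kernel
#' \deqn{(2\pi r^2)^{-3/2} \exp\{-|c - p|^2 / (2 r^2)\}}
#' (with \eqn{r} the atom's Van der Waals radius, \eqn{p} the atom position
#' and \eqn{c} a voxel centre) at the atom's voxel and its 26 neighbours,
#' then normalizes the 27 weights to sum to one. Neighbours falling outside
#' the grid are dropped \emph{after} normalization, so boundary atoms lose
#' mass.
#'
#' @param coord Length-3 atom position, box frame (Angstrom).
#' @param r Van der Waals radius (Angstrom); must be positive.
#' @param spec A \code{box_spec}.
#' @return data.frame with columns ix, iy, iz (1-based voxel indices,
#'   in-grid only) and w (weights; sum to 1 before boundary clipping).
#' @export
gaussian_splat <- function(coord, r, spec = box_spec()) {
  stopifnot(r > 0)
  h <- spec$voxel; nv <- spec$n_voxels
  v0 <- floor(coord / h)  # 0-based index of the atom's own voxel
  if (any(v0 < 0) || any(v0 >= nv)) stop("atom outside grid")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  vox <- sweep(off, 2, v0, "+")                 # 0-based neighbour indices
  centers <- (vox + 0.5) * h
  d2 <- rowSums(sweep(centers, 2, coord, "-")^2)
  w <- (2 * pi * r^2)^(-1.5) * exp(-d2 / (2 * r^2))
  w <- w / sum(w)
  keep <- vox[, 1] >= 0 & vox[, 1] < nv & vox[, 2] >= 0 & vox[, 2] < nv &
          vox[, 3] >= 0 & vox[, 3] < nv
  data.frame(ix = vox[keep, 1] + 1L, iy = vox[keep, 2] + 1L,
             iz = vox[keep, 3] + 1L, w = w[keep])
}

#' Build a grid box around the true ligand site
#'
#' Applies a uniformly random rotation to the whole complex (about the
#' ligand centroid), then samples a box centre uniformly over the set of
#' centres that keep every true-pose ligand atom at least \code{margin}
#' from all faces, rejecting candidates with fewer than
#' \code{min_protein_atoms} protein atoms inside. Protein atoms outside
#' the box are discarded. All coordinates in the returned box are
#' box-frame (cube = \code{[0, edge)^3}).
#'
#' @param record An eligible \code{complex_record}.
#' @param spec A \code{box_spec}.
#' @param seed Integer seed; the same (record, spec, seed) triple always
#'   yields bit-identical geometry.
#' @return A \code{grid_box}: list with \code{spec}, \code{channel_map},
#'   \code{rotation}, \code{origin} (world coordinates of box corner),
#'   \code{protein} (data.frame of in-box protein atoms, box frame),
#'   \code{true_pose} (a \code{ligand_pose}) and \code{seed}.
#' @export
make_box <- function(record, spec = box_spec(), seed = 1L) {
  with_seed_(seed, {
    P <- as.matrix(record$protein[, c("x", "y", "z"), drop = FALSE])
    L <- as.matrix(record$ligand[, c("x", "y", "z"), drop = FALSE])
    ctr <- colMeans(L)
    R <- random_rotation()
    Pr <- if (nrow(P)) sweep(sweep(P, 2, ctr) %*% t(R), 2, ctr, "+") else P
    Lr <- sweep(sweep(L, 2, ctr) %*% t(R), 2, ctr, "+")

    half <- spec$edge / 2
    lo <- apply(Lr, 2, max) - half + spec$margin
    hi <- apply(Lr, 2, min) + half - spec$margin
    if (any(lo > hi)) stop("box placement failed: ligand too large for margin")
    for (attempt in seq_len(spec$max_attempts)) {
      center <- lo + runif(3) * (hi - lo)
      origin <- center - half
      if (nrow(Pr)) {
        inside <- Pr[, 1] >= origin[1] & Pr[, 1] < origin[1] + spec$edge &
                  Pr[, 2] >= origin[2] & Pr[, 2] < origin[2] + spec$edge &
                  Pr[, 3] >= origin[3] & Pr[, 3] < origin[3] + spec$edge
      } else inside <- logical(0)
      if (sum(inside) >= spec$min_protein_atoms) {
        prot <- record$protein[inside, , drop = FALSE]
        pc <- sweep(Pr[inside, , drop = FALSE], 2, origin)
        prot$x <- pc[, 1]; prot$y <- pc[, 2]; prot$z <- pc[, 3]
        true_pose <- ligand_pose(sweep(Lr, 2, origin), record$ligand$element)
        return(structure(list(spec = spec, channel_map = record$channel_map,
                              rotation = R, rot_center = ctr,
                              origin = origin, protein = prot,
                              true_pose = true_pose, seed = as.integer(seed)),
                         class = "grid_box"))
      }
    }
    stop("box placement failed: min_protein_atoms not met after ",
         spec$max_attempts, " attempts")
  })
}

#' Random start pose inside a box
#'
#' Uniformly random position (and, for multi-atom ligands, uniformly
#' random orientation) of the rigid ligand, rejection-sampled until every
#' atom lies strictly inside the box.
#'
#' @param box A \code{grid_box}.
#' @param seed Integer seed.
#' @return A \code{ligand_pose}.
#' @export
random_start_pose <- function(box, seed = 1L) {
  spec <- box$spec
  tp <- unclass(box$true_pose)
  centered <- sweep(tp, 2, colMeans(tp))
  with_seed_(seed, {
    repeat {
      R <- if (nrow(tp) > 1) random_rotation() else diag(3)
      pos <- runif(3) * spec$edge
      cand <- sweep(centered %*% t(R), 2, pos, "+")
      if (all(cand > 0) && all(cand < spec$edge)) {
        return(pose_update(box$true_pose, cand))
      }
    }
  })
}

#' Render per-channel densities
#'
#' Sums the Gaussian splats of all atoms into their channels. Protein
#' channels depend only on the box's protein atoms; ligand channels only on
#' the supplied pose, which is what makes incremental re-rendering of a
#' moved ligand cheap (see \code{\link{render_ligand}}).
#'
#' @param box A \code{grid_box}.
#' @param pose A \code{ligand_pose}, or NULL to render protein channels only.
#' @return 4-D array \code{(nx, ny, nz, n_channels)} of non-negative
#'   densities.
#' @export
render_grid <- function(box, pose = NULL) {
  cm <- box$channel_map
  nv <- box$spec$n_voxels
  g <- array(0, dim = c(nv, nv, nv, cm$n_channels))
  if (nrow(box$protein)) {
    g <- splat_into(g, as.matrix(box$protein[, c("x", "y", "z")]),
                    box$protein$vdw, box$protein$channel, box$spec)
  }
  if (!is.null(pose)) g <- render_ligand(g, box, pose)
  g
}

#' Overwrite the ligand channels of a rendered grid
#'
#' @param grid 4-D density array from \code{\link{render_grid}} (any ligand
#'   content in it is zeroed first).
#' @param box The \code{grid_box} the grid was rendered from.
#' @param pose A \code{ligand_pose}; every atom must lie inside the box.
#' @return The updated 4-D array.
#' @export
render_ligand <- function(grid, box, pose) {
  cm <- box$channel_map
  co <- unclass(pose)
  if (any(co <= 0) || any(co >= box$spec$edge)) stop("pose atom out of box")
  el <- pose_elements(pose)
  ch <- ligand_channel(cm, el)
  grid[, , , (cm$n_protein + 1):cm$n_channels] <- 0
  splat_into(grid, co, vdw_radius(el), ch, box$spec)
}

# accumulate the splats of a set of atoms into a density array
splat_into <- function(grid, coords, vdw, channel, spec) {
  nv <- spec$n_voxels
  for (i in seq_len(nrow(coords))) {
    s <- gaussian_splat(coords[i, ], vdw[i], spec)
    idx <- cbind(s$ix, s$iy, s$iz, channel[i])
    grid[idx] <- grid[idx] + s$w
  }
  grid
}
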