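#' @name synthetic_fixtures
#' @title Deterministic synthetic protein-ligand complexes
#'
#' @description
#' Toy complexes for desk-scale testing and training: a protein-like heavy
#' atom cloud (elements C/N/O/S, minimum inter-atom spacing 1.5 Angstrom,
#' mimicking real heavy-atom packing) surrounding a designated true ligand
#' pose. Pocket geometries: \code{"empty"} (no protein atoms),
#' \code{"shell"} (atoms on a spherical shell around the site),
#' \code{"cleft"} (a shell with an approach channel carved out). Records
#' carry synthetic X-ray metadata (resolution 1.5 Angstrom) so the
#' standard dataset filters pass. Output is standard PDB text that
#' round-trips through \code{\link{parse_complex}}.
NULL

# regular tetrahedron vertices, unit circumradius
.TETRA <- matrix(c(1, 1, 1,  1, -1, -1,  -1, 1, -1,  -1, -1, 1),
                 ncol = 3, byrow = TRUE) / sqrt(3)
.SO4_BOND <- 1.49  # S-O bond length, Angstrom

#' Generate one synthetic complex
#'
#' @param n_protein_atoms Number of protein-like atoms (ignored for
#'   \code{pocket = "empty"}).
#' @param pocket \code{"shell"}, \code{"cleft"} or \code{"empty"}.
#' @param ligand \code{"single_atom"} (a copper ion) or
#'   \code{"sulfate_like"} (1 S + 4 O in a regular tetrahedron).
#' @param shell_radius Range (min, max) of protein-atom distances from the
#'   true site, Angstrom. The default spans the first and second
#'   coordination shells of a bound ion (contact distances ~2.8 Angstrom
#'   out to ~6.5 Angstrom), so the site sits inside its pocket the way a
#'   crystallographic ion does.
#' @param min_spacing Minimum protein inter-atom distance, Angstrom.
#' @param seed Integer seed; identical specs give byte-identical PDB text.
#' @param cm Channel map; defaults to the coarse protein scheme with the
#'   matching ligand channels.
#' @return A list with \code{record} (a \code{complex_record}),
#'   \code{pdb} (character vector of PDB lines) and \code{true_site}
#'   (the site centre, world frame).
#' @export
make_fixture <- function(n_protein_atoms = 60L,
                         pocket = c("shell", "cleft", "empty"),
                         ligand = c("single_atom", "sulfate_like"),
                         shell_radius = c(2.8, 6.5),
                         min_spacing = 1.5, seed = 1L,
                         cm = NULL) {
  pocket <- match.arg(pocket)
  ligand <- match.arg(ligand)
  if (is.null(cm)) {
    cm <- channel_map(if (ligand == "single_atom") "CU" else "SO4", "coarse")
  }
  with_seed_(seed, {
    # comfortably positive world coordinates, jittered per seed so every
    # fixture has its own true pose
    site <- 25 + runif(3, -3, 3)
    if (ligand == "single_atom") {
      lig_xyz <- matrix(site, 1, 3)
      lig_el <- "CU"; lig_name <- "CU"; lig_res <- "CU"
    } else {
      R <- random_rotation()
      lig_xyz <- rbind(site,
                       sweep(.SO4_BOND * .TETRA %*% t(R), 2, site, "+"))
      lig_el <- c("S", "O", "O", "O", "O")
      lig_name <- c("S", "O1", "O2", "O3", "O4")
      lig_res <- "SO4"
    }
    prot <- matrix(numeric(0), 0, 3)
    # (residue, atom name, element) tuples with heavy-atom frequencies
    # roughly matching a protein interior, so the full channel map sees a
    # realistic class spread (backbone, aliphatic/aromatic C, polar N/O, S)
    atom_pool <- data.frame(
      res = c("GLY", "GLY", "GLY", "GLY", "ALA", "LEU", "PHE", "ASP",
              "SER", "HIS", "LYS", "ASN", "CYS", "MET"),
      nm  = c("N",   "CA",  "C",   "O",   "CB",  "CG",  "CD1", "OD1",
              "OG",  "ND1", "NZ",  "ND2", "SG",  "SD"),
      el  = c("N",   "C",   "C",   "O",   "C",   "C",   "C",   "O",
              "O",   "N",   "N",   "N",   "S",   "S"),
      w   = c(0.11,  0.12,  0.11,  0.11,  0.10,  0.09,  0.09,  0.06,
              0.06,  0.04,  0.04,  0.03,  0.02,  0.02),
      stringsAsFactors = FALSE)
    picks <- integer(0)
    if (pocket != "empty") {
      tries <- 0L
      while (nrow(prot) < n_protein_atoms) {
        tries <- tries + 1L
        if (tries > 200L * n_protein_atoms) {
          stop("infeasible fixture geometry: cannot place protein atoms")
        }
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        if (pocket == "cleft") {
          # carve an approach channel within 35 degrees of +x
          if (acos(min(max(u[1], -1), 1)) < 35 * pi / 180) next
        }
        r <- runif(1, shell_radius[1], shell_radius[2])
        cand <- site + r * u
        if (nrow(prot) &&
            min(sqrt(rowSums(sweep(prot, 2, cand)^2))) < min_spacing) next
        if (min(sqrt(rowSums(sweep(lig_xyz, 2, cand)^2))) < 2.5) next  # vdW contact
        prot <- rbind(prot, cand)
        picks <- c(picks, sample.int(nrow(atom_pool), 1, prob = atom_pool$w))
      }
    }
    n <- nrow(prot)
    elements <- atom_pool$el[picks]
    atoms <- data.frame(
      record = c(rep("ATOM", n), rep("HETATM", nrow(lig_xyz))),
      serial = seq_len(n + nrow(lig_xyz)),
      name = c(atom_pool$nm[picks], lig_name),
      altloc = " ",
      resname = c(atom_pool$res[picks], rep(lig_res, nrow(lig_xyz))),
      chain = c(rep("A", n), rep("B", nrow(lig_xyz))),
      resseq = c(seq_len(max(n, 0)), rep(900L, nrow(lig_xyz))),
      x = c(prot[, 1], lig_xyz[, 1]),
      y = c(prot[, 2], lig_xyz[, 2]),
      z = c(prot[, 3], lig_xyz[, 3]),
      occupancy = 1.0,
      element = c(elements, lig_el),
      stringsAsFactors = FALSE
    )
    meta <- list(method = "X-RAY DIFFRACTION", resolution = 1.5)
    pdb <- write_pdb(atoms, meta)
    record <- parse_complex(pdb, lig_res, cm,
                            pdb_id = sprintf("SYN%04d", seed %% 10000))[[1]]
    # the record keeps full-precision coordinates; the PDB text (3 decimal
    # places) is only the serialization. parse_complex may reorder atoms,
    # so match rows through the serial numbers.
    if (n) {
      pi_ <- record$protein$serial
      record$protein$x <- prot[pi_, 1]; record$protein$y <- prot[pi_, 2]
      record$protein$z <- prot[pi_, 3]
    }
    li_ <- record$ligand$serial - n
    record$ligand$x <- lig_xyz[li_, 1]; record$ligand$y <- lig_xyz[li_, 2]
    record$ligand$z <- lig_xyz[li_, 3]
    list(record = record, pdb = pdb, true_site = site)
  })
}

#' Generate a suite of fixtures with a manifest
#'
#' @param n Number of fixtures.
#' @param dir Directory to write PDB files and \code{manifest.csv} into;
#'   NULL keeps everything in memory.
#' @param base_seed Fixture i uses a seed derived from this.
#' @param ... Passed to \code{\link{make_fixture}} (shared template).
#' @return List with \code{records} (list of \code{complex_record}) and
#'   \code{manifest} (data.frame: pdb_id, file, ligand_code, eligible,
#'   reasons).
#' @export
make_suite <- function(n, dir = NULL, base_seed = 1L, ...) {
  stopifnot(n >= 1)
  fixtures <- lapply(seq_len(n), function(i) {
    make_fixture(seed = derive_seed(base_seed, i), ...)
  })
  records <- lapply(fixtures, `[[`, "record")
  man <- dataset_manifest(records)
  man$file <- NA_character_
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n)) {
      f <- file.path(dir, paste0(records[[i]]$metadata$pdb_id, "_", i, ".pdb"))
      writeLines(fixtures[[i]]$pdb, f)
      man$file[i] <- f
    }
    write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(records = records, manifest = man)
}
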