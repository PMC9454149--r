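#' @name channels
#' @title Atom-type channels and Van der Waals radii
#'
#' @description
#' Every heavy atom that enters a grid box is assigned to one density
#' channel. Protein atoms use a fixed ordered set of atom-type classes
#' (21 in the full map); each distinct ligand atom type gets its own
#' additional channel, so the grid depth is \code{N = n_protein + M}.
#' The Gaussian splat width of an atom is its Van der Waals radius.
NULL

# Bondi-style Van der Waals radii in Angstrom. The width parameter r of the
# atom density splat. Elements not listed fall back to 1.70 (carbon).
.VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
  CU = 1.40, ZN = 1.39, FE = 2.05, MN = 2.05, MG = 1.73,
  `NA` = 2.27, K = 2.75, CA = 2.31, CO = 2.00, NI = 1.63
)

#' Van der Waals radius of an element
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Numeric vector of radii in Angstrom; unknown elements get the
#'   carbon radius 1.70.
#' @export
vdw_radius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# The full protein atom typing: 20 named classes plus a fallback, 21 total.
# The original encoding this mirrors is not published as a table, so the map
# is an explicit, configurable stand-in: backbone atoms, then side-chain
# classes grouped by element and chemical context.
.PROTEIN_CLASSES_FULL <- c(
  "N_backbone", "CA_backbone", "C_backbone", "O_backbone", "CB",
  "C_sp3", "C_aromatic", "C_carboxamide", "C_carboxylate", "C_guanidinium",
  "N_amide", "N_guanidinium", "N_amine", "N_imidazole", "N_indole",
  "O_amide", "O_carboxylate", "O_hydroxyl", "S_thiol", "S_thioether",
  "other"
)

.PROTEIN_CLASSES_COARSE <- c("C", "N", "O", "S", "other")

# Atom-name lookup tables for the full map. Names are PDB atom names
# (stripped); residue context disambiguates the chemically distinct cases.
.classify_protein_atom_full <- function(name, resname, element) {
  nm <- toupper(name); rs <- toupper(resname); el <- toupper(element)
  if (nm == "N")  return("N_backbone")
  if (nm == "CA" && el == "C") return("CA_backbone")
  if (nm == "C")  return("C_backbone")
  if (nm %in% c("O", "OXT")) return("O_backbone")
  if (nm == "CB") return("CB")
  if (el == "C") {
    if ((rs %in% c("PHE", "TYR") && nm %in% c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")) ||
        (rs == "TRP" && nm %in% c("CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")) ||
        (rs == "HIS" && nm %in% c("CG", "CD2", "CE1")))
      return("C_aromatic")
    if ((rs == "ASN" && nm == "CG") || (rs == "GLN" && nm == "CD"))
      return("C_carboxamide")
    if ((rs == "ASP" && nm == "CG") || (rs == "GLU" && nm == "CD"))
      return("C_carboxylate")
    if (rs == "ARG" && nm == "CZ") return("C_guanidinium")
    return("C_sp3")
  }
  if (el == "N") {
    if ((rs == "ASN" && nm == "ND2") || (rs == "GLN" && nm == "NE2")) return("N_amide")
    if (rs == "ARG" && nm %in% c("NE", "NH1", "NH2")) return("N_guanidinium")
    if (rs == "LYS" && nm == "NZ") return("N_amine")
    if (rs == "HIS" && nm %in% c("ND1", "NE2")) return("N_imidazole")
    if (rs == "TRP" && nm == "NE1") return("N_indole")
    return("other")
  }
  if (el == "O") {
    if ((rs == "ASN" && nm == "OD1") || (rs == "GLN" && nm == "OE1")) return("O_amide")
    if (rs %in% c("ASP", "GLU") && nm %in% c("OD1", "OD2", "OE1", "OE2"))
      return("O_carboxylate")
    if (nm %in% c("OG", "OG1", "OH")) return("O_hydroxyl")
    return("other")
  }
  if (el == "S") {
    if (rs == "CYS" && nm == "SG") return("S_thiol")
    if (rs == "MET" && nm == "SD") return("S_thioether")
    return("other")
  }
  "other"
}

.classify_protein_atom_coarse <- function(name, resname, element) {
  el <- toupper(element)
  if (el %in% c("C", "N", "O", "S")) el else "other"
}

#' Build a channel map
#'
#' A channel map fixes the ordered list of protein atom-type classes and the
#' ligand atom-type classes, hence the channel depth \code{N} of every grid.
#' The \code{"full"} protein scheme has exactly 21 classes (backbone N, CA,
#' C, O, CB, then side-chain element/context classes, with an \code{"other"}
#' fallback); the \code{"coarse"} scheme (5 classes, by element) exists for
#' desk-scale experiments where 21 protein channels are wasteful.
#'
#' @param ligand Ligand scheme: \code{"CU"} (one channel) or \code{"SO4"}
#'   (two channels, S and O), or a character vector of element symbols
#'   defining one channel per distinct ligand atom type.
#' @param protein \code{"full"} (21 classes) or \code{"coarse"} (5 classes).
#' @return An object of class \code{channel_map} with fields
#'   \code{protein_classes}, \code{ligand_elements}, \code{n_protein},
#'   \code{n_ligand} and total depth \code{n_channels}.
#' @examples
#' cm <- channel_map("CU")
#' cm$n_channels  # 22: 21 protein classes + the copper channel
#' @export
channel_map <- function(ligand = "CU", protein = c("full", "coarse")) {
  protein <- match.arg(protein)
  ligand_elements <- switch(toupper(ligand[1]),
    CU = "CU", SO4 = c("S", "O"), toupper(ligand))
  if (length(ligand) > 1) ligand_elements <- toupper(ligand)
  classes <- if (protein == "full") .PROTEIN_CLASSES_FULL else .PROTEIN_CLASSES_COARSE
  cm <- structure(list(
    protein_scheme = protein,
    protein_classes = classes,
    ligand_elements = ligand_elements,
    n_protein = length(classes),
    n_ligand = length(ligand_elements),
    n_channels = length(classes) + length(ligand_elements)
  ), class = "channel_map")
  if (protein == "full") stopifnot(cm$n_protein == 21L)
  cm
}

#' Assign protein atoms to channels
#'
#' @param cm A \code{channel_map}.
#' @param name,resname,element Parallel character vectors describing atoms.
#' @return Integer channel indices in \code{1..n_protein}.
#' @export
protein_channel <- function(cm, name, resname, element) {
  f <- if (cm$protein_scheme == "full") .classify_protein_atom_full
       else .classify_protein_atom_coarse
  cls <- mapply(f, name, resname, element, USE.NAMES = FALSE)
  idx <- match(cls, cm$protein_classes)
  idx[is.na(idx)] <- match("other", cm$protein_classes)
  as.integer(idx)
}

#' Assign ligand atoms to channels
#'
#' @param cm A \code{channel_map}.
#' @param element Character vector of ligand atom elements.
#' @return Integer channel indices in \code{(n_protein+1)..n_channels}.
#'   Unknown ligand elements raise an error: the map is ligand-specific.
#' @export
ligand_channel <- function(cm, element) {
  idx <- match(toupper(element), cm$ligand_elements)
  if (anyNA(idx)) {
    stop("ligand element(s) not in channel map: ",
         paste(unique(element[is.na(idx)]), collapse = ", "))
  }
  as.integer(cm$n_protein + idx)
}

#' @export
print.channel_map <- function(x, ...) {
  cat("<channel_map> ", x$n_channels, " channels (",
      x$n_protein, " protein [", x$protein_scheme, "] + ",
      x$n_ligand, " ligand: ", paste(x$ligand_elements, collapse = ","),
      ")\n", sep = "")
  invisible(x)
}
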