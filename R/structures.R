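#' @name structures_io
#' @title Protein-ligand complex records and dataset filters
#'
#' @description
#' A \code{complex_record} holds the retained protein heavy atoms, the
#' ligand atoms in their crystallographic (true) pose, and the metadata the
#' dataset filters act on. Hydrogens and waters are always excluded; every
#' retained atom carries a channel index and a Van der Waals radius.
NULL

#' Parse a protein-ligand complex from PDB text
#'
#' Extracts one record per instance of the requested het group. Hydrogens
#' and waters are dropped; alternate locations resolve to the
#' highest-occupancy conformer; every retained atom gets a channel from
#' \code{cm} and a Van der Waals radius.
#'
#' @param pdb_text PDB text (single string or character vector of lines).
#' @param ligand_code 3-letter (or shorter) het code, e.g. \code{"CU"},
#'   \code{"SO4"}.
#' @param cm A \code{channel_map}.
#' @param pdb_id Optional identifier stored in the metadata.
#' @return A list of \code{complex_record} objects, one per ligand
#'   instance, each with fields \code{protein} (data.frame with coords,
#'   element, vdw, channel), \code{ligand} (same layout; the true pose
#'   \code{s0}) and \code{metadata} (pdb_id, method, resolution, residues,
#'   ligand_code).
#' @export
parse_complex <- function(pdb_text, ligand_code, cm = channel_map("CU"),
                          pdb_id = NA_character_) {
  parsed <- read_pdb(pdb_text)
  atoms <- parsed$atoms
  if (!nrow(atoms)) stop("no atoms in PDB text")
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  atoms <- atoms[!(atoms$resname %in% .WATER_RES), , drop = FALSE]
  atoms <- .resolve_altloc(atoms)

  lig_mask <- atoms$record == "HETATM" & atoms$resname == toupper(ligand_code)
  if (!any(lig_mask)) stop("ligand not found: ", ligand_code)
  lig <- atoms[lig_mask, , drop = FALSE]
  prot <- atoms[atoms$record == "ATOM", , drop = FALSE]

  unknown <- !(toupper(prot$element) %in% names(.VDW_RADII))
  if (any(unknown)) {
    warning("unknown element(s) assigned fallback radius/channel: ",
            paste(unique(prot$element[unknown]), collapse = ", "))
  }
  prot$vdw <- vdw_radius(prot$element)
  prot$channel <- if (nrow(prot)) {
    protein_channel(cm, prot$name, prot$resname, prot$element)
  } else integer()
  lig$vdw <- vdw_radius(lig$element)
  lig$channel <- ligand_channel(cm, lig$element)

  meta <- list(pdb_id = pdb_id, method = parsed$metadata$method,
               resolution = parsed$metadata$resolution,
               residues = parsed$metadata$residues,
               ligand_code = toupper(ligand_code))
  # one record per ligand instance (chain + residue number)
  inst <- unique(paste(lig$chain, lig$resseq))
  lapply(inst, function(k) {
    li <- lig[paste(lig$chain, lig$resseq) == k, , drop = FALSE]
    structure(list(protein = prot, ligand = li, metadata = meta,
                   channel_map = cm),
              class = "complex_record")
  })
}

#' @export
print.complex_record <- function(x, ...) {
  cat("<complex_record> ", x$metadata$pdb_id %||% "?", ": ",
      nrow(x$protein), " protein atoms, ", nrow(x$ligand), " ligand atoms (",
      x$metadata$ligand_code, ")\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Dataset eligibility filter
#'
#' A record is eligible when it was determined by X-ray crystallography at
#' a resolution better than 2.0 Angstrom and contains no DNA/RNA/UNK
#' residues. All failed criteria are reported.
#'
#' @param record A \code{complex_record}.
#' @param max_resolution Resolution cutoff in Angstrom (exclusive).
#' @return A list with \code{eligible} (logical) and \code{reasons}
#'   (character vector of failed criteria, empty when eligible).
#' @export
filter_record <- function(record, max_resolution = 2.0) {
  md <- record$metadata
  reasons <- character()
  if (is.null(md$method) || is.na(md$method) ||
      !grepl("X-RAY", toupper(md$method))) {
    reasons <- c(reasons, "not X-ray")
  }
  if (is.null(md$resolution) || is.na(md$resolution)) {
    reasons <- c(reasons, "no resolution")
  } else if (md$resolution >= max_resolution) {
    reasons <- c(reasons, sprintf("resolution %.2f >= %.1f", md$resolution,
                                  max_resolution))
  }
  bad <- intersect(toupper(md$residues), c(.NUCLEIC_RES, "UNK"))
  if (length(bad)) {
    reasons <- c(reasons, paste0("DNA/RNA/UNK residues: ",
                                 paste(bad, collapse = ",")))
  }
  list(eligible = length(reasons) == 0L, reasons = reasons)
}

#' Write a complex record back to PDB text
#'
#' @param record A \code{complex_record}.
#' @param ligand_coords Optional n x 3 matrix overriding the ligand
#'   coordinates (e.g. a docked pose).
#' @return Character vector of PDB lines.
#' @export
write_complex_pdb <- function(record, ligand_coords = NULL) {
  lig <- record$ligand
  if (!is.null(ligand_coords)) {
    stopifnot(nrow(ligand_coords) == nrow(lig))
    lig$x <- ligand_coords[, 1]; lig$y <- ligand_coords[, 2]
    lig$z <- ligand_coords[, 3]
  }
  cols <- c("record", "serial", "name", "altloc", "resname", "chain",
            "resseq", "x", "y", "z", "occupancy", "element")
  atoms <- rbind(record$protein[, cols, drop = FALSE],
                 lig[, cols, drop = FALSE])
  write_pdb(atoms, record$metadata)
}

#' Build a dataset manifest
#'
#' Applies \code{\link{filter_record}} to each record and returns the
#' manifest table used by the training and evaluation drivers.
#'
#' @param records List of \code{complex_record}.
#' @return data.frame with columns pdb_id, ligand_code, n_protein_atoms,
#'   n_ligand_atoms, eligible, reasons.
#' @export
dataset_manifest <- function(records) {
  rows <- lapply(records, function(r) {
    f <- filter_record(r)
    data.frame(pdb_id = r$metadata$pdb_id %||% NA_character_,
               ligand_code = r$metadata$ligand_code,
               n_protein_atoms = nrow(r$protein),
               n_ligand_atoms = nrow(r$ligand),
               eligible = f$eligible,
               reasons = paste(f$reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
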