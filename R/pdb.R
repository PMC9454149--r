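#' @name pdb_io
#' @title Minimal fixed-column PDB reader/writer
#'
#' @description
#' Reads ATOM/HETATM records plus the header fields the dataset filters
#' need (EXPDTA, REMARK 2 RESOLUTION). Only the classic fixed-column PDB
#' layout is supported; mmCIF is out of scope.
NULL

.WATER_RES <- c("HOH", "WAT", "DOD")
.NUCLEIC_RES <- c("DA", "DC", "DG", "DT", "DI", "DU", "A", "C", "G", "U", "I", "N")

# Parse the element of an ATOM/HETATM line: columns 77-78 when present,
# otherwise inferred from the atom name (first alphabetic character,
# two-letter when the name starts in column 13).
.guess_element <- function(line, name) {
  el <- ""
  if (nchar(line) >= 78) el <- trimws(substr(line, 77, 78))
  if (el == "") {
    nm <- gsub("[^A-Za-z]", "", name)
    el <- if (nchar(nm) >= 1) substr(nm, 1, 1) else "X"
    # names like "CU"/"FE" packed left indicate two-letter elements
    if (substr(line, 13, 13) != " " && nchar(nm) >= 2 &&
        toupper(substr(nm, 1, 2)) %in% names(.VDW_RADII)) {
      el <- substr(nm, 1, 2)
    }
  }
  toupper(el)
}

#' Parse PDB text into an atom table
#'
#' @param pdb_text A single string or character vector of PDB lines.
#' @return A list with \code{atoms} (data.frame: record, serial, name,
#'   altloc, resname, chain, resseq, x, y, z, occupancy, element) and
#'   \code{metadata} (list: method, resolution, residues).
#' @export
read_pdb <- function(pdb_text) {
  lines <- if (length(pdb_text) == 1L) strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
           else pdb_text
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  al <- lines[is_atom]
  method <- NA_character_
  expdta <- lines[startsWith(lines, "EXPDTA")]
  if (length(expdta)) method <- trimws(substr(expdta[1], 11, 79))
  resolution <- NA_real_
  rem2 <- lines[startsWith(lines, "REMARK   2 RESOLUTION")]
  if (length(rem2)) {
    s <- substr(rem2[1], 23, 70)
    m <- regmatches(s, regexpr("[0-9]+\\.?[0-9]*", s))
    if (length(m)) resolution <- suppressWarnings(as.numeric(m))
  }
  if (!length(al)) {
    return(list(atoms = data.frame(), metadata = list(method = method,
                resolution = resolution, residues = character())))
  }
  name <- trimws(substr(al, 13, 16))
  atoms <- data.frame(
    record = trimws(substr(al, 1, 6)),
    serial = suppressWarnings(as.integer(substr(al, 7, 11))),
    name = name,
    altloc = substr(al, 17, 17),
    resname = trimws(substr(al, 18, 20)),
    chain = substr(al, 22, 22),
    resseq = suppressWarnings(as.integer(substr(al, 23, 26))),
    x = as.numeric(substr(al, 31, 38)),
    y = as.numeric(substr(al, 39, 46)),
    z = as.numeric(substr(al, 47, 54)),
    occupancy = suppressWarnings(as.numeric(substr(al, 55, 60))),
    element = vapply(seq_along(al), function(i) .guess_element(al[i], name[i]), ""),
    stringsAsFactors = FALSE
  )
  atoms$occupancy[is.na(atoms$occupancy)] <- 1.0
  list(atoms = atoms,
       metadata = list(method = method, resolution = resolution,
                       residues = unique(atoms$resname)))
}

# Keep the highest-occupancy alternate conformer of each atom site.
.resolve_altloc <- function(atoms) {
  if (!nrow(atoms)) return(atoms)
  key <- paste(atoms$record, atoms$chain, atoms$resseq, atoms$resname, atoms$name)
  ord <- order(key, -atoms$occupancy)
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(key[ord]), , drop = FALSE]
}

.pdb_atom_line <- function(record, serial, name, resname, chain, resseq,
                           x, y, z, occupancy, element) {
  # atom names start in column 14, except 4-char names and two-letter
  # elements (CU, FE, ...) which pack left into column 13
  nm <- if (nchar(name) >= 4 || nchar(element) == 2)
    sprintf("%-4s", name) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, " ", resname, chain, resseq, " ",
          x, y, z, occupancy, 0, toupper(element))
}

#' Write an atom table to PDB text
#'
#' @param atoms Data frame in the layout returned by \code{read_pdb}.
#' @param metadata Optional list with \code{method} and \code{resolution};
#'   written as EXPDTA / REMARK 2 header lines.
#' @return A character vector of PDB lines (ends with END).
#' @export
write_pdb <- function(atoms, metadata = NULL) {
  hdr <- character()
  if (!is.null(metadata)) {
    if (!is.null(metadata$method) && !is.na(metadata$method))
      hdr <- c(hdr, sprintf("EXPDTA    %s", metadata$method))
    if (!is.null(metadata$resolution) && !is.na(metadata$resolution))
      hdr <- c(hdr, sprintf("REMARK   2 RESOLUTION. %8.2f ANGSTROMS.",
                            metadata$resolution))
  }
  body <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    .pdb_atom_line(a$record, a$serial, a$name, a$resname, a$chain, a$resseq,
                   a$x, a$y, a$z, a$occupancy, a$element)
  }, "")
  c(hdr, body, "END")
}
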