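#' @useDynLib exposite, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats setNames
NULL

# Columns every atom table carries, in order.
.atom_cols <- c("serial", "name", "altloc", "res_name", "chain", "res_seq",
                "icode", "x", "y", "z", "occupancy", "b", "element", "uid")

.empty_atoms <- function() {
  data.frame(serial = integer(), name = character(), altloc = character(),
             res_name = character(), chain = character(), res_seq = integer(),
             icode = character(), x = numeric(), y = numeric(), z = numeric(),
             occupancy = numeric(), b = numeric(), element = character(),
             uid = character(), stringsAsFactors = FALSE)
}

#' Residue identifier string
#'
#' Residues are identified by chain, author residue number and insertion
#' code, joined as `"chain:res_seq"` or `"chain:res_seqicode"`.
#'
#' @param chain chain identifier(s).
#' @param res_seq integer residue number(s).
#' @param icode insertion code(s); `""` when absent.
#' @return character vector of residue identifiers.
#' @export
residue_uid <- function(chain, res_seq, icode = "") {
  if (length(chain) == 0) return(character())
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste0(chain, ":", res_seq, icode)
}

new_structure <- function(id, atoms, ligand = .empty_atoms()) {
  stopifnot(all(.atom_cols %in% names(atoms)))
  structure(list(id = id,
                 atoms = atoms[, .atom_cols],
                 ligand = ligand[, .atom_cols]),
            class = "exposite_structure")
}

#' @export
print.exposite_structure <- function(x, ...) {
  cat(sprintf("<exposite_structure> %s: %d residues, %d atoms, %d ligand atoms\n",
              x$id, n_residues(x), nrow(x$atoms), nrow(x$ligand)))
  invisible(x)
}

#' Residue identifiers of a structure, in order of appearance
#' @param structure an `exposite_structure`.
#' @return character vector of residue identifiers.
#' @export
residue_ids <- function(structure) unique(structure$atoms$uid)

#' Number of residues in a structure
#' @inheritParams residue_ids
#' @export
n_residues <- function(structure) length(residue_ids(structure))

#' C-alpha coordinates of a structure
#'
#' @inheritParams residue_ids
#' @return numeric matrix, one row per residue possessing a CA atom,
#'   rownames are residue identifiers; residue order preserved.
#' @export
ca_coords <- function(structure) {
  a <- structure$atoms
  ca <- a[a$name == "CA", , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$uid
  m
}

.guess_element <- function(name) {
  # strip digits and spaces; first letter is the element for heavy-atom
  # protein/ligand names (CA -> C, OD1 -> O, NZ -> N, SG -> S)
  s <- gsub("[ 0-9']", "", name)
  two <- toupper(substr(s, 1, 2))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CU", "SE"),
         two, toupper(substr(s, 1, 1)))
}

.parse_atom_lines <- function(lines) {
  n <- length(lines)
  num <- function(a, b) suppressWarnings(as.numeric(trimws(substr(lines, a, b))))
  df <- data.frame(
    serial = suppressWarnings(as.integer(trimws(substr(lines, 7, 11)))),
    name = trimws(substr(lines, 13, 16)),
    altloc = substr(lines, 17, 17),
    res_name = trimws(substr(lines, 18, 20)),
    chain = substr(lines, 22, 22),
    res_seq = suppressWarnings(as.integer(trimws(substr(lines, 23, 26)))),
    icode = substr(lines, 27, 27),
    x = num(31, 38), y = num(39, 46), z = num(47, 54),
    occupancy = num(55, 60), b = num(61, 66),
    element = trimws(substr(lines, 77, 78)),
    stringsAsFactors = FALSE)
  df$altloc[df$altloc == " "] <- ""
  df$icode[df$icode == " "] <- ""
  df$occupancy[is.na(df$occupancy)] <- 1
  df$b[is.na(df$b)] <- 0
  blank <- df$element == ""
  df$element[blank] <- .guess_element(df$name[blank])
  df$uid <- residue_uid(df$chain, df$res_seq, df$icode)
  df
}

.resolve_altloc <- function(df) {
  if (nrow(df) == 0 || all(df$altloc == "")) return(df)
  key <- paste(df$uid, df$name)
  # highest occupancy wins; ties go to the record seen first
  ord <- order(key, -df$occupancy, seq_len(nrow(df)))
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(paste(df$uid, df$name)), , drop = FALSE]
  df[order(df$serial), , drop = FALSE]
}

#' Read a structure from PDB-format text
#'
#' Parses fixed-column `ATOM`/`HETATM` records. Only the first `MODEL` of a
#' multi-model file is used. Hydrogens are dropped. Alternate locations are
#' resolved to the highest-occupancy record (ties: first seen). Non-water
#' `HETATM` atoms are collected separately as ligand atoms; waters
#' (HOH/WAT/DOD) are discarded.
#'
#' @param x path to a PDB file, or a character vector of PDB lines (a
#'   single string containing newlines is also accepted).
#' @param chain optional chain identifier; if given, only that chain's
#'   polymer atoms are kept.
#' @param id structure identifier stored on the returned object.
#' @return an `exposite_structure`: list with `id`, polymer `atoms` and
#'   `ligand` atom tables.
#' @export
read_pdb <- function(x, chain = NULL, id = "structure") {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    if (id == "structure") id <- sub("\\.(pdb|ent)$", "", basename(x))
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  # keep only the first model
  endm <- grep("^ENDMDL", lines)
  if (length(endm) > 0) lines <- lines[seq_len(endm[1] - 1)]
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  "
  is_het <- rec == "HETATM"
  if (!any(is_atom) && !any(is_het))
    stop("no parseable ATOM/HETATM records found", call. = FALSE)
  atoms <- .parse_atom_lines(lines[is_atom])
  het <- .parse_atom_lines(lines[is_het])
  # hydrogens out
  atoms <- atoms[!atoms$element %in% c("H", "D"), , drop = FALSE]
  het <- het[!het$element %in% c("H", "D"), , drop = FALSE]
  # waters never count as ligand
  het <- het[!het$res_name %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  if (!is.null(chain)) {
    if (!chain %in% atoms$chain)
      stop(sprintf("chain '%s' not present in structure", chain), call. = FALSE)
    atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  }
  atoms <- .resolve_altloc(atoms)
  het <- .resolve_altloc(het)
  new_structure(id, atoms, het)
}

.format_atom_line <- function(a, record = "ATOM  ") {
  name <- a$name
  name <- ifelse(nchar(name) < 4, paste0(" ", name), name)
  sprintf("%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, a$serial, name, " ", a$res_name,
          ifelse(a$chain == "", " ", a$chain), a$res_seq,
          ifelse(a$icode == "", " ", a$icode),
          a$x, a$y, a$z, a$occupancy, a$b, a$element)
}

#' Write a structure as PDB-format text
#'
#' Round-trip safe with [read_pdb()]: residue identities, atom names and
#' coordinates survive (coordinates to 3 decimals). An optional per-residue
#' scalar is written into the B-factor column of every atom of that residue,
#' clipped to `[0, 999.99]` — convenient for colouring structures by
#' per-residue |dSAS|.
#'
#' @param structure an `exposite_structure`.
#' @param per_residue_scalar optional named numeric vector (names are
#'   residue identifiers) written into the B-factor column.
#' @param file optional path; if given the text is also written there.
#' @return character scalar of PDB text, invisibly if `file` is given.
#' @export
write_pdb <- function(structure, per_residue_scalar = NULL, file = NULL) {
  a <- structure$atoms
  if (nrow(a) == 0) stop("structure has no atoms", call. = FALSE)
  if (!is.null(per_residue_scalar)) {
    v <- per_residue_scalar[a$uid]
    v[is.na(v)] <- 0
    a$b <- pmin(pmax(v, 0), 999.99)
  }
  lines <- .format_atom_line(a, "ATOM  ")
  if (nrow(structure$ligand) > 0)
    lines <- c(lines, .format_atom_line(structure$ligand, "HETATM"))
  txt <- paste0(paste(c(lines, "END"), collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Centroid of selected C-alpha atoms
#'
#' The unweighted mean of the C-alpha coordinates of the selected residues.
#' Both the predicted site (centroid of exposure-flagged residues) and the
#' observed site (centroid of annotated catalytic residues) are defined
#' this way.
#'
#' @param structure an `exposite_structure`.
#' @param residues character vector of residue identifiers
#'   (see [residue_uid()]).
#' @return numeric length-3 coordinate (Angstrom).
#' @export
ca_centroid <- function(structure, residues) {
  if (length(residues) == 0) stop("empty residue selection", call. = FALSE)
  ca <- ca_coords(structure)
  missing <- setdiff(residues, rownames(ca))
  if (length(missing) > 0)
    stop("residues lack a CA atom: ", paste(missing, collapse = ", "),
         call. = FALSE)
  colMeans(ca[residues, , drop = FALSE])
}

#' Molecular centroid (mean of all C-alpha atoms)
#'
#' The reference point of the EnSite-style baseline, which picks the pocket
#' nearest the molecular centroid.
#'
#' @inheritParams ca_centroid
#' @return numeric length-3 coordinate (Angstrom).
#' @export
molecular_centroid <- function(structure) {
  ca <- ca_coords(structure)
  if (nrow(ca) == 0) stop("structure has no CA atoms", call. = FALSE)
  colMeans(ca)
}

#' Read a residue-list evaluation file
#'
#' Plain text, one residue per line as `chain res_seq [icode]`; `#` starts
#' a comment.
#'
#' @param path file path.
#' @return character vector of residue identifiers.
#' @export
read_residue_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(character())
  parts <- strsplit(lines, "[[:space:]]+")
  vapply(parts, function(p) {
    if (length(p) < 2) stop("malformed residue-list line: ", paste(p, collapse = " "),
                            call. = FALSE)
    residue_uid(p[1], as.integer(p[2]), if (length(p) >= 3) p[3] else "")
  }, character(1))
}
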