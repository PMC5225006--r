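# Shrake-Rupley solvent-accessible surface area and the per-residue
# exposure change between a mode's two extreme conformers.

#' Van der Waals radii table
#'
#' Compact per-element radii for heavy atoms, plus the probe radius. The
#' exposure-change signal |dSAS| is robust to the exact radii: a difference
#' of areas cancels calculator-specific offsets.
#'
#' @param probe probe radius in Angstrom (water, 1.4).
#' @param default radius used for elements not in the table.
#' @return a `radii_table` list.
#' @export
radii_table <- function(probe = 1.4, default = 1.70) {
  structure(list(radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80),
                 default = default, probe = probe),
            class = "radii_table")
}

.atom_radii <- function(elements, radii) {
  r <- radii$radii[elements]
  r[is.na(r)] <- radii$default
  unname(r)
}

#' Deterministic unit-sphere point lattice (golden-section spiral)
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Shrake-Rupley SASA for an arbitrary atom set
#'
#' Low-level routine: per-atom accessible area from a deterministic
#' spherical point lattice. Exposed fraction of test points times the
#' expanded-sphere area `4 pi (r + probe)^2`.
#'
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param radii numeric vector of per-atom vdW radii.
#' @param probe probe radius (Angstrom).
#' @param n_sphere_points number of lattice points per atom (>= 24).
#' @return numeric vector of per-atom areas (Angstrom^2).
#' @export
sasa_atoms <- function(xyz, radii, probe = 1.4, n_sphere_points = 960) {
  stopifnot(n_sphere_points >= 24, nrow(xyz) == length(radii))
  sasa_kernel(as.matrix(xyz), as.numeric(radii), probe,
              sphere_points(n_sphere_points))
}

#' Per-residue solvent-accessible surface area of a structure
#'
#' Computes per-atom Shrake-Rupley areas over the polymer heavy atoms and
#' aggregates them per residue (sum over the residue's atoms, DSSP-like
#' residue accessibility).
#'
#' @param structure an `exposite_structure`.
#' @param radii a [radii_table()].
#' @param n_sphere_points test points per atom (default 960).
#' @return a `sas_profile`: named per-residue areas (`residue_area`),
#'   per-atom areas (`atom_area`), and `n_sphere_points`.
#' @export
shrake_rupley <- function(structure, radii = radii_table(),
                          n_sphere_points = 960) {
  a <- structure$atoms
  if (nrow(a) == 0) stop("structure has no atoms", call. = FALSE)
  r <- .atom_radii(a$element, radii)
  atom_area <- sasa_atoms(as.matrix(a[, c("x", "y", "z")]), r,
                          radii$probe, n_sphere_points)
  res_area <- tapply(atom_area, factor(a$uid, levels = unique(a$uid)), sum)
  structure(list(residue_area = setNames(as.numeric(res_area), names(res_area)),
                 atom_area = atom_area,
                 n_sphere_points = n_sphere_points),
            class = "sas_profile")
}

#' Per-residue |dSAS| between two conformers
#'
#' The absolute per-residue SASA difference between a mode's two extreme
#' conformers — the exposure-change signal used for flagging residues.
#'
#' @param profile_plus,profile_minus `sas_profile`s over the same residues.
#' @param mode_index 1-based mode index recorded on the result.
#' @return a `dsas_profile`: named per-residue `value` (Angstrom^2) and
#'   `mode_index`.
#' @export
delta_sas <- function(profile_plus, profile_minus, mode_index = NA_integer_) {
  rp <- profile_plus$residue_area
  rm <- profile_minus$residue_area
  if (length(rp) != length(rm) || !all(names(rp) == names(rm)))
    stop("conformer profiles cover different residue sets", call. = FALSE)
  structure(list(value = abs(rp - rm), mode_index = mode_index),
            class = "dsas_profile")
}

#' Write per-mode SASA and |dSAS| values as TSV
#'
#' @param profiles list of `dsas_profile`s.
#' @param file output path.
#' @export
write_dsas_tsv <- function(profiles, file) {
  rows <- do.call(rbind, lapply(profiles, function(p)
    data.frame(residue = names(p$value), mode = p$mode_index,
               dsas = as.numeric(p$value), stringsAsFactors = FALSE)))
  utils::write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
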