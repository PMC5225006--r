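# LIGSITE-style grid pocket detection: label a grid protein/solvent, scan
# for protein-solvent-protein (PSP) events along 7 directions, cluster
# buried solvent cells into pockets.

#' Build a labelled grid around a structure
#'
#' Cells whose centre lies within (vdW radius + 1.4 Angstrom) of any heavy
#' atom are labelled protein; all others start as solvent. The grid extends
#' `margin` beyond the atom bounding box, guaranteeing a solvent shell
#' around the molecule.
#'
#' @param structure an `exposite_structure`.
#' @param spacing grid spacing in Angstrom (default 1.0).
#' @param margin bounding-box margin in Angstrom (default 4.0, larger than
#'   the probe diameter).
#' @param radii a [radii_table()]; its probe inflates the atom radii.
#' @return a `pocket_grid`: `origin`, `spacing`, `dims`, integer `label`
#'   vector (0 solvent, 1 protein, 2 pocket) in x-fastest order.
#' @export
build_grid <- function(structure, spacing = 1.0, margin = 4.0,
                       radii = radii_table()) {
  a <- structure$atoms
  if (nrow(a) == 0) stop("structure has no atoms", call. = FALSE)
  stopifnot(spacing > 0, margin >= 2 * radii$probe)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  r <- .atom_radii(a$element, radii) + radii$probe
  origin <- apply(xyz, 2, min) - margin
  upper <- apply(xyz, 2, max) + margin
  dims <- as.integer(floor((upper - origin) / spacing)) + 1L
  lab <- grid_mark_protein(dims, origin, spacing, xyz, r)
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 label = lab),
            class = "pocket_grid")
}

#' @export
print.pocket_grid <- function(x, ...) {
  cat(sprintf("<pocket_grid> %d x %d x %d cells, spacing %.2f A (%d protein, %d pocket)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              sum(x$label == 1), sum(x$label == 2)))
  invisible(x)
}

#' Protein-solvent-protein scan
#'
#' Relabels a solvent cell as pocket when, in at least `min_psp` of the 7
#' scan directions (the 3 axes and the 4 cube diagonals), the line through
#' the cell hits protein on both sides — the cell is buried between
#' protein walls.
#'
#' @param grid a `pocket_grid` from [build_grid()].
#' @param min_psp minimum number of PSP directions (default 3 of 7).
#' @return the grid with pocket cells labelled 2.
#' @export
psp_scan <- function(grid, min_psp = 3) {
  stopifnot(inherits(grid, "pocket_grid"), min_psp >= 1, min_psp <= 7)
  grid$label <- psp_scan_kernel(grid$label, grid$dims, as.integer(min_psp))
  grid
}

.cell_centers <- function(grid, idx) {
  # idx: 1-based linear indices into the label vector (x fastest)
  nx <- grid$dims[1]; ny <- grid$dims[2]
  i0 <- idx - 1L
  i <- i0 %% nx
  j <- (i0 %/% nx) %% ny
  k <- i0 %/% (nx * ny)
  cbind(grid$origin[1] + i * grid$spacing,
        grid$origin[2] + j * grid$spacing,
        grid$origin[3] + k * grid$spacing)
}

#' Cluster pocket cells into pockets
#'
#' Face-connected (6-neighbour) components of pocket-labelled cells. Each
#' pocket carries its cell set, centre (unweighted mean of cell centres)
#' and volume (`cells x spacing^3`). Pockets are sorted by volume
#' descending; ties are broken by the distance of the pocket centre to
#' `ref_point` (closer first), then lexicographically by centre.
#'
#' @param grid a `pocket_grid` after [psp_scan()].
#' @param ref_point tie-break reference, typically the molecular centroid;
#'   defaults to the mean of protein cell centres.
#' @return list of `pocket` objects (fields `cells`, `center`, `volume`,
#'   `n_cells`, `rank_by_size`).
#' @export
cluster_pockets <- function(grid, ref_point = NULL) {
  stopifnot(inherits(grid, "pocket_grid"))
  comp <- pocket_components(grid$label, grid$dims)
  idx <- which(comp > 0)
  if (length(idx) == 0) return(list())
  if (is.null(ref_point)) {
    prot <- which(grid$label == 1)
    ref_point <- colMeans(.cell_centers(grid, prot))
  }
  ids <- comp[idx]
  pockets <- lapply(split(idx, ids), function(cells) {
    centers <- .cell_centers(grid, cells)
    center <- colMeans(centers)
    list(cells = cells, center = center,
         volume = length(cells) * grid$spacing^3,
         n_cells = length(cells))
  })
  vol <- vapply(pockets, `[[`, numeric(1), "volume")
  d <- vapply(pockets, function(p) sqrt(sum((p$center - ref_point)^2)),
              numeric(1))
  cx <- vapply(pockets, function(p) p$center[1], numeric(1))
  cy <- vapply(pockets, function(p) p$center[2], numeric(1))
  cz <- vapply(pockets, function(p) p$center[3], numeric(1))
  ord <- order(-vol, d, cx, cy, cz)
  pockets <- unname(pockets[ord])
  for (i in seq_along(pockets)) {
    pockets[[i]]$rank_by_size <- i
    class(pockets[[i]]) <- "pocket"
  }
  pockets
}

#' @export
print.pocket <- function(x, ...) {
  cat(sprintf("<pocket> rank %d: %d cells, %.1f A^3, center (%.1f, %.1f, %.1f)\n",
              x$rank_by_size, x$n_cells, x$volume,
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Drop tiny pockets and keep the largest few
#'
#' Pockets smaller than `min_volume` (default 7 Angstrom^3) are too small
#' to accommodate a ligand and are discarded; at most `keep` (default 10)
#' of the largest remaining pockets are returned.
#'
#' @param pockets list of pockets sorted by volume (from
#'   [cluster_pockets()]).
#' @param min_volume volume floor in Angstrom^3.
#' @param keep maximum number of pockets returned.
#' @return filtered, truncated pocket list.
#' @export
filter_and_truncate <- function(pockets, min_volume = 7.0, keep = 10L) {
  vol <- vapply(pockets, `[[`, numeric(1), "volume")
  pockets <- pockets[vol >= min_volume]
  utils::head(pockets, keep)
}

#' Detect pockets of a structure in one call
#'
#' Convenience wrapper: [build_grid()], [psp_scan()], [cluster_pockets()],
#' [filter_and_truncate()].
#'
#' @inheritParams build_grid
#' @inheritParams psp_scan
#' @inheritParams filter_and_truncate
#' @param ref_point tie-break reference passed to [cluster_pockets()];
#'   defaults to the molecular centroid when the structure has CA atoms.
#' @return list of pockets.
#' @export
find_pockets <- function(structure, spacing = 1.0, margin = 4.0,
                         min_psp = 3, min_volume = 7.0, keep = 10L,
                         radii = radii_table(), ref_point = NULL) {
  if (is.null(ref_point) && any(structure$atoms$name == "CA"))
    ref_point <- molecular_centroid(structure)
  g <- psp_scan(build_grid(structure, spacing, margin, radii), min_psp)
  filter_and_truncate(cluster_pockets(g, ref_point), min_volume, keep)
}

#' Export pocket centres as pseudo-atom PDB text
#'
#' One HETATM per pocket centre, B-factor carrying the pocket volume.
#'
#' @param pockets list of pockets.
#' @param file optional output path.
#' @return PDB text (invisibly when `file` is given).
#' @export
write_pocket_pdb <- function(pockets, file = NULL) {
  lines <- vapply(seq_along(pockets), function(i) {
    p <- pockets[[i]]
    sprintf("HETATM%5d  O   POK %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, "P", i, p$center[1], p$center[2], p$center[3], 1.0,
            min(p$volume, 999.99), "O")
  }, character(1))
  txt <- paste0(paste(c(lines, "END"), collapse = "\n"), "\n")
  if (!is.null(file)) { writeLines(txt, file, sep = ""); return(invisible(txt)) }
  txt
}
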