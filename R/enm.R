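# Tirion elastic-network normal modes on the C-alpha network.

#' Build a C-alpha elastic network
#'
#' Uniform-spring Tirion network: every pair of C-alpha nodes closer than
#' `cutoff` is connected by a harmonic spring of stiffness `gamma`. No
#' energy minimisation is involved; the input coordinates are the minimum
#' by construction.
#'
#' @param x an `exposite_structure`, or an N x 3 coordinate matrix.
#' @param cutoff contact cutoff in Angstrom (default 12).
#' @param gamma uniform spring constant (energy / Angstrom^2).
#' @return an `elastic_network`: list with `coords`, `cutoff`, `gamma`.
#' @export
elastic_network <- function(x, cutoff = 12, gamma = 1) {
  stopifnot(cutoff > 0, gamma > 0)
  coords <- if (inherits(x, "exposite_structure")) ca_coords(x) else as.matrix(x)
  if (nrow(coords) < 2)
    stop("need at least 2 CA nodes for an elastic network", call. = FALSE)
  structure(list(coords = coords, cutoff = cutoff, gamma = gamma),
            class = "elastic_network")
}

.contact_pairs <- function(coords, cutoff) {
  d <- as.matrix(stats::dist(coords))
  adj <- d < cutoff & upper.tri(d)
  which(adj, arr.ind = TRUE)
}

.connected_components <- function(n, pairs) {
  # union-find over contact pairs
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Build the elastic-network Hessian
#'
#' Standard anisotropic-network form: for each contacting pair (i, j) the
#' off-diagonal 3x3 block is `-gamma * d d^T` with `d` the unit inter-node
#' vector; diagonal blocks are minus the sum of the row's off-diagonal
#' blocks. The result is symmetric positive semi-definite with a 6-dim
#' rigid-body null space for any connected, non-collinear network.
#'
#' @param network an [elastic_network()].
#' @return dense symmetric 3N x 3N matrix.
#' @export
build_hessian <- function(network) {
  stopifnot(inherits(network, "elastic_network"))
  coords <- network$coords
  n <- nrow(coords)
  pairs <- .contact_pairs(coords, network$cutoff)
  comp <- .connected_components(n, pairs)
  if (max(comp) > 1)
    stop(sprintf("elastic network is disconnected (%d components); increase the cutoff",
                 max(comp)), call. = FALSE)
  hessian_kernel(coords, matrix(as.integer(pairs), ncol = 2), network$gamma)
}

#' Diagonalise the Hessian and drop the rigid-body modes
#'
#' Removes the near-zero rigid-body eigenpairs (eigenvalue below
#' `1e-8 x` the largest eigenvalue; exactly 6 of them for any connected,
#' non-collinear network, 5 for a collinear one) and returns the next
#' `n_modes` lowest-frequency eigenpairs in ascending eigenvalue order.
#' More than 6 near-zero eigenvalues signals a disconnected network and
#' is an error.
#'
#' @param hessian symmetric 3N x 3N matrix from [build_hessian()].
#' @param n_modes number of non-trivial modes to keep (default 10).
#' @return an `exposite_modes`: `values` (ascending), `vectors`
#'   (3N x K, orthonormal columns), `n_trivial_removed` (6 in the
#'   ordinary case), `truncated` flag (TRUE when fewer than `n_modes`
#'   non-trivial modes exist).
#' @export
compute_modes <- function(hessian, n_modes = 10) {
  stopifnot(n_modes >= 1)
  e <- eigen(hessian, symmetric = TRUE)
  values <- rev(e$values)
  vectors <- e$vectors[, rev(seq_along(e$values)), drop = FALSE]
  tol <- 1e-8 * max(values)
  n_zero <- sum(values < tol)
  if (n_zero > 6)
    stop(sprintf("degenerate network: %d near-zero modes (expected 6); network is disconnected",
                 n_zero), call. = FALSE)
  keep <- seq(n_zero + 1, min(n_zero + n_modes, length(values)))
  truncated <- length(keep) < n_modes
  if (truncated)
    warning(sprintf("only %d non-trivial modes available (requested %d)",
                    length(keep), n_modes), call. = FALSE)
  structure(list(values = values[keep],
                 vectors = vectors[, keep, drop = FALSE],
                 n_trivial_removed = as.integer(n_zero),
                 truncated = truncated),
            class = "exposite_modes")
}

#' @export
print.exposite_modes <- function(x, ...) {
  cat(sprintf("<exposite_modes> %d non-trivial modes, eigenvalues %.4g .. %.4g\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

.shift_structure <- function(structure, disp) {
  # disp: N x 3 per-residue displacement, rows aligned with CA residue order
  s <- structure
  idx <- match(s$atoms$uid, rownames(disp))
  s$atoms$x <- s$atoms$x + disp[idx, 1]
  s$atoms$y <- s$atoms$y + disp[idx, 2]
  s$atoms$z <- s$atoms$z + disp[idx, 3]
  s
}

#' Generate the two opposite-extreme conformers of a mode
#'
#' Displaces the structure along one normal mode in both directions. Each
#' residue moves rigidly: the mode's per-node 3-vector is applied to every
#' atom of that residue. The overall scale is chosen so that the C-alpha
#' RMSD between the two extreme conformers equals `amplitude` — a
#' size-independent, physically interpretable deformation measure. The
#' midpoint of the pair reproduces the input coordinates exactly.
#'
#' @param structure an `exposite_structure` whose CA set defined the network.
#' @param modes an `exposite_modes` from [compute_modes()].
#' @param mode_index 1-based index among the retained non-trivial modes.
#' @param amplitude target inter-extreme C-alpha RMSD in Angstrom.
#' @return a `conformer_pair`: `plus`, `minus` (structures), `mode_index`,
#'   `amplitude`.
#' @export
generate_extremes <- function(structure, modes, mode_index, amplitude = 2) {
  stopifnot(inherits(modes, "exposite_modes"), amplitude > 0)
  if (mode_index < 1 || mode_index > length(modes$values))
    stop(sprintf("mode_index %d out of range (1..%d)", mode_index,
                 length(modes$values)), call. = FALSE)
  ca <- ca_coords(structure)
  n <- nrow(ca)
  v <- matrix(modes$vectors[, mode_index], ncol = 3, byrow = TRUE)
  rownames(v) <- rownames(ca)
  # unit eigenvector: RMSD(plus, minus) = 2 s sqrt(sum(v^2) / n) = 2 s / sqrt(n)
  s <- amplitude * sqrt(n) / 2
  structure(list(plus = .shift_structure(structure, s * v),
                 minus = .shift_structure(structure, -s * v),
                 mode_index = mode_index,
                 amplitude = amplitude),
            class = "conformer_pair")
}

#' Inter-extreme C-alpha RMSD of a conformer pair
#' @param pair a `conformer_pair`.
#' @return RMSD in Angstrom.
#' @export
pair_rmsd <- function(pair) {
  d <- ca_coords(pair$plus) - ca_coords(pair$minus)
  sqrt(mean(rowSums(d^2)))
}

#' Export a conformer pair as a 2-model PDB file
#' @param pair a `conformer_pair`.
#' @param file output path.
#' @export
write_conformer_pair <- function(pair, file) {
  body <- function(s, k) c(sprintf("MODEL %8d", k),
                           sub("\nEND\n$", "\n", write_pdb(s)),
                           "ENDMDL")
  writeLines(c(body(pair$plus, 1), body(pair$minus, 2), "END"), file)
  invisible(file)
}
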