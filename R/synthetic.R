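# Deterministic synthetic fixtures with built-in ground truth: a two-domain
# hinge with a known cleft, a slab with a carved well, and a rigid helix.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.atoms_from_coords <- function(ca, cb = NULL, cg = NULL, chain = "A",
                               res_name = "ALA") {
  # ca: n x 3; cb/cg: n x 3 with NA rows for residues lacking that atom
  n <- nrow(ca)
  rows <- list()
  serial <- 0L
  add <- function(name, p, i) {
    serial <<- serial + 1L
    rows[[length(rows) + 1]] <<- data.frame(
      serial = serial, name = name, altloc = "", res_name = res_name,
      chain = chain, res_seq = i, icode = "",
      x = p[1], y = p[2], z = p[3],
      occupancy = 1, b = 0, element = "C", stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    add("CA", ca[i, ], i)
    if (!is.null(cb) && !is.na(cb[i, 1])) add("CB", cb[i, ], i)
    if (!is.null(cg) && !is.na(cg[i, 1])) add("CG", cg[i, ], i)
  }
  a <- do.call(rbind, rows)
  a$uid <- residue_uid(a$chain, a$res_seq, a$icode)
  a
}

#' Two-domain hinge fixture with a known cleft
#'
#' Two compact C-alpha/C-beta domains built on a cubic lattice face each
#' other across a cleft and are joined by a sparse 3-residue linker bar
#' above it. The linker acts as a hinge axle: the softest non-trivial mode
#' is a clamshell opening/closing of the domains about it, along the
#' inter-domain axis. The central patch of each cleft face carries a
#' protruding pseudo side chain (CB plus an extended CG "finger") reaching
#' into the cleft; the mutual occlusion of opposing fingers switches on
#' and off as the cleft breathes, which is the exposure-change signal the
#' predictor looks for. One domain additionally carries an open well on
#' its outer face — a decoy pocket far from the cleft, larger than the
#' cleft pocket, so pocket ranking by exposure (not by size) can be
#' exercised.
#'
#' Ground truth is fixed geometrically at build time: `cleft_center` is
#' the midpoint between the facing surfaces at mid-face height, and
#' `cleft_lining_residues` are the residues whose C-alpha lies within 8
#' Angstrom of it.
#'
#' @param n_per_domain residues per domain (>= 10, at most 60; default 40
#'   gives two complete 4 x 5 layers per domain).
#' @param gap separation between the van der Waals surfaces of the facing
#'   CB shells (Angstrom, default 6); the CG fingers protrude beyond them
#'   into the cleft.
#' @param jitter uniform coordinate noise half-width (Angstrom).
#' @param seed integer seed; fixtures are bitwise reproducible.
#' @return a `hinge_fixture`: `structure`, `cleft_center`,
#'   `cleft_lining_residues`, `decoy_center`, `seed`.
#' @export
make_hinge <- function(n_per_domain = 40L, gap = 6, jitter = 0.3, seed = 1L) {
  stopifnot(n_per_domain >= 10, n_per_domain <= 60, gap > 0, jitter >= 0)
  a <- 4.0                          # lattice spacing: dense contact graph
  r_c <- 1.7                        # carbon vdW radius
  cb_len <- 1.8                     # CB pseudo-bond length
  cg_len <- NA                      # set below: finger reach beyond CA
  x0 <- (gap + 2 * r_c + 2 * cb_len) / 2   # facing CA planes at +/- x0
  cg_len <- x0 - 2.7                # opposing finger tips rest ~5.4 A apart
  ys <- c(0, 4, 8, 12)

  # per-domain site pool: cleft-facing plate first (complete, so the
  # cleft is fully walled), then the outer plate, then a third layer
  zs <- c(0, 4, 8, 12, 16)
  pool <- as.matrix(expand.grid(x = c(x0, x0 + a, x0 + 2 * a), y = ys, z = zs))
  pool <- pool[order(pool[, 1], abs(pool[, 2] - 6), abs(pool[, 3] - 8)), ]
  template <- pool[seq_len(n_per_domain), , drop = FALSE]

  # decoy canyon: domain A's outer plate is pushed outward so the two
  # plates enclose a slab void wider than the cleft slit, and the outer
  # plate's top row bends inward to roof it (burying its upper cells).
  # The void is far too wide for any atom-atom occlusion, so it carries
  # no exposure-change signal
  void_sep <- 11.4                  # plate separation across the decoy void
  dom_a <- template
  outer_a <- dom_a[, 1] > x0 + a / 2
  dom_a[outer_a, 1] <- x0 + void_sep
  roof_a <- outer_a & dom_a[, 3] > 14
  dom_a[roof_a, 1] <- x0 + void_sep / 2
  dom_a[roof_a, 3] <- 18.5
  dom_b <- template
  decoy_center <- c(-(x0 + void_sep / 2), 6, 8)
  dom_a[, 1] <- -dom_a[, 1]

  # linker bar along y at the hinge level: rotation about it (the
  # clamshell) is the one relative domain motion its springs do not resist
  linker <- rbind(c(0, 2, 16), c(0, 6, 16.8), c(0, 10, 16))
  ca <- rbind(dom_a, linker, dom_b)

  ca <- .with_seed(seed, ca + matrix(stats::runif(length(ca), -jitter, jitter),
                                     nrow(ca), 3))

  n <- nrow(ca)
  na <- nrow(dom_a)
  # fingers: central 2 x 2 patch of each cleft face (nearest template
  # site decides, so jitter cannot change the selection)
  face_sel <- abs(abs(ca[, 1]) - x0) < 1.0
  cy <- round(ca[, 2] / a) * a
  cz <- round(ca[, 3] / a) * a
  finger <- face_sel & cy %in% c(4, 8) & cz %in% c(4, 8)
  finger[(na + 1):(na + 3)] <- FALSE

  cb <- matrix(NA_real_, n, 3)
  cg <- matrix(NA_real_, n, 3)
  ctr_a <- colMeans(dom_a)
  ctr_b <- colMeans(dom_b)
  for (i in seq_len(n)) {
    if (i > na && i <= na + 3) next           # linker residues: CA only
    p <- ca[i, ]
    if (finger[i]) {
      dirv <- c(-sign(p[1]), 0, 0)            # into the cleft
      cb[i, ] <- p + cb_len * dirv
      cg[i, ] <- p + cg_len * dirv
    } else {
      ctr <- if (i <= na) ctr_a else ctr_b
      dirv <- p - ctr
      nv <- sqrt(sum(dirv^2))
      dirv <- if (nv < 1e-6) c(0, 0, 1) else dirv / nv
      cb[i, ] <- p + cb_len * dirv
    }
  }

  s <- new_structure(sprintf("hinge_seed%d", seed),
                     .atoms_from_coords(ca, cb, cg))
  cleft_center <- c(0, 6, 8)
  cac <- ca_coords(s)
  d <- sqrt(rowSums((cac - matrix(cleft_center, nrow(cac), 3, byrow = TRUE))^2))
  structure(list(structure = s,
                 cleft_center = cleft_center,
                 cleft_lining_residues = rownames(cac)[d < 8],
                 decoy_center = decoy_center,
                 seed = seed),
            class = "hinge_fixture")
}

#' Continuum buried-void volume by analytic ray casting
#'
#' Independent reference for the grid pocket detector: on a fine point
#' lattice, a point is part of the buried void when it lies outside every
#' probe-expanded atom sphere and, in at least `min_psp` of the 7 scan
#' directions, rays cast both ways intersect an atom sphere
#' (protein-solvent-protein enclosure). Ray-sphere intersections are
#' solved analytically, so no occupancy grid or marching is involved.
#'
#' @param atoms n x 3 atom coordinate matrix.
#' @param radius probe-expanded sphere radius per atom (scalar or vector).
#' @param lower,upper region bounds (the fine lattice spans them).
#' @param fine fine lattice step in Angstrom.
#' @param min_psp minimum number of enclosed directions (of 7).
#' @return list with `volume` (Angstrom^3) and `centroid`.
#' @export
psp_void_volume <- function(atoms, radius, lower, upper, fine = 0.4,
                            min_psp = 3) {
  radius <- rep_len(radius, nrow(atoms))
  fg <- as.matrix(expand.grid(
    x = seq(lower[1], upper[1], by = fine),
    y = seq(lower[2], upper[2], by = fine),
    z = seq(lower[3], upper[3], by = fine)))
  # outside every sphere (chunked distance test)
  free <- logical(nrow(fg))
  for (i0 in seq(1, nrow(fg), by = 4096)) {
    i1 <- min(i0 + 4095, nrow(fg))
    blk <- fg[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(atoms^2), "+") -
      2 * tcrossprod(blk, atoms)
    free[i0:i1] <- apply(sweep(d2, 2, radius^2) > 0, 1, all)
  }
  p <- fg[free, , drop = FALSE]
  if (nrow(p) == 0) return(list(volume = 0, centroid = c(NA, NA, NA)))
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pc <- tcrossprod(p, atoms)            # p . c
  p2 <- rowSums(p^2)
  c2 <- rowSums(atoms^2)
  npsp <- integer(nrow(p))
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ]
    cd <- as.numeric(atoms %*% d)
    pd <- as.numeric(p %*% d)
    # t* = d.(c - p); hit iff closest approach within radius at t > 0
    tstar <- outer(-pd, cd, "+")
    d2line <- outer(p2, c2, "+") - 2 * pc - tstar^2
    disc <- sweep(-d2line, 2, radius^2, "+")
    hit <- disc >= 0
    tex <- tstar + sqrt(pmax(disc, 0))  # exit parameter
    fwd <- apply(hit & tex > 0, 1, any)
    bwd <- apply(hit & (-tstar + sqrt(pmax(disc, 0))) > 0, 1, any)
    npsp <- npsp + (fwd & bwd)
  }
  buried <- npsp >= min_psp
  list(volume = sum(buried) * fine^3,
       centroid = colMeans(p[buried, , drop = FALSE]))
}

#' Slab with a carved well: a pocket-detection test bed
#'
#' A dense pseudo-atom lattice slab from whose top face a rectangular well
#' is excavated. Atoms are removed wherever their probe-expanded sphere
#' would intrude into the nominal well box, so the accessible void closely
#' matches the box. The reported `well_volume_nominal` is the ground-truth
#' buried-void volume of the excavation, computed by [psp_void_volume()] —
#' the continuum enclosure criterion with analytic ray casting,
#' independent of the grid detector.
#'
#' @param slab_dims integer 3-vector, slab extent in lattice cells.
#' @param well_dims integer 3-vector, well extent in lattice cells; the
#'   well is centred on the top (+z) face and open there.
#' @param spacing lattice spacing in Angstrom (default 2).
#' @return a `slab_fixture`: `structure`, `well_center`,
#'   `well_volume_nominal` (Angstrom^3), `well_dims_ang`.
#' @export
make_slab_with_well <- function(slab_dims = c(10, 10, 5),
                                well_dims = c(2, 2, 2), spacing = 2.0) {
  stopifnot(length(slab_dims) == 3, length(well_dims) == 3, spacing > 0)
  if (any(well_dims < 0)) stop("well_dims must be non-negative", call. = FALSE)
  if (any(well_dims > 0) &&
      (any(well_dims[1:2] + 4 > slab_dims[1:2]) || well_dims[3] + 2 > slab_dims[3]))
    stop("well does not fit inside the slab with 2-cell walls", call. = FALSE)
  g <- expand.grid(x = (0:(slab_dims[1] - 1)) * spacing,
                   y = (0:(slab_dims[2] - 1)) * spacing,
                   z = (0:(slab_dims[3] - 1)) * spacing)
  atoms <- as.matrix(g)
  r_clear <- 1.7 + 1.4
  top <- max(atoms[, 3])
  wx <- well_dims[1] * spacing; wy <- well_dims[2] * spacing
  wz <- well_dims[3] * spacing
  cx <- mean(range(atoms[, 1])); cy <- mean(range(atoms[, 2]))
  # well box, open at the top surface
  lo <- c(cx - wx / 2, cy - wy / 2, top - wz)
  hi <- c(cx + wx / 2, cy + wy / 2, top + r_clear + spacing)
  well_center <- c(cx, cy, top - wz / 2)
  if (all(well_dims > 0)) {
    # drop atoms whose expanded sphere intrudes into the box
    dbox <- function(p) {
      d <- pmax(lo - p, 0, p - hi)
      sqrt(sum(d^2))
    }
    keep <- apply(atoms, 1, dbox) >= r_clear
    atoms <- atoms[keep, , drop = FALSE]
    # ground truth: continuum buried-void volume of the excavation (box
    # plus the moat left by the carve, including the enclosed mouth)
    pad <- r_clear + spacing
    ref <- psp_void_volume(atoms, r_clear,
                           lower = lo - pad,
                           upper = c(hi[1] + pad, hi[2] + pad,
                                     top + r_clear + 1),
                           fine = spacing / 5)
    nominal <- ref$volume
  } else {
    nominal <- 0
  }
  s <- new_structure(sprintf("slab_%s_well_%s",
                             paste(slab_dims, collapse = "x"),
                             paste(well_dims, collapse = "x")),
                     .atoms_from_coords(atoms))
  structure(list(structure = s, well_center = well_center,
                 well_volume_nominal = nominal,
                 well_dims_ang = c(wx, wy, wz)),
            class = "slab_fixture")
}

#' Ideal alpha-helical C-alpha trace (rigid control)
#'
#' A single helix has no hinge; end-to-end prediction on it should raise a
#' no-signal condition or return a site near the axis, never crash.
#'
#' @param n_res number of residues (>= 6).
#' @return an `exposite_structure` with one CA per residue.
#' @export
make_helix <- function(n_res = 20L) {
  stopifnot(n_res >= 6)
  i <- seq_len(n_res) - 1
  theta <- i * 100 * pi / 180
  ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  new_structure(sprintf("helix_%d", n_res), .atoms_from_coords(ca))
}
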