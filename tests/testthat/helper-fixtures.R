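# Shared helpers: tiny handmade structures and rigid-body transforms.

# a structure from bare CA coordinates (one CA atom per residue)
ca_structure <- function(coords, id = "test") {
  n <- nrow(coords)
  atoms <- data.frame(
    serial = seq_len(n), name = "CA", altloc = "", res_name = "ALA",
    chain = "A", res_seq = seq_len(n), icode = "",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occupancy = 1, b = 0, element = "C", stringsAsFactors = FALSE)
  atoms$uid <- residue_uid(atoms$chain, atoms$res_seq, atoms$icode)
  exposite:::new_structure(id, atoms)
}

# seeded random rotation matrix (QR of a normal matrix, det +1)
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# apply a rigid-body transform to every atom (polymer and ligand)
transform_structure <- function(s, R = diag(3), t = c(0, 0, 0)) {
  for (part in c("atoms", "ligand")) {
    a <- s[[part]]
    if (nrow(a) == 0) next
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
    a$x <- xyz[, 1] + t[1]
    a$y <- xyz[, 2] + t[2]
    a$z <- xyz[, 3] + t[3]
    s[[part]] <- a
  }
  s
}

# random connected CA globule: a 3.8 A random walk confined to a ball of
# protein-like density, so consecutive steps guarantee connectivity at
# the default 12 A cutoff and every node has a well-conditioned local
# contact environment (no floppy dangling ends)
random_chain <- function(n, seed) {
  set.seed(seed)
  r_max <- 2.6 * n^(1 / 3)
  p <- matrix(0, n, 3)
  for (i in 2:n) {
    repeat {
      st <- rnorm(3)
      cand <- p[i - 1, ] + 3.8 * st / sqrt(sum(st^2))
      if (sum(cand^2) <= r_max^2) break
    }
    p[i, ] <- cand
  }
  p
}

# accessible area of two equal spheres at separation d: each loses a
# spherical cap of height h = R - d/2 (closed form)
two_sphere_area <- function(R, d) {
  if (d >= 2 * R) return(2 * 4 * pi * R^2)
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

# minimal PDB text: one residue, three atoms
minimal_pdb <- function() {
  paste(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END", sep = "\n")
}
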