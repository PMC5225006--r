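# helper: hand-built grid with a given label array
raw_grid <- function(dims, label, spacing = 1, origin = c(0, 0, 0)) {
  structure(list(origin = origin, spacing = spacing, dims = as.integer(dims),
                 label = as.integer(label)),
            class = "pocket_grid")
}

test_that("build_grid labels a ball of protein cells around a single atom", {
  s <- ca_structure(matrix(c(0, 0, 0), 1))
  g <- build_grid(s, spacing = 1, margin = 4)
  centers <- exposite:::.cell_centers(g, seq_along(g$label))
  d <- sqrt(rowSums(centers^2))
  expect_true(all((g$label == 1) == (d <= 1.7 + 1.4)))
  # the outermost shell of the grid is pure solvent
  nx <- g$dims[1]; ny <- g$dims[2]; nz <- g$dims[3]
  i0 <- seq_along(g$label) - 1L
  i <- i0 %% nx; j <- (i0 %/% nx) %% ny; k <- i0 %/% (nx * ny)
  rim <- i == 0 | i == nx - 1 | j == 0 | j == ny - 1 | k == 0 | k == nz - 1
  expect_true(all(g$label[rim] == 0))
})

test_that("psp_scan: open cells stay solvent, enclosed cells reach 7 directions", {
  # 9^3 grid: protein box with a hollow 1-cell cavity at the centre
  dims <- c(9, 9, 9)
  lab <- array(0L, dims)
  lab[3:7, 3:7, 3:7] <- 1L
  lab[5, 5, 5] <- 0L
  g <- psp_scan(raw_grid(dims, lab), min_psp = 3)
  out <- array(g$label, dims)
  expect_identical(out[5, 5, 5], 2L)   # fully enclosed -> pocket
  expect_identical(out[1, 1, 1], 0L)   # open corner stays solvent
  # even min_psp = 7 flags the cavity (all directions enclosed)
  g7 <- psp_scan(raw_grid(dims, lab), min_psp = 7)
  expect_identical(array(g7$label, dims)[5, 5, 5], 2L)
})

test_that("a convex atom cluster yields zero pockets", {
  s0 <- make_slab_with_well(c(10, 10, 5), c(0, 0, 0))
  expect_length(find_pockets(s0$structure, ref_point = s0$well_center), 0)
  # compact convex blob
  blob <- ca_structure(as.matrix(expand.grid(x = c(0, 2, 4), y = c(0, 2, 4),
                                             z = c(0, 2, 4))))
  expect_length(find_pockets(blob), 0)
})

test_that("cluster_pockets counts, sorts and tie-breaks as documented", {
  dims <- c(12, 12, 12)
  lab <- array(0L, dims)
  lab[2:4, 2:4, 2:4] <- 2L          # 27-cell component
  lab[8:9, 8:9, 8:9] <- 2L          # 8-cell component
  pk <- cluster_pockets(raw_grid(dims, lab), ref_point = c(0, 0, 0))
  expect_length(pk, 2)
  expect_equal(sapply(pk, `[[`, "volume"), c(27, 8))
  expect_equal(sapply(pk, `[[`, "rank_by_size"), c(1, 2))
  expect_equal(unname(pk[[1]]$center), c(2, 2, 2))  # cavity centre, 0-origin
  # volume tie: the component closer to the reference point ranks first
  lab2 <- array(0L, dims)
  lab2[2:3, 2, 2] <- 2L
  lab2[9:10, 9, 9] <- 2L
  pk2 <- cluster_pockets(raw_grid(dims, lab2), ref_point = c(9.5, 9, 9))
  expect_equal(unname(pk2[[1]]$center), c(8.5, 8, 8))
  # empty grid -> empty list
  expect_length(cluster_pockets(raw_grid(dims, array(0L, dims)),
                                ref_point = c(0, 0, 0)), 0)
})

test_that("filter_and_truncate applies the volume floor and the keep cap", {
  mkp <- function(v) structure(list(cells = seq_len(v), center = c(0, 0, 0),
                                    volume = v, n_cells = v), class = "pocket")
  pk <- lapply(c(27, 8, 6), mkp)
  kept <- filter_and_truncate(pk, min_volume = 7, keep = 10)
  expect_equal(sapply(kept, `[[`, "volume"), c(27, 8))
  many <- lapply(seq(100, 12), mkp)
  expect_length(filter_and_truncate(many, min_volume = 7, keep = 10), 10)
  expect_length(filter_and_truncate(list(), 7, 10), 0)
})

test_that("slab well is recovered: one pocket, centred, sized", {
  sx <- make_slab_with_well(c(10, 10, 5), c(2, 2, 2))
  pk <- find_pockets(sx$structure, ref_point = sx$well_center)
  expect_length(pk, 1)
  expect_lt(sqrt(sum((pk[[1]]$center - sx$well_center)^2)), 1)
  expect_lt(abs(pk[[1]]$volume - sx$well_volume_nominal) /
              sx$well_volume_nominal, 0.25)
})

test_that("detected volume against the ray-cast reference improves with finer grids", {
  sx <- make_slab_with_well(c(10, 10, 5), c(2, 2, 2))
  nom <- sx$well_volume_nominal
  v1 <- find_pockets(sx$structure, spacing = 1.0,
                     ref_point = sx$well_center)[[1]]$volume
  v05 <- find_pockets(sx$structure, spacing = 0.5,
                      ref_point = sx$well_center)[[1]]$volume
  e1 <- abs(v1 - nom) / nom
  e05 <- abs(v05 - nom) / nom
  expect_lte(e05, e1 / 2)
})

test_that("doubling the margin leaves the pocket set unchanged", {
  sx <- make_slab_with_well(c(10, 10, 5), c(2, 2, 2))
  p4 <- find_pockets(sx$structure, margin = 4, ref_point = sx$well_center)
  p8 <- find_pockets(sx$structure, margin = 8, ref_point = sx$well_center)
  expect_equal(length(p4), length(p8))
  expect_equal(p4[[1]]$volume, p8[[1]]$volume)
  expect_equal(p4[[1]]$center, p8[[1]]$center, tolerance = 1e-9)
})

test_that("pockets are stable under whole-step grid-aligned translation", {
  sx <- make_slab_with_well(c(10, 10, 5), c(2, 2, 2))
  s1 <- transform_structure(sx$structure, diag(3), c(3, -2, 5))
  p0 <- find_pockets(sx$structure, ref_point = sx$well_center)
  p1 <- find_pockets(s1, ref_point = sx$well_center + c(3, -2, 5))
  expect_equal(p1[[1]]$volume, p0[[1]]$volume)
  expect_equal(unname(p1[[1]]$center - p0[[1]]$center), c(3, -2, 5),
               tolerance = 1e-9)
})

test_that("pocket volume is approximately rotation invariant", {
  sx <- make_slab_with_well(c(10, 10, 5), c(2, 2, 2))
  v0 <- find_pockets(sx$structure, ref_point = sx$well_center)[[1]]$volume
  R <- random_rotation(13)
  sr <- transform_structure(sx$structure, R)
  vr <- find_pockets(sr, ref_point = as.numeric(R %*% sx$well_center))[[1]]$volume
  expect_lt(abs(vr - v0) / v0, 0.25)
})

test_that("pocket centres export as HETATM pseudo-atoms", {
  sx <- make_slab_with_well(c(10, 10, 5), c(2, 2, 2))
  pk <- find_pockets(sx$structure, ref_point = sx$well_center)
  txt <- write_pocket_pdb(pk)
  expect_match(txt, "^HETATM")
  parsed <- read_pdb(txt)
  expect_equal(nrow(parsed$ligand), length(pk))
})
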