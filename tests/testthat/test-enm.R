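test_that("one-spring dimer has the analytic single mode 2*gamma", {
  for (gam in c(1, 2.5)) {
    net <- elastic_network(rbind(c(0, 0, 0), c(5, 0, 0)), cutoff = 8,
                           gamma = gam)
    H <- build_hessian(net)
    expect_equal(H, t(H))
    m <- suppressWarnings(compute_modes(H, n_modes = 10))
    expect_length(m$values, 1)
    expect_equal(m$values, 2 * gam, tolerance = 1e-12)
    expect_true(m$truncated)
  }
})

test_that("nodes beyond the cutoff raise a connectivity error", {
  net <- elastic_network(rbind(c(0, 0, 0), c(0, 0, 50), c(0, 1, 50)),
                         cutoff = 8)
  expect_error(build_hessian(net), "disconnected")
})

test_that("hessian rows of blocks sum to zero and the matrix is PSD", {
  coords <- random_chain(25, seed = 42)
  H <- build_hessian(elastic_network(coords))
  n <- nrow(coords)
  # translation null-space: H annihilates each uniform axis translation
  for (ax in 1:3) {
    tvec <- rep(0, 3 * n); tvec[seq(ax, 3 * n, by = 3)] <- 1
    expect_lt(max(abs(H %*% tvec)), 1e-12)
  }
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
})

test_that("eigenpairs agree with an independent dense decomposition", {
  coords <- random_chain(20, seed = 7)
  H <- build_hessian(elastic_network(coords))
  m <- compute_modes(H, n_modes = 10)
  # independent route: singular value decomposition (different LAPACK
  # driver); for a symmetric PSD matrix the singular values are the
  # eigenvalues
  sv <- sort(svd(H)$d)
  expect_equal(m$values, sv[7:16], tolerance = 1e-10)
  # residual check of each retained eigenpair
  for (k in seq_along(m$values)) {
    r <- H %*% m$vectors[, k] - m$values[k] * m$vectors[, k]
    expect_lt(max(abs(r)), 1e-10)
  }
})

test_that("the hessian matches an independent ANM implementation", {
  skip_if_not_installed("bio3d")
  for (seed in c(3, 17)) {
    coords <- random_chain(15, seed)
    H <- build_hessian(elastic_network(coords, cutoff = 12, gamma = 1))
    H_ref <- bio3d::build.hessian(as.numeric(t(coords)),
                                  pfc.fun = bio3d::load.enmff("anm"),
                                  cutoff = 12)
    expect_equal(H, unclass(H_ref), tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("connected 3D networks shed exactly 6 rigid-body modes", {
  for (seed in 1:5) {
    m <- compute_modes(build_hessian(elastic_network(random_chain(30, seed))))
    expect_identical(m$n_trivial_removed, 6L)
    expect_true(all(diff(m$values) >= -1e-12))
    expect_true(all(m$values > 0))
    G <- crossprod(m$vectors)
    expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  }
})

test_that("eigenvalues are invariant under rigid-body transforms", {
  s <- ca_structure(random_chain(18, seed = 5))
  m0 <- compute_modes(build_hessian(elastic_network(s)), 8)
  st <- transform_structure(s, random_rotation(2), c(-4, 7, 1))
  m1 <- compute_modes(build_hessian(elastic_network(st)), 8)
  expect_equal(m1$values, m0$values, tolerance = 1e-9)
})

test_that("generate_extremes is symmetric, scaled, and COM-preserving", {
  fx <- make_hinge(seed = 2)
  s <- fx$structure
  modes <- compute_modes(build_hessian(elastic_network(s)), 10)
  for (k in c(1, 4, 10)) {
    pair <- generate_extremes(s, modes, k, amplitude = 2)
    mid <- (as.matrix(pair$plus$atoms[, c("x", "y", "z")]) +
            as.matrix(pair$minus$atoms[, c("x", "y", "z")])) / 2
    expect_equal(mid, as.matrix(s$atoms[, c("x", "y", "z")]),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(pair_rmsd(pair), 2, tolerance = 1e-6)
    # non-trivial modes are orthogonal to translations: COM fixed
    expect_equal(unname(colMeans(ca_coords(pair$plus))),
                 unname(colMeans(ca_coords(s))), tolerance = 1e-8)
  }
  # requested amplitude is honoured over a range
  p5 <- generate_extremes(s, modes, 1, amplitude = 0.5)
  expect_equal(pair_rmsd(p5), 0.5, tolerance = 1e-6)
  expect_error(generate_extremes(s, modes, 99, 1), "out of range")
})

test_that("tiny amplitudes reduce to the input structure", {
  s <- ca_structure(random_chain(12, seed = 9))
  modes <- compute_modes(build_hessian(elastic_network(s)), 3)
  pair <- generate_extremes(s, modes, 1, amplitude = 1e-9)
  expect_equal(as.matrix(pair$plus$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]),
               tolerance = 1e-8, ignore_attr = TRUE)
})
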