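test_that("distance matrix matches hand values and the brute-force oracle", {
  expect_equal(compute_distance_matrix(rbind(c(0, 0, 0), c(3, 4, 0)))[1, 2], 5)
  expect_identical(compute_distance_matrix(matrix(c(1, 2, 3), 1, 3)),
                   matrix(0, 1, 1))
  set.seed(11)
  for (m in c(2, 4, 6, 10)) {
    coords <- matrix(rnorm(m * 3, sd = 3), m, 3)
    D <- compute_distance_matrix(coords)
    expect_equal(D, bf_distance_matrix(coords), tolerance = 1e-12)
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
  }
  expect_error(compute_distance_matrix(rbind(c(0, 0, NA), c(1, 1, 1))),
               "finite")
})

test_that("local frames are orthonormal, right-handed, aligned with v1", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  fr <- build_local_frame(coords, 2)
  expect_false(fr$degenerate)
  expect_equal(fr$R, diag(3), tolerance = 1e-12)
  set.seed(21)
  for (rep in 1:20) {
    m <- sample(3:9, 1)
    coords <- matrix(rnorm(m * 3, sd = 2), m, 3)
    for (i in seq_len(m)) {
      fr <- build_local_frame(coords, i)
      R <- fr$R
      expect_equal(R %*% t(R), diag(3), tolerance = 1e-8)
      expect_equal(det(R), 1, tolerance = 1e-8)
      if (!fr$degenerate && i > 1) {
        v1 <- coords[min(i, m), ] - coords[min(i, m) - 1, ]
        v1 <- v1 / sqrt(sum(v1^2))
        expect_equal(abs(sum(R[1, ] * v1)), 1, tolerance = 1e-8)
      }
    }
  }
})

test_that("the literal Gram-Schmidt residual u3 vanishes (v3 = v1 + v2)", {
  set.seed(31)
  for (rep in 1:50) {
    x <- matrix(rnorm(9, sd = 2), 3, 3)
    v1 <- x[2, ] - x[1, ]
    v2 <- x[3, ] - x[2, ]
    v3 <- x[3, ] - x[1, ]
    u1 <- v1
    u2 <- v2 - sum(v2 * u1) / sum(u1 * u1) * u1
    u3 <- v3 - sum(v3 * u1) / sum(u1 * u1) * u1 -
      sum(v3 * u2) / sum(u2 * u2) * u2
    expect_lt(sqrt(sum(u3^2)), 1e-10)
  }
})

test_that("collinear stencils fall back to the canonical frame with a flag", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  fr <- build_local_frame(coords, 2)
  expect_true(fr$degenerate)
  expect_equal(fr$R, diag(3))
  expect_true(build_local_frame(matrix(rnorm(6), 2, 3), 1)$degenerate)
})

test_that("spatial positions are rigid-motion invariant and norm-consistent", {
  set.seed(41)
  mol <- generate_conformer(synthetic_spec(), seed = 5, n_atoms = 8)
  sp <- compute_spatial_position_matrix(mol$coords)
  D <- compute_distance_matrix(mol$coords)
  m <- nrow(mol$coords)
  for (i in seq_len(m)) {
    expect_equal(sp$P[i, i, ], c(0, 0, 0))
    if (sp$degenerate[i]) next
    for (j in seq_len(m))
      expect_equal(sqrt(sum(sp$P[i, j, ]^2)), D[i, j], tolerance = 1e-5)
  }
  for (rep in 1:20) {
    R <- random_rotation()
    tr <- rnorm(3, sd = 10)
    sp2 <- compute_spatial_position_matrix(apply_rigid(mol$coords, R, tr))
    expect_lt(max(abs(sp2$P - sp$P)), 1e-6)
  }
  expect_equal(compute_spatial_position_matrix(matrix(0, 1, 3))$P,
               array(0, c(1, 1, 3)))
})

test_that("discretization follows the declared bin edges", {
  sch <- binning_scheme()
  dvals <- matrix(c(0, 0.49, 0.5, 15.99, 16, 100), 1)
  P <- array(0, c(1, 6, 3))
  P[1, , 1] <- c(-100, -10, -9.5, 0, 9.99, 100)
  D6 <- matrix(0, 6, 6); P6 <- array(0, c(6, 6, 3))
  D6[1, ] <- dvals; P6[1, , 1] <- P[1, , 1]
  b <- discretize_pair_features(D6, P6, sch)
  expect_equal(b$D_bins[1, ], c(0L, 0L, 1L, 31L, 32L, 32L))
  expect_equal(b$P_bins[1, , 1], c(0L, 1L, 1L, 11L, 20L, 21L))
  # monotone in distance below overflow
  ds <- seq(0, 20, by = 0.01)
  Dm <- matrix(0, length(ds), length(ds)); Dm[1, ] <- ds
  bb <- discretize_pair_features(Dm, array(0, c(length(ds), length(ds), 3)),
                                 sch)
  expect_true(all(diff(bb$D_bins[1, ]) >= 0))
  # idempotent on bin centres
  centres <- (0:31) * 0.5 + 0.25
  Dc <- matrix(0, 32, 32); Dc[1, ] <- centres
  bc <- discretize_pair_features(Dc, array(0, c(32, 32, 3)), sch)
  expect_equal(bc$D_bins[1, ], 0:31)
})

test_that("pair featurization is invariant under rigid motions", {
  set.seed(51)
  spec <- synthetic_spec()
  for (rep in 1:5) {
    mol <- generate_conformer(spec, seed = 100 + rep)
    pf <- pair_features(mol)
    for (k in 1:4) {
      mol2 <- mol
      mol2$coords <- apply_rigid(mol$coords, random_rotation(),
                                 rnorm(3, sd = 20))
      pf2 <- pair_features(mol2)
      expect_identical(pf2$D_bins, pf$D_bins)
      expect_identical(pf2$P_bins, pf$P_bins)
      expect_lt(max(abs(pf2$D - pf$D)), 1e-5)
      expect_lt(max(abs(pf2$P - pf$P)), 1e-5)
    }
  }
})

test_that("initial pair representation is deterministic, shaped, invariant", {
  cfg <- tiny_encoder_config()
  params <- init_encoder_params(cfg, atom_vocabulary(), "enc", seed = 5)
  mol <- generate_conformer(synthetic_spec(), seed = 9, n_atoms = 6)
  pf <- pair_features(mol)
  z1 <- pairbind:::pair_init_forward(params, "enc", pf$D_bins, pf$P_bins, cfg)
  z2 <- pairbind:::pair_init_forward(params, "enc", pf$D_bins, pf$P_bins, cfg)
  expect_identical(z1$z0, z2$z0)
  expect_equal(dim(z1$z0), c(7L * 7L, cfg$d_pair))
  mol2 <- mol
  mol2$coords <- apply_rigid(mol$coords, random_rotation(), rnorm(3))
  pf2 <- pair_features(mol2)
  z3 <- pairbind:::pair_init_forward(params, "enc", pf2$D_bins, pf2$P_bins,
                                     cfg)
  expect_identical(z1$z0, z3$z0)
})

test_that("the compiled featurizer matches the reference R pipeline", {
  spec <- synthetic_spec()
  for (s in 1:10) {
    mol <- generate_conformer(spec, seed = 700 + s)
    a <- pair_features(mol)
    b <- pair_features_r(mol)
    expect_equal(a$D, b$D, tolerance = 1e-12)
    expect_equal(a$P, b$P, tolerance = 1e-12)
    expect_identical(a$D_bins, b$D_bins)
    expect_identical(a$P_bins, b$P_bins)
    expect_equal(as.logical(a$degenerate), b$degenerate)
  }
  # degenerate cases: single atom, two atoms, collinear chain
  for (mol in list(molecule("C", matrix(0, 1, 3)),
                   molecule(c("C", "O"), rbind(c(0, 0, 0), c(1.5, 0, 0))),
                   molecule(c("C", "C", "C"),
                            rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0))))) {
    a <- pair_features(mol)
    b <- pair_features_r(mol)
    expect_equal(a$D, b$D, tolerance = 1e-12)
    expect_identical(a$D_bins, b$D_bins)
    expect_identical(a$P_bins, b$P_bins)
    expect_true(all(a$P[as.logical(a$degenerate), , ] == 0))
  }
})
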