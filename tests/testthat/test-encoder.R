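test_that("zero pair bias reduces each layer to a vanilla transformer", {
  cfg <- tiny_encoder_config()
  params <- init_encoder_params(cfg, atom_vocabulary(), "enc", seed = 5)
  for (l in seq_len(cfg$n_layers)) {
    params[[sprintf("enc.l%d.Wzb", l)]][] <- 0
    params[[sprintf("enc.l%d.bzb", l)]][] <- 0
  }
  set.seed(2)
  Tn <- 6
  s0 <- matrix(rnorm(Tn * cfg$d_model), Tn)
  z0 <- matrix(rnorm(Tn * Tn * cfg$d_pair), Tn * Tn)
  fwd <- pairbind:::encoder_stack_forward_r(params, "enc", s0, z0, cfg)
  # independent vanilla reference, layer by layer
  s_ref <- s0
  for (l in seq_len(cfg$n_layers))
    s_ref <- vanilla_layer_forward(params, "enc", l, s_ref)
  g <- params[["enc.lnfg"]]; b <- params[["enc.lnfb"]]
  s_ref <- t(apply(s_ref, 1, function(r)
    g * (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5) + b))
  expect_equal(fwd$s, s_ref, tolerance = 1e-6)
})

test_that("a large negative pair bias removes attention to that column", {
  cfg <- tiny_encoder_config()
  params <- init_encoder_params(cfg, atom_vocabulary(), "enc", seed = 6)
  # route pair channel 1 straight through to every head's bias
  params[["enc.l1.Wzb"]][] <- 0
  params[["enc.l1.Wzb"]][1, ] <- 1
  Tn <- 5; j <- 3
  set.seed(3)
  s0 <- matrix(rnorm(Tn * cfg$d_model), Tn)
  z0 <- matrix(0, Tn * Tn, cfg$d_pair)
  z0[(j - 1) * Tn + seq_len(Tn), 1] <- -1e9   # pairs (i, j) for all i
  fwd <- pairbind:::encoder_stack_forward_r(params, "enc", s0, z0, cfg)
  for (h in seq_along(fwd$caches[[1]]$A))
    expect_lt(max(fwd$caches[[1]]$A[[h]][, j]), 1e-6)
})

test_that("encoding is deterministic and permutation-equivariant", {
  cfg <- tiny_encoder_config()
  params <- init_encoder_params(cfg, atom_vocabulary(), "enc", seed = 7)
  mol <- generate_conformer(synthetic_spec(), seed = 15, n_atoms = 6)
  pf <- pair_features(mol)
  e1 <- encode_molecule(params, pf, cfg)
  e2 <- encode_molecule(params, pf, cfg)
  expect_identical(e1$single, e2$single)
  expect_identical(e1$pair, e2$pair)
  # permute atoms (keeping [CLS] first) consistently across all features
  m <- 6
  perm <- c(1, 1 + sample(m))
  pf_p <- pf
  pf_p$tokens <- pf$tokens[perm]
  pf_p$D_bins <- pf$D_bins[perm, perm]
  pf_p$P_bins <- pf$P_bins[perm, perm, ]
  e3 <- encode_molecule(params, pf_p, cfg)
  expect_equal(e3$single, e1$single[perm, ], tolerance = 1e-5)
  expect_equal(e3$single[1, ], e1$single[1, ], tolerance = 1e-5)
})

test_that("rigid motions leave the encoding unchanged", {
  cfg <- tiny_encoder_config()
  params <- init_encoder_params(cfg, atom_vocabulary(), "enc", seed = 8)
  mol <- generate_conformer(synthetic_spec(), seed = 16, n_atoms = 7)
  e1 <- encode_molecule(params, pair_features(mol), cfg)
  set.seed(4)
  mol2 <- mol
  mol2$coords <- apply_rigid(mol$coords, random_rotation(), rnorm(3, sd = 8))
  e2 <- encode_molecule(params, pair_features(mol2), cfg)
  expect_equal(e1$single, e2$single, tolerance = 1e-8)
})

test_that("single-atom molecules encode to the declared shapes", {
  cfg <- tiny_encoder_config()
  params <- init_encoder_params(cfg, atom_vocabulary(), "enc", seed = 9)
  mol <- molecule("C", matrix(0, 1, 3))
  enc <- encode_molecule(params, pair_features(mol), cfg)
  expect_equal(dim(enc$single), c(2L, cfg$d_model))
  expect_equal(dim(enc$pair), c(4L, cfg$d_pair))
  cfg_small <- cfg; cfg_small$max_len <- 3L
  big <- generate_conformer(synthetic_spec(), seed = 3, n_atoms = 10)
  expect_error(encode_molecule(params, pair_features(big), cfg_small),
               "maximum")
})

test_that("pair updates propagate and freezing them changes the output", {
  cfg <- tiny_encoder_config()
  params <- init_encoder_params(cfg, atom_vocabulary(), "enc", seed = 10)
  mol <- generate_conformer(synthetic_spec(), seed = 17, n_atoms = 5)
  pf <- pair_features(mol)
  e_full <- encode_molecule(params, pf, cfg)
  params_frozen <- params
  for (l in seq_len(cfg$n_layers)) {
    params_frozen[[sprintf("enc.l%d.Wup", l)]][] <- 0
    params_frozen[[sprintf("enc.l%d.bup", l)]][] <- 0
  }
  e_frozen <- encode_molecule(params_frozen, pf, cfg)
  expect_gt(max(abs(e_full$single - e_frozen$single)), 1e-8)
  # with zero update projection, z passes through unchanged
  pi_ <- pairbind:::pair_init_forward(params_frozen, "enc", pf$D_bins,
                                      pf$P_bins, cfg)
  expect_equal(e_frozen$pair, pi_$z0, tolerance = 1e-12)
})

test_that("pretraining heads meet their structural contracts", {
  cfg <- tiny_encoder_config()
  params <- c(init_encoder_params(cfg, atom_vocabulary(), "enc", seed = 11),
              init_pretrain_heads(cfg, atom_vocabulary(), "heads", seed = 12))
  mol <- generate_conformer(synthetic_spec(), seed = 18, n_atoms = 6)
  cr <- corrupt_molecule(mol, seed = 2)
  pf <- pair_features(list(atom_types = cr$input_types,
                           coords = cr$noisy_coords))
  enc <- encode_molecule(params, pf, cfg)
  heads <- pretrain_heads_forward(params, enc, cr$noisy_coords, cfg)
  expect_equal(heads$dist, t(heads$dist))
  expect_true(all(heads$dist >= 0))
  expect_equal(dim(heads$type_logits), c(6L, length(atom_vocabulary())))
  # zeroed final coordinate layer -> identity on noisy coords
  params0 <- params
  params0[["heads.Wc2"]][] <- 0
  params0[["heads.bc2"]][] <- 0
  h0 <- pretrain_heads_forward(params0, enc, cr$noisy_coords, cfg)
  expect_identical(h0$coords, cr$noisy_coords)
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- tiny_encoder_config()
  mol <- generate_conformer(synthetic_spec(), seed = 7, n_atoms = 5)
  cr <- corrupt_molecule(mol, seed = 9)
  params <- c(init_encoder_params(cfg, atom_vocabulary(), "enc", seed = 5),
              init_pretrain_heads(cfg, atom_vocabulary(), "heads", seed = 6))
  pl <- pretrain_loss(params, cr, cfg)
  lossfn <- function(p) pretrain_loss(p, cr, cfg, want_grads = FALSE)$loss
  h <- 1e-5
  set.seed(1)
  for (nm in sample(names(params), 15)) {
    x <- params[[nm]]
    k <- sample(length(x), 1)
    pp <- params; pp[[nm]][k] <- x[k] + h
    pm <- params; pm[[nm]][k] <- x[k] - h
    num <- (lossfn(pp) - lossfn(pm)) / (2 * h)
    ana <- if (is.null(pl$grads[[nm]])) 0 else pl$grads[[nm]][k]
    expect_lt(abs(num - ana) / max(1e-6, abs(num), abs(ana)), 1e-4)
  }
})

test_that("all three pretraining losses reach every encoder parameter", {
  cfg <- tiny_encoder_config()
  mol <- generate_conformer(synthetic_spec(), seed = 8, n_atoms = 6)
  cr <- corrupt_molecule(mol, seed = 10)
  params <- c(init_encoder_params(cfg, atom_vocabulary(), "enc", seed = 15),
              init_pretrain_heads(cfg, atom_vocabulary(), "heads", seed = 16))
  pl <- pretrain_loss(params, cr, cfg)
  weight_names <- grep("\\.(W|ln|E)", names(params), value = TRUE)
  for (nm in weight_names) {
    g <- pl$grads[[nm]]
    expect_false(is.null(g), info = nm)
    expect_gt(max(abs(g)), 0, label = sprintf("grad norm of %s", nm))
  }
})

test_that("the compiled stack matches the reference implementation exactly", {
  cfg <- tiny_encoder_config()
  params <- init_encoder_params(cfg, atom_vocabulary(), "enc", seed = 31)
  set.seed(9)
  Tn <- 7
  s0 <- matrix(rnorm(Tn * cfg$d_model), Tn)
  z0 <- matrix(rnorm(Tn * Tn * cfg$d_pair), Tn * Tn)
  ref <- pairbind:::encoder_stack_forward_r(params, "enc", s0, z0, cfg)
  cpp <- pairbind:::encoder_stack_forward(params, "enc", s0, z0, cfg)
  expect_equal(cpp$s, ref$s, tolerance = 1e-12)
  expect_equal(cpp$z, ref$z, tolerance = 1e-12)
  ds <- matrix(rnorm(Tn * cfg$d_model), Tn)
  dz <- matrix(rnorm(Tn * Tn * cfg$d_pair), Tn * Tn)
  bref <- pairbind:::encoder_stack_backward_r(params, "enc", ref, ds, dz, cfg)
  bcpp <- pairbind:::encoder_stack_backward(params, "enc", cpp, ds, dz, cfg)
  expect_equal(bcpp$ds0, bref$ds0, tolerance = 1e-12)
  expect_equal(bcpp$dz0, bref$dz0, tolerance = 1e-12)
  for (nm in names(bref$grads)) {
    expect_equal(unname(as.matrix(bcpp$grads[[nm]]))[, , drop = TRUE],
                 unname(as.matrix(bref$grads[[nm]]))[, , drop = TRUE],
                 tolerance = 1e-12, label = nm)
  }
})
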