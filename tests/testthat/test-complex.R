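make_tiny_sample <- function(seed = 11) {
  spec <- synthetic_spec(protein_len_range = c(5, 8),
                         atom_count_range = c(3, 6))
  generate_toy_complex(spec, seed = seed)
}

test_that("the substitute protein encoder meets the interface contract", {
  cfg <- tiny_encoder_config()
  params <- init_encoder_params(cfg, residue_vocabulary(), "prot", seed = 4)
  prot1 <- protein_input("A", list(matrix(0, 1, 3)), matrix(0, 1, 3))
  e1 <- encode_protein(params, prot1, cfg)
  expect_equal(dim(e1$single), c(2L, cfg$d_model))
  expect_equal(dim(e1$pair), c(4L, cfg$d_pair))
  smp <- make_tiny_sample()
  ep <- encode_protein(params, smp$protein, cfg)
  expect_identical(encode_protein(params, smp$protein, cfg)$single,
                   ep$single)
  # rigid motion leaves the representation unchanged
  prot2 <- smp$protein
  set.seed(5)
  R <- random_rotation(); tr <- rnorm(3, sd = 15)
  prot2$ca_coords <- apply_rigid(prot2$ca_coords, R, tr)
  prot2$heavy_atom_coords <- lapply(prot2$heavy_atom_coords, apply_rigid,
                                    R = R, t = tr)
  expect_equal(encode_protein(params, prot2, cfg)$single, ep$single,
               tolerance = 1e-8)
  # plug-in encoder hook is honoured
  fake <- function(params, protein, cfg, prefix, structure_mode)
    list(single = matrix(1, 2, cfg$d_model),
         pair = matrix(0, 4, cfg$d_pair), Tn = 2L)
  expect_equal(encode_protein(params, prot1, cfg, encoder_fn = fake)$single,
               matrix(1, 2, cfg$d_model))
})

test_that("complex assembly is block-diagonal with ligand first", {
  cfg <- tiny_encoder_config()
  lig <- list(single = matrix(1, 3, cfg$d_model),
              pair = matrix(2, 9, cfg$d_pair), Tn = 3L)    # m=2 + [CLS]
  prot <- list(single = matrix(3, 4, cfg$d_model),
               pair = matrix(4, 16, cfg$d_pair), Tn = 4L)  # n=3 + [CLS]
  cx <- assemble_complex(lig, prot)
  expect_equal(nrow(cx$single), 7)
  expect_equal(dim(cx$pair), c(49L, cfg$d_pair))
  z <- array(cx$pair, dim = c(7, 7, cfg$d_pair))
  expect_true(all(z[1:3, 1:3, ] == 2))
  expect_true(all(z[4:7, 4:7, ] == 4))
  expect_true(all(z[1:3, 4:7, ] == 0))    # 3 x 4 zero block
  expect_true(all(z[4:7, 1:3, ] == 0))    # 4 x 3 zero block
  expect_equal(cx$lig_cls, 1L)
  expect_equal(cx$prot_cls, 4L)
  bad <- prot; bad$single <- matrix(0, 4, cfg$d_model + 1)
  expect_error(assemble_complex(lig, bad), "widths")
})

test_that("relative ligand placement cannot leak into the model input", {
  cfg <- tiny_complex_config()
  model <- init_complex_model(cfg)
  smp <- make_tiny_sample()
  smp_shift <- smp
  smp_shift$ligand$coords <- sweep(smp$ligand$coords, 2, c(50, -20, 10), "+")
  expect_equal(affinity_forward(model, smp),
               affinity_forward(model, smp_shift), tolerance = 1e-10)
  expect_equal(binding_site_forward(model, smp),
               binding_site_forward(model, smp_shift), tolerance = 1e-10)
})

test_that("affinity prediction is invariant to rigid motions of either side", {
  cfg <- tiny_complex_config()
  model <- init_complex_model(cfg)
  smp <- make_tiny_sample(seed = 21)
  y0 <- affinity_forward(model, smp)
  set.seed(6)
  smp2 <- smp
  smp2$ligand$coords <- apply_rigid(smp$ligand$coords, random_rotation(),
                                    rnorm(3, sd = 30))
  R <- random_rotation(); tr <- rnorm(3, sd = 30)
  smp2$protein$ca_coords <- apply_rigid(smp$protein$ca_coords, R, tr)
  smp2$protein$heavy_atom_coords <-
    lapply(smp$protein$heavy_atom_coords, apply_rigid, R = R, t = tr)
  expect_equal(affinity_forward(model, smp2), y0, tolerance = 1e-6)
})

test_that("zeroed output layers give the analytic neutral predictions", {
  cfg <- tiny_complex_config()
  model <- init_complex_model(cfg)
  model$params[["aff.W2"]][] <- 0
  model$params[["aff.b2"]][] <- 0
  model$params[["site.W2"]][] <- 0
  model$params[["site.b2"]][] <- 0
  smp <- make_tiny_sample(seed = 31)
  expect_equal(affinity_forward(model, smp), 0)
  probs <- binding_site_forward(model, smp)
  expect_length(probs, length(smp$protein$residue_types))
  expect_true(all(probs == 0.5))
})

test_that("losses match their closed forms", {
  y <- c(5, 6, 7)
  l1 <- affinity_losses(y, y)
  expect_equal(l1$mse, 0)
  l2 <- affinity_losses(y + 1, y)
  expect_equal(l2$mse, 1)
  labs <- c(0, 1, 1, 0)
  l3 <- affinity_losses(y, y, site_probs = rep(0.5, 4), site_labels = labs)
  expect_equal(l3$bce, log(2), tolerance = 1e-12)
  l4 <- affinity_losses(y, y, site_probs = labs, site_labels = labs)
  expect_lt(l4$bce, 1e-5)
  expect_equal(l3$total, l3$mse + l3$bce)
  expect_error(affinity_losses(1:3, 1:4), "mismatch")
})

test_that("protein-block bookkeeping survives extraction and reinsertion", {
  cfg <- tiny_complex_config()
  model <- init_complex_model(cfg)
  smp <- make_tiny_sample(seed = 41)
  fw <- pairbind:::.complex_forward(model$params, cfg, smp, want_cache = TRUE)
  s_up <- fw$cache$tr$s
  cx <- fw$cache$cx
  sp <- s_up[cx$prot_rows, , drop = FALSE]
  rebuilt <- s_up
  rebuilt[cx$prot_rows, ] <- sp
  expect_identical(rebuilt, s_up)
  expect_equal(nrow(sp), length(smp$protein$residue_types))
})

test_that("fine-tuning gradients match numerical differentiation", {
  cfg <- tiny_complex_config()
  smp <- make_tiny_sample(seed = 51)
  model <- init_complex_model(cfg)
  fg <- finetune_sample_grads(model$params, cfg, smp, "both")
  lossfn <- function(p) {
    fw <- pairbind:::.complex_forward(p, cfg, smp, want_cache = FALSE)
    pr <- pmin(pmax(fw$site_probs, 1e-7), 1 - 1e-7)
    lab <- smp$site_labels
    (fw$yhat - smp$pK)^2 +
      cfg$lambda_site * (-mean(lab * log(pr) + (1 - lab) * log(1 - pr)))
  }
  h <- 1e-5
  set.seed(2)
  for (nm in sample(names(model$params), 12)) {
    x <- model$params[[nm]]
    k <- sample(length(x), 1)
    pp <- model$params; pp[[nm]][k] <- x[k] + h
    pm <- model$params; pm[[nm]][k] <- x[k] - h
    num <- (lossfn(pp) - lossfn(pm)) / (2 * h)
    ana <- if (is.null(fg$grads[[nm]])) 0 else fg$grads[[nm]][k]
    expect_lt(abs(num - ana) / max(1e-5, abs(num), abs(ana)), 5e-4)
  }
})

test_that("freezing the encoders stops their gradients", {
  cfg <- tiny_complex_config(freeze_encoders = TRUE)
  smp <- make_tiny_sample(seed = 61)
  model <- init_complex_model(cfg)
  fg <- finetune_sample_grads(model$params, cfg, smp, "both")
  expect_false(any(grepl("^(lig|prot)\\.", names(fg$grads))))
  expect_true(any(grepl("^trunk\\.", names(fg$grads))))
})
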