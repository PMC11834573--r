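# Complex-level model: protein encoding (pluggable; a lightweight
# residue-level substitute encoder is bundled), ligand+protein assembly with
# a zero-padded block-diagonal pair representation, a pair-biased
# transformer trunk, and the affinity / binding-site heads with losses.

#' Configuration for the complex-level model
#'
#' Ligand encoder, protein encoder and trunk share `d_model`, `n_heads` and
#' `d_pair` so representations concatenate without adapters.
#'
#' @param encoder Shared [encoder_config()] for the two molecule encoders.
#' @param trunk_layers Transformer layers in the complex trunk (4 at full
#'   scale).
#' @param protein_layers Depth of the substitute protein encoder (defaults
#'   to the shared encoder depth; the burial/pocket geometry it must
#'   represent benefits from extra layers).
#' @param lambda_site Weight of the binding-site BCE in the joint loss.
#' @param structure_mode Structural-feature ablation flag passed to the
#'   encoders (`"full"`, `"no_distance"`, `"no_position"`, `"none"`).
#' @param freeze_encoders Train only trunk + heads when TRUE.
#' @param seed Parameter-init seed.
#' @return List of class `pairbind_complex_config`.
#' @export
complex_config <- function(encoder = encoder_config(), trunk_layers = 4L,
                           lambda_site = 1.0, structure_mode = "full",
                           freeze_encoders = FALSE, seed = encoder$seed,
                           protein_layers = encoder$n_layers) {
  trunk <- encoder
  trunk$n_layers <- as.integer(trunk_layers)
  protein <- encoder
  protein$n_layers <- as.integer(protein_layers)
  structure(list(encoder = encoder, protein = protein, trunk = trunk,
                 lambda_site = lambda_site,
                 structure_mode = structure_mode,
                 freeze_encoders = freeze_encoders,
                 seed = as.integer(seed)),
            class = "pairbind_complex_config")
}

#' Initialise the full complex model
#'
#' Parameter prefixes: `lig.*` (ligand encoder), `prot.*` (substitute
#' protein encoder), `trunk.*` (complex transformer), `aff.*` / `site.*`
#' (prediction heads). A pretrained ligand encoder checkpoint can seed the
#' `lig.*` block.
#'
#' @param cfg [complex_config()].
#' @param pretrained_ligand Optional flat parameter list whose `lig.*`
#'   entries (or `enc.*` entries, renamed) override the fresh init.
#' @return List of class `pairbind_affinity_model` with `params`, `cfg`.
#' @export
init_complex_model <- function(cfg, pretrained_ligand = NULL) {
  with_seed_(cfg$seed, {
    d <- cfg$encoder$d_model
    p <- c(init_encoder_params(cfg$encoder, atom_vocabulary(), "lig",
                               seed = cfg$seed + 11L),
           init_encoder_params(cfg$protein, residue_vocabulary(), "prot",
                               seed = cfg$seed + 22L),
           with_seed_(cfg$seed + 33L, init_stack_params(cfg$trunk, "trunk")))
    with_seed_(cfg$seed + 44L, {
      p[["aff.W1"]] <- .winit(2 * d, d)
      p[["aff.b1"]] <- rep(0, d)
      p[["aff.W2"]] <- .winit(d, 1, scale = 0.01)
      p[["aff.b2"]] <- rep(0, 1)
      p[["site.W1"]] <- .winit(d, 32)
      p[["site.b1"]] <- rep(0, 32)
      p[["site.W2"]] <- .winit(32, 1, scale = 0.01)
      p[["site.b2"]] <- rep(0, 1)
    })
    if (!is.null(pretrained_ligand)) {
      src <- pretrained_ligand
      enc_names <- grep("^enc\\.", names(src), value = TRUE)
      if (length(enc_names) > 0) {
        names(src)[match(enc_names, names(src))] <-
          sub("^enc\\.", "lig.", enc_names)
      }
      for (nm in intersect(names(src), names(p))) p[[nm]] <- src[[nm]]
    }
    structure(list(params = p, cfg = cfg), class = "pairbind_affinity_model")
  })
}

#' Encode a protein with the bundled substitute encoder
#'
#' Residue types are embedded; pair features are the distance and
#' spatial-position features of the C-alpha trace in chain order (the
#' `[CLS]` token sits at the C-alpha centroid), run through the same
#' pair-biased transformer architecture as the ligand. Any external protein
#' encoder producing `(n+1) x d_model` single and `(n+1)^2 x d_pair` pair
#' representations with `[CLS]` first can be plugged in via `encoder_fn`.
#'
#' @param params Flat parameter list.
#' @param protein A [protein_input()].
#' @param cfg [encoder_config()] of the protein encoder.
#' @param prefix Parameter prefix (default `"prot"`).
#' @param structure_mode Ablation flag.
#' @param encoder_fn Optional replacement encoder with the same signature
#'   and return contract as this function.
#' @return Same contract as [encode_molecule()].
#' @export
encode_protein <- function(params, protein, cfg, prefix = "prot",
                           structure_mode = "full", encoder_fn = NULL) {
  if (!is.null(encoder_fn))
    return(encoder_fn(params, protein, cfg, prefix, structure_mode))
  pf <- pair_features(list(atom_types = protein$residue_types,
                           coords = protein$ca_coords),
                      include_cls = TRUE)
  # residue [CLS] reuses the shared special token in the residue vocabulary
  encode_molecule(params, pf, cfg, prefix = prefix,
                  vocab = residue_vocabulary(),
                  structure_mode = structure_mode)
}

#' Assemble ligand and protein encoder outputs into a complex representation
#'
#' Single representations are stacked ligand-first (each `[CLS]`-first);
#' the pair representation is block-diagonal with exact zeros off-diagonal,
#' standing in for the unknown ligand-protein interactions.
#'
#' @param lig Output of [encode_molecule()] for the ligand.
#' @param prot Output of [encode_protein()].
#' @return List with `single`, `pair` (flattened `T^2 x d_pair`), `Tl`,
#'   `Tp`, `Tn` and index helpers.
#' @export
assemble_complex <- function(lig, prot) {
  if (ncol(lig$single) != ncol(prot$single) ||
      ncol(lig$pair) != ncol(prot$pair))
    stop("ligand and protein encoder widths do not match")
  Tl <- lig$Tn; Tp <- prot$Tn; Tn <- Tl + Tp
  s <- rbind(lig$single, prot$single)
  z <- cpp_assemble_pair(lig$pair, prot$pair, Tl, Tp)
  list(single = s, pair = z, Tl = Tl, Tp = Tp, Tn = Tn,
       lig_cls = 1L, prot_cls = Tl + 1L,
       prot_rows = (Tl + 2L):Tn)
}

# Split a complex-level gradient back into ligand / protein blocks.
.split_complex_grads <- function(ds, dz, Tl, Tp) {
  sp <- cpp_split_pair(dz, Tl, Tp)
  list(ds_lig = ds[seq_len(Tl), , drop = FALSE],
       ds_prot = ds[(Tl + 1):(Tl + Tp), , drop = FALSE],
       dz_lig = sp$lig, dz_prot = sp$prot)
}

#' Precompute pair featurizations for a set of complexes
#'
#' Featurization is parameter-free, so training loops can compute it once
#' per complex instead of once per step.
#'
#' @param samples List of complex samples (`ligand`, `protein`, ...).
#' @return The samples with `pf_lig` / `pf_prot` fields attached.
#' @export
precompute_features <- function(samples) {
  lapply(samples, function(s) {
    if (is.null(s$pf_lig)) s$pf_lig <- pair_features(s$ligand)
    if (is.null(s$pf_prot))
      s$pf_prot <- pair_features(list(atom_types = s$protein$residue_types,
                                      coords = s$protein$ca_coords))
    s
  })
}

# Forward through trunk + heads. Returns prediction, probabilities, caches.
.complex_forward <- function(params, cfg, sample, want_cache = TRUE) {
  pf <- if (!is.null(sample$pf_lig)) sample$pf_lig
        else pair_features(sample$ligand, include_cls = TRUE)
  lig <- encode_molecule(params, pf, cfg$encoder, prefix = "lig",
                         structure_mode = cfg$structure_mode)
  prot_cfg <- if (is.null(cfg$protein)) cfg$encoder else cfg$protein
  prot <- if (!is.null(sample$pf_prot))
    encode_molecule(params, sample$pf_prot, prot_cfg, prefix = "prot",
                    vocab = residue_vocabulary(),
                    structure_mode = cfg$structure_mode)
  else encode_protein(params, sample$protein, prot_cfg,
                      structure_mode = cfg$structure_mode)
  cx <- assemble_complex(lig, prot)
  tr <- encoder_stack_forward(params, "trunk", cx$single, cx$pair, cfg$trunk)
  s_up <- tr$s
  hcat <- c(s_up[cx$lig_cls, ], s_up[cx$prot_cls, ])
  Ha <- drop(hcat %*% params[["aff.W1"]]) + params[["aff.b1"]]
  Ga <- gelu(Ha)
  yhat <- sum(Ga * params[["aff.W2"]][, 1]) + params[["aff.b2"]][1]
  Sp <- s_up[cx$prot_rows, , drop = FALSE]
  Hs <- Sp %*% params[["site.W1"]] + rep(params[["site.b1"]], each = nrow(Sp))
  Gs <- gelu(Hs)
  slogit <- drop(Gs %*% params[["site.W2"]]) + params[["site.b2"]][1]
  probs <- sigmoid_(slogit)
  out <- list(yhat = yhat, site_probs = probs, Tn = cx$Tn)
  if (want_cache)
    out$cache <- list(lig = lig, prot = prot, cx = cx, tr = tr, hcat = hcat,
                      Ha = Ha, Ga = Ga, Sp = Sp, Hs = Hs, Gs = Gs,
                      slogit = slogit)
  out
}

#' Predict binding affinity for one complex
#'
#' Runs both encoders, assembles the block representation, applies the
#' trunk, and maps the concatenated ligand/protein `[CLS]` embeddings
#' through the affinity head.
#'
#' @param model A `pairbind_affinity_model`.
#' @param sample List with `ligand` ([molecule()]) and `protein`
#'   ([protein_input()]).
#' @return Predicted pK (scalar).
#' @export
affinity_forward <- function(model, sample) {
  out <- .complex_forward(model$params, model$cfg, sample, want_cache = FALSE)
  if (!is.finite(out$yhat)) stop("non-finite affinity prediction")
  st <- model$label_stats
  if (is.null(st)) st <- c(mu = 0, sd = 1)
  st[["mu"]] + st[["sd"]] * out$yhat
}

#' Predict per-residue binding-site probabilities
#'
#' @inheritParams affinity_forward
#' @return Numeric vector of length n (protein `[CLS]` excluded).
#' @export
binding_site_forward <- function(model, sample) {
  out <- .complex_forward(model$params, model$cfg, sample, want_cache = FALSE)
  out$site_probs
}

#' Affinity MSE and binding-site BCE losses
#'
#' @param yhat,y Predicted and true pK vectors.
#' @param site_probs,site_labels Lists (per complex) or vectors of
#'   per-residue probabilities and 0/1 labels (optional).
#' @param lambda Weight of the BCE term in the total.
#' @return List with `mse`, `bce`, `total`.
#' @export
affinity_losses <- function(yhat, y, site_probs = NULL, site_labels = NULL,
                            lambda = 1.0) {
  if (length(yhat) != length(y)) stop("prediction/label length mismatch")
  mse <- mean((yhat - y)^2)
  bce <- NA_real_
  if (!is.null(site_probs)) {
    p <- unlist(site_probs); lab <- unlist(site_labels)
    if (length(p) != length(lab)) stop("site prediction/label length mismatch")
    p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    bce <- -mean(lab * log(p) + (1 - lab) * log(1 - p))
  }
  total <- mse + if (is.na(bce)) 0 else lambda * bce
  list(mse = mse, bce = bce, total = total)
}

# Per-sample joint loss + parameter gradients for fine-tuning.
# tasks: "affinity", "site" or "both".
finetune_sample_grads <- function(params, cfg, sample, tasks = "both") {
  fw <- .complex_forward(params, cfg, sample, want_cache = TRUE)
  cc <- fw$cache; cx <- cc$cx
  d <- cfg$encoder$d_model
  use_aff <- tasks %in% c("affinity", "both")
  use_site <- tasks %in% c("site", "both")
  loss_mse <- if (use_aff) (fw$yhat - sample$pK)^2 else 0
  lab <- sample$site_labels
  loss_bce <- 0
  if (use_site) {
    p <- pmin(pmax(fw$site_probs, 1e-7), 1 - 1e-7)
    loss_bce <- -mean(lab * log(p) + (1 - lab) * log(1 - p))
  }
  loss <- loss_mse + cfg$lambda_site * loss_bce
  grads <- list()
  ds_up <- matrix(0, cx$Tn, d)
  # affinity head backward
  if (use_aff) {
    dyhat <- 2 * (fw$yhat - sample$pK)
    grads[["aff.W2"]] <- matrix(dyhat * cc$Ga, ncol = 1)
    grads[["aff.b2"]] <- dyhat
    dGa <- dyhat * params[["aff.W2"]][, 1]
    dHa <- dGa * gelu_grad(cc$Ha)
    grads[["aff.W1"]] <- outer(cc$hcat, dHa)
    grads[["aff.b1"]] <- dHa
    dhcat <- drop(params[["aff.W1"]] %*% dHa)
    ds_up[cx$lig_cls, ] <- ds_up[cx$lig_cls, ] + dhcat[seq_len(d)]
    ds_up[cx$prot_cls, ] <- ds_up[cx$prot_cls, ] + dhcat[d + seq_len(d)]
  }
  # site head backward
  if (use_site) {
    n_res <- length(lab)
    dlogit <- cfg$lambda_site * (sigmoid_(cc$slogit) - lab) / n_res
    grads[["site.W2"]] <- crossprod(cc$Gs, matrix(dlogit, ncol = 1))
    grads[["site.b2"]] <- sum(dlogit)
    dGs <- matrix(dlogit, ncol = 1) %*% t(params[["site.W2"]])
    dHs <- dGs * gelu_grad(cc$Hs)
    grads[["site.W1"]] <- crossprod(cc$Sp, dHs)
    grads[["site.b1"]] <- colSums(dHs)
    ds_up[cx$prot_rows, ] <- ds_up[cx$prot_rows, ] + dHs %*% t(params[["site.W1"]])
  }
  # trunk backward
  tb <- encoder_stack_backward(params, "trunk", cc$tr, ds_up, NULL, cfg$trunk)
  grads <- c(grads, tb$grads)
  if (!cfg$freeze_encoders) {
    sp <- .split_complex_grads(tb$ds0, tb$dz0, cx$Tl, cx$Tp)
    prot_cfg <- if (is.null(cfg$protein)) cfg$encoder else cfg$protein
    grads <- c(grads,
               encode_molecule_backward(params, cc$lig, sp$ds_lig,
                                        sp$dz_lig, cfg$encoder,
                                        prefix = "lig"),
               encode_molecule_backward(params, cc$prot, sp$ds_prot,
                                        sp$dz_prot, prot_cfg,
                                        prefix = "prot"))
  }
  list(loss = loss, mse = loss_mse, bce = loss_bce, grads = grads,
       yhat = fw$yhat, site_probs = fw$site_probs)
}
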