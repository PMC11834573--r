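# Pair-biased transformer encoder: atom/residue tokens are embedded into a
# single representation s; discretized pair features are embedded into a
# pair representation z that enters every attention layer as an additive
# per-head bias and is itself updated from the attention logits. Includes
# the three pretraining heads (type classification, distance recovery,
# coordinate denoising) and their losses, all with analytic backward passes.

#' Encoder configuration
#'
#' @param n_layers Number of transformer layers.
#' @param d_model Hidden width (divisible by `n_heads`).
#' @param n_heads Attention heads.
#' @param d_pair Pair-representation channels.
#' @param d_ffn Feed-forward width.
#' @param d_embed_pair Embedding width per discretized feature (distance +
#'   three position axes are concatenated).
#' @param d_pair_hidden Hidden width of the pair-init MLP.
#' @param d_head_hidden Hidden width of the pretraining heads.
#' @param n_dist_bins,n_pos_bins Bin counts (must match the binning scheme).
#' @param max_len Maximum token count accepted by [encode_molecule()].
#' @param seed Parameter-init seed recorded alongside the config.
#' @return List of class `pairbind_encoder_config`.
#' @export
encoder_config <- function(n_layers = 2L, d_model = 64L, n_heads = 4L,
                           d_pair = 16L, d_ffn = 4L * d_model,
                           d_embed_pair = 8L, d_pair_hidden = 32L,
                           d_head_hidden = 16L,
                           n_dist_bins = 33L, n_pos_bins = 22L,
                           max_len = 256L, seed = 1L) {
  if (d_model %% n_heads != 0) stop("d_model must be divisible by n_heads")
  structure(list(n_layers = as.integer(n_layers),
                 d_model = as.integer(d_model),
                 n_heads = as.integer(n_heads),
                 d_k = as.integer(d_model / n_heads),
                 d_pair = as.integer(d_pair), d_ffn = as.integer(d_ffn),
                 d_embed_pair = as.integer(d_embed_pair),
                 d_pair_hidden = as.integer(d_pair_hidden),
                 d_head_hidden = as.integer(d_head_hidden),
                 n_dist_bins = as.integer(n_dist_bins),
                 n_pos_bins = as.integer(n_pos_bins),
                 max_len = as.integer(max_len), seed = as.integer(seed)),
            class = "pairbind_encoder_config")
}

#' Full-scale pretraining configuration (15 layers, 512 hidden, 4 heads)
#' @param ... Overrides passed to [encoder_config()].
#' @export
encoder_config_full <- function(...) {
  encoder_config(n_layers = 15L, d_model = 512L, n_heads = 4L,
                 d_ffn = 2048L, ...)
}

# ---- Parameter initialisation --------------------------------------------

.layer_param_names <- c("ln1g", "ln1b", "Wq", "bq", "Wk", "bk", "Wv", "bv",
                        "Wo", "bo", "Wzb", "bzb", "Wup", "bup",
                        "ln2g", "ln2b", "W1", "b1", "W2", "b2")

# Transformer stack parameters under `prefix` (no embeddings).
init_stack_params <- function(cfg, prefix) {
  d <- cfg$d_model; H <- cfg$n_heads; dp <- cfg$d_pair; df <- cfg$d_ffn
  p <- list()
  for (l in seq_len(cfg$n_layers)) {
    k <- function(nm) sprintf("%s.l%d.%s", prefix, l, nm)
    p[[k("ln1g")]] <- rep(1, d); p[[k("ln1b")]] <- rep(0, d)
    p[[k("Wq")]] <- .winit(d, d); p[[k("bq")]] <- rep(0, d)
    p[[k("Wk")]] <- .winit(d, d); p[[k("bk")]] <- rep(0, d)
    p[[k("Wv")]] <- .winit(d, d); p[[k("bv")]] <- rep(0, d)
    p[[k("Wo")]] <- .winit(d, d); p[[k("bo")]] <- rep(0, d)
    p[[k("Wzb")]] <- .winit(dp, H); p[[k("bzb")]] <- rep(0, H)
    p[[k("Wup")]] <- .winit(H, dp, scale = 0.02); p[[k("bup")]] <- rep(0, dp)
    p[[k("ln2g")]] <- rep(1, d); p[[k("ln2b")]] <- rep(0, d)
    p[[k("W1")]] <- .winit(d, df); p[[k("b1")]] <- rep(0, df)
    p[[k("W2")]] <- .winit(df, d); p[[k("b2")]] <- rep(0, d)
  }
  p[[paste0(prefix, ".lnfg")]] <- rep(1, d)
  p[[paste0(prefix, ".lnfb")]] <- rep(0, d)
  p
}

#' Initialise encoder parameters
#'
#' @param cfg An [encoder_config()].
#' @param vocab Token vocabulary (character); rows of the embedding table.
#' @param prefix Name prefix for the flat parameter list.
#' @param seed Integer seed.
#' @return Flat named list of parameter arrays.
#' @export
init_encoder_params <- function(cfg, vocab = atom_vocabulary(),
                                prefix = "enc", seed = cfg$seed) {
  with_seed_(seed, {
    d <- cfg$d_model; de <- cfg$d_embed_pair
    p <- list()
    p[[paste0(prefix, ".Wemb")]] <- .winit(length(vocab), d, scale = 0.02)
    # pair-bin embeddings feed the attention bias directly (no intervening
    # normalisation), so they start at unit scale to make the geometric
    # bias active from the first step
    p[[paste0(prefix, ".ED")]] <- .winit(cfg$n_dist_bins, de, scale = 1)
    p[[paste0(prefix, ".EPx")]] <- .winit(cfg$n_pos_bins, de, scale = 1)
    p[[paste0(prefix, ".EPy")]] <- .winit(cfg$n_pos_bins, de, scale = 1)
    p[[paste0(prefix, ".EPz")]] <- .winit(cfg$n_pos_bins, de, scale = 1)
    p[[paste0(prefix, ".Wp1")]] <- .winit(4 * de, cfg$d_pair_hidden)
    p[[paste0(prefix, ".bp1")]] <- rep(0, cfg$d_pair_hidden)
    p[[paste0(prefix, ".Wp2")]] <- .winit(cfg$d_pair_hidden, cfg$d_pair)
    p[[paste0(prefix, ".bp2")]] <- rep(0, cfg$d_pair)
    c(p, init_stack_params(cfg, prefix))
  })
}

# ---- Pair-representation initialisation (Eq.-4-style MLP on embeddings) --

# Reference R implementation (parity-checked against the compiled path).
pair_init_forward_r <- function(params, prefix, D_bins, P_bins, cfg,
                                structure_mode = "full") {
  Tn <- nrow(D_bins)
  if (structure_mode == "none")
    return(list(z0 = matrix(0, Tn * Tn, cfg$d_pair),
                cache = list(mode = "none", Tn = Tn)))
  g <- function(nm) params[[paste0(prefix, ".", nm)]]
  de <- cfg$d_embed_pair
  dflat <- as.vector(D_bins) + 1L
  px <- as.vector(P_bins[, , 1]) + 1L
  py <- as.vector(P_bins[, , 2]) + 1L
  pz <- as.vector(P_bins[, , 3]) + 1L
  Ein <- cbind(g("ED")[dflat, , drop = FALSE],
               g("EPx")[px, , drop = FALSE],
               g("EPy")[py, , drop = FALSE],
               g("EPz")[pz, , drop = FALSE])
  if (structure_mode == "no_distance") Ein[, seq_len(de)] <- 0
  if (structure_mode == "no_position") Ein[, -seq_len(de)] <- 0
  H1 <- Ein %*% g("Wp1") + rep(g("bp1"), each = nrow(Ein))
  G <- gelu(H1)
  z0 <- G %*% g("Wp2") + rep(g("bp2"), each = nrow(Ein))
  list(z0 = z0, cache = list(mode = structure_mode, Ein = Ein, H1 = H1,
                             G = G, dflat = dflat, px = px, py = py,
                             pz = pz, Tn = Tn))
}

pair_init_backward_r <- function(params, prefix, cache, dz0, cfg) {
  if (cache$mode == "none") return(list())
  g <- function(nm) params[[paste0(prefix, ".", nm)]]
  de <- cfg$d_embed_pair
  grads <- list()
  grads[[paste0(prefix, ".Wp2")]] <- crossprod(cache$G, dz0)
  grads[[paste0(prefix, ".bp2")]] <- colSums(dz0)
  dG <- tcrossprod(dz0, g("Wp2"))
  dH1 <- dG * gelu_grad(cache$H1)
  grads[[paste0(prefix, ".Wp1")]] <- crossprod(cache$Ein, dH1)
  grads[[paste0(prefix, ".bp1")]] <- colSums(dH1)
  dEin <- tcrossprod(dH1, g("Wp1"))
  scatter <- function(block, idx, nrow_table) {
    out <- matrix(0, nrow_table, de)
    rs <- rowsum(block, group = idx)
    out[as.integer(rownames(rs)), ] <- rs
    out
  }
  if (cache$mode != "no_distance")
    grads[[paste0(prefix, ".ED")]] <-
      scatter(dEin[, seq_len(de), drop = FALSE], cache$dflat, cfg$n_dist_bins)
  if (cache$mode != "no_position") {
    grads[[paste0(prefix, ".EPx")]] <-
      scatter(dEin[, de + seq_len(de), drop = FALSE], cache$px, cfg$n_pos_bins)
    grads[[paste0(prefix, ".EPy")]] <-
      scatter(dEin[, 2 * de + seq_len(de), drop = FALSE], cache$py,
              cfg$n_pos_bins)
    grads[[paste0(prefix, ".EPz")]] <-
      scatter(dEin[, 3 * de + seq_len(de), drop = FALSE], cache$pz,
              cfg$n_pos_bins)
  }
  grads
}

.structure_mode_code <- function(mode) {
  switch(mode, full = 0L, no_distance = 1L, no_position = 2L,
         stop("unknown structure mode"))
}

pair_init_forward <- function(params, prefix, D_bins, P_bins, cfg,
                              structure_mode = "full") {
  Tn <- nrow(D_bins)
  if (structure_mode == "none")
    return(list(z0 = matrix(0, Tn * Tn, cfg$d_pair),
                cache = list(mode = "none", Tn = Tn)))
  g <- function(nm) params[[paste0(prefix, ".", nm)]]
  out <- cpp_pair_init_forward(as.vector(D_bins) + 1L,
                               as.vector(P_bins[, , 1]) + 1L,
                               as.vector(P_bins[, , 2]) + 1L,
                               as.vector(P_bins[, , 3]) + 1L,
                               g("ED"), g("EPx"), g("EPy"), g("EPz"),
                               g("Wp1"), g("bp1"), g("Wp2"), g("bp2"),
                               .structure_mode_code(structure_mode))
  list(z0 = out$z0, cache = list(mode = structure_mode, cpp = out$cache))
}

pair_init_backward <- function(params, prefix, cache, dz0, cfg) {
  if (cache$mode == "none") return(list())
  g <- function(nm) params[[paste0(prefix, ".", nm)]]
  res <- cpp_pair_init_backward(cache$cpp, dz0, g("Wp1"), g("Wp2"),
                                cfg$n_dist_bins, cfg$n_pos_bins)
  grads <- list()
  grads[[paste0(prefix, ".Wp1")]] <- res$Wp1
  grads[[paste0(prefix, ".bp1")]] <- as.numeric(res$bp1)
  grads[[paste0(prefix, ".Wp2")]] <- res$Wp2
  grads[[paste0(prefix, ".bp2")]] <- as.numeric(res$bp2)
  if (cache$mode != "no_distance")
    grads[[paste0(prefix, ".ED")]] <- res$ED
  if (cache$mode != "no_position") {
    grads[[paste0(prefix, ".EPx")]] <- res$EPx
    grads[[paste0(prefix, ".EPy")]] <- res$EPy
    grads[[paste0(prefix, ".EPz")]] <- res$EPz
  }
  grads
}

# ---- Transformer stack ----------------------------------------------------

# Forward through the pair-biased layers. s0: T x d, z0: T^2 x d_pair
# (column-major pair flattening: row i + (j-1)*T holds pair (i, j)).
# Reference R implementation; the compiled path below is the default and
# is held to exact parity with this one by the test suite.
encoder_stack_forward_r <- function(params, prefix, s0, z0, cfg) {
  Tn <- nrow(s0); H <- cfg$n_heads; dk <- cfg$d_k
  s <- s0; z <- z0
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    g <- function(nm) params[[sprintf("%s.l%d.%s", prefix, l, nm)]]
    ln1 <- layernorm_fwd(s, g("ln1g"), g("ln1b"))
    h1 <- ln1$y
    Q <- h1 %*% g("Wq") + rep(g("bq"), each = Tn)
    K <- h1 %*% g("Wk") + rep(g("bk"), each = Tn)
    V <- h1 %*% g("Wv") + rep(g("bv"), each = Tn)
    B <- z %*% g("Wzb") + rep(g("bzb"), each = Tn * Tn)
    A_list <- vector("list", H)
    Lflat <- matrix(0, Tn * Tn, H)
    O <- matrix(0, Tn, cfg$d_model)
    for (h in seq_len(H)) {
      idx <- ((h - 1) * dk + 1):(h * dk)
      logits <- tcrossprod(Q[, idx, drop = FALSE],
                           K[, idx, drop = FALSE]) / sqrt(dk) +
        matrix(B[, h], Tn, Tn)
      A <- softmax_rows(logits)
      A_list[[h]] <- A
      Lflat[, h] <- as.vector(logits)
      O[, idx] <- A %*% V[, idx, drop = FALSE]
    }
    attn <- O %*% g("Wo") + rep(g("bo"), each = Tn)
    s1 <- s + attn
    z_next <- z + Lflat %*% g("Wup") + rep(g("bup"), each = Tn * Tn)
    ln2 <- layernorm_fwd(s1, g("ln2g"), g("ln2b"))
    h2 <- ln2$y
    Hf <- h2 %*% g("W1") + rep(g("b1"), each = Tn)
    Gf <- gelu(Hf)
    s2 <- s1 + Gf %*% g("W2") + rep(g("b2"), each = Tn)
    caches[[l]] <- list(x = s, ln1 = ln1, h1 = h1, Q = Q, K = K, V = V,
                        A = A_list, Lflat = Lflat, z_prev = z, O = O,
                        s1 = s1, ln2 = ln2, h2 = h2, Hf = Hf, Gf = Gf)
    s <- s2; z <- z_next
  }
  lnf <- layernorm_fwd(s, params[[paste0(prefix, ".lnfg")]],
                       params[[paste0(prefix, ".lnfb")]])
  list(s = lnf$y, z = z, caches = caches, lnf = lnf, s_pre = s)
}

encoder_stack_backward_r <- function(params, prefix, fwd, ds_out, dz_out, cfg) {
  Tn <- nrow(ds_out); H <- cfg$n_heads; dk <- cfg$d_k
  grads <- list()
  lnfb <- layernorm_bwd(ds_out, fwd$lnf, params[[paste0(prefix, ".lnfg")]])
  grads[[paste0(prefix, ".lnfg")]] <- lnfb$dg
  grads[[paste0(prefix, ".lnfb")]] <- lnfb$db
  ds <- lnfb$dX
  dz <- if (is.null(dz_out)) matrix(0, Tn * Tn, cfg$d_pair) else dz_out
  for (l in rev(seq_len(cfg$n_layers))) {
    g <- function(nm) params[[sprintf("%s.l%d.%s", prefix, l, nm)]]
    k <- function(nm) sprintf("%s.l%d.%s", prefix, l, nm)
    cc <- fwd$caches[[l]]
    # FFN sublayer
    grads[[k("W2")]] <- crossprod(cc$Gf, ds)
    grads[[k("b2")]] <- colSums(ds)
    dGf <- tcrossprod(ds, g("W2"))
    dHf <- dGf * gelu_grad(cc$Hf)
    grads[[k("W1")]] <- crossprod(cc$h2, dHf)
    grads[[k("b1")]] <- colSums(dHf)
    dh2 <- tcrossprod(dHf, g("W1"))
    ln2b <- layernorm_bwd(dh2, cc$ln2, g("ln2g"))
    grads[[k("ln2g")]] <- ln2b$dg
    grads[[k("ln2b")]] <- ln2b$db
    ds1 <- ds + ln2b$dX
    # pair update path
    grads[[k("Wup")]] <- crossprod(cc$Lflat, dz)
    grads[[k("bup")]] <- colSums(dz)
    dLup <- tcrossprod(dz, g("Wup")) # T^2 x H
    # attention sublayer
    grads[[k("Wo")]] <- crossprod(cc$O, ds1)
    grads[[k("bo")]] <- colSums(ds1)
    dO <- tcrossprod(ds1, g("Wo"))
    dQ <- matrix(0, Tn, cfg$d_model)
    dK <- matrix(0, Tn, cfg$d_model)
    dV <- matrix(0, Tn, cfg$d_model)
    dB <- matrix(0, Tn * Tn, H)
    for (h in seq_len(H)) {
      idx <- ((h - 1) * dk + 1):(h * dk)
      A <- cc$A[[h]]
      dout <- dO[, idx, drop = FALSE]
      dA <- tcrossprod(dout, cc$V[, idx, drop = FALSE])
      dV[, idx] <- crossprod(A, dout)
      dlog <- A * (dA - rowSums(dA * A)) + matrix(dLup[, h], Tn, Tn)
      dQ[, idx] <- dlog %*% cc$K[, idx, drop = FALSE] / sqrt(dk)
      dK[, idx] <- crossprod(dlog, cc$Q[, idx, drop = FALSE]) / sqrt(dk)
      dB[, h] <- as.vector(dlog)
    }
    dzp <- dz + tcrossprod(dB, g("Wzb"))
    grads[[k("Wzb")]] <- crossprod(cc$z_prev, dB)
    grads[[k("bzb")]] <- colSums(dB)
    grads[[k("Wq")]] <- crossprod(cc$h1, dQ)
    grads[[k("bq")]] <- colSums(dQ)
    grads[[k("Wk")]] <- crossprod(cc$h1, dK)
    grads[[k("bk")]] <- colSums(dK)
    grads[[k("Wv")]] <- crossprod(cc$h1, dV)
    grads[[k("bv")]] <- colSums(dV)
    dh1 <- tcrossprod(dQ, g("Wq")) + tcrossprod(dK, g("Wk")) + tcrossprod(dV, g("Wv"))
    ln1b <- layernorm_bwd(dh1, cc$ln1, g("ln1g"))
    grads[[k("ln1g")]] <- ln1b$dg
    grads[[k("ln1b")]] <- ln1b$db
    ds <- ds1 + ln1b$dX
    dz <- dzp
  }
  list(grads = grads, ds0 = ds, dz0 = dz)
}

# Per-layer parameter lists for the compiled stack.
.stack_layer_list <- function(params, prefix, n_layers) {
  lapply(seq_len(n_layers), function(l) {
    out <- lapply(.layer_param_names, function(nm)
      params[[sprintf("%s.l%d.%s", prefix, l, nm)]])
    names(out) <- .layer_param_names
    out
  })
}

# Compiled forward (RcppArmadillo); cache lives C++-side behind an XPtr.
encoder_stack_forward <- function(params, prefix, s0, z0, cfg,
                                  want_cache = TRUE) {
  layers <- .stack_layer_list(params, prefix, cfg$n_layers)
  out <- cpp_stack_forward(s0, z0, layers,
                           params[[paste0(prefix, ".lnfg")]],
                           params[[paste0(prefix, ".lnfb")]],
                           cfg$n_heads, want_cache)
  list(s = out$s, z = out$z, cpp = out$cache)
}

encoder_stack_backward <- function(params, prefix, fwd, ds_out, dz_out,
                                   cfg) {
  layers <- .stack_layer_list(params, prefix, cfg$n_layers)
  res <- cpp_stack_backward(fwd$cpp, layers,
                            params[[paste0(prefix, ".lnfg")]], ds_out,
                            dz_out, cfg$n_heads, cfg$d_pair)
  grads <- list()
  for (l in seq_len(cfg$n_layers)) {
    gl <- res$grads[[l]]
    for (nm in .layer_param_names) {
      key <- sprintf("%s.l%d.%s", prefix, l, nm)
      g <- gl[[nm]]
      grads[[key]] <- if (is.matrix(params[[key]])) g else as.numeric(g)
    }
  }
  grads[[paste0(prefix, ".lnfg")]] <- as.numeric(res$lnfg)
  grads[[paste0(prefix, ".lnfb")]] <- as.numeric(res$lnfb)
  list(grads = grads, ds0 = res$ds0, dz0 = res$dz0)
}

# ---- Molecule-level encoding ---------------------------------------------

#' Encode a featurized molecule
#'
#' Embeds the token sequence (with `[CLS]` first), builds the initial pair
#' representation from the discretized features, and runs the pair-biased
#' transformer stack.
#'
#' @param params Flat parameter list from [init_encoder_params()].
#' @param pf [pair_features()] output (computed with `include_cls = TRUE`).
#' @param cfg [encoder_config()].
#' @param prefix Parameter prefix.
#' @param vocab Token vocabulary matching the embedding table.
#' @param structure_mode One of `"full"`, `"no_distance"`, `"no_position"`,
#'   `"none"` (structural-feature ablations).
#' @return List with `single` (`T x d_model`, `[CLS]` row first), `pair`
#'   (`T^2 x d_pair`, column-major pair flattening), `Tn`, and `cache` for
#'   the backward pass.
#' @export
encode_molecule <- function(params, pf, cfg, prefix = "enc",
                            vocab = atom_vocabulary(),
                            structure_mode = "full") {
  tokens <- pf$tokens
  Tn <- length(tokens)
  if (Tn > cfg$max_len) stop("sequence length exceeds configured maximum")
  idx <- match(tokens, vocab)
  if (anyNA(idx)) stop("token outside vocabulary")
  s0 <- params[[paste0(prefix, ".Wemb")]][idx, , drop = FALSE]
  pi_ <- pair_init_forward(params, prefix, pf$D_bins, pf$P_bins, cfg,
                           structure_mode)
  st <- encoder_stack_forward(params, prefix, s0, pi_$z0, cfg)
  list(single = st$s, pair = st$z, Tn = Tn,
       cache = list(idx = idx, pair_cache = pi_$cache, stack = st,
                    structure_mode = structure_mode))
}

# Backward for encode_molecule. ds/dz are grads w.r.t. single/pair outputs.
encode_molecule_backward <- function(params, enc, ds, dz, cfg,
                                     prefix = "enc") {
  sb <- encoder_stack_backward(params, prefix, enc$cache$stack, ds, dz, cfg)
  grads <- sb$grads
  # token embeddings
  demb <- matrix(0, nrow(params[[paste0(prefix, ".Wemb")]]), cfg$d_model)
  rs <- rowsum(sb$ds0, group = enc$cache$idx)
  demb[as.integer(rownames(rs)), ] <- rs
  grads[[paste0(prefix, ".Wemb")]] <- demb
  c(grads, pair_init_backward(params, prefix, enc$cache$pair_cache,
                              sb$dz0, cfg))
}

# ---- Pretraining heads ----------------------------------------------------

#' Initialise the three pretraining heads
#'
#' @param cfg [encoder_config()].
#' @param vocab Token vocabulary (the classification head predicts over it).
#' @param prefix Parameter prefix.
#' @param seed Integer seed.
#' @return Flat named parameter list.
#' @export
init_pretrain_heads <- function(cfg, vocab = atom_vocabulary(),
                                prefix = "heads", seed = cfg$seed + 1L) {
  with_seed_(seed, {
    d <- cfg$d_model; dp <- cfg$d_pair; dh <- cfg$d_head_hidden
    p <- list()
    p[[paste0(prefix, ".Wt")]] <- .winit(d, length(vocab))
    p[[paste0(prefix, ".bt")]] <- rep(0, length(vocab))
    p[[paste0(prefix, ".Wd1")]] <- .winit(dp, dh)
    p[[paste0(prefix, ".bd1")]] <- rep(0, dh)
    p[[paste0(prefix, ".Wd2")]] <- .winit(dh, 1)
    p[[paste0(prefix, ".bd2")]] <- rep(0, 1)
    p[[paste0(prefix, ".Wc1")]] <- .winit(d, dh)
    p[[paste0(prefix, ".bc1")]] <- rep(0, dh)
    p[[paste0(prefix, ".Wc2")]] <- .winit(dh, 3, scale = 0.01)
    p[[paste0(prefix, ".bc2")]] <- rep(0, 3)
    p
  })
}

# transpose permutation of column-major pair flattening
.pair_transpose_idx <- function(Tn) as.vector(t(matrix(seq_len(Tn * Tn), Tn, Tn)))

#' Run the three pretraining heads
#'
#' Type head: linear on atom rows of `s`. Distance head: symmetrised pair
#' representation through a small MLP with softplus output (predictions are
#' exactly symmetric and non-negative). Coordinate head: residual
#' displacement added to the noisy input coordinates.
#'
#' @param params Head parameters ([init_pretrain_heads()]).
#' @param enc Output of [encode_molecule()].
#' @param noisy_coords `m x 3` noisy coordinates the displacement is added
#'   to.
#' @param cfg Encoder config.
#' @param prefix Head parameter prefix.
#' @return List with `type_logits` (`m x |vocab|`), `dist` (`T x T`),
#'   `coords` (`m x 3`), and `cache`.
#' @export
pretrain_heads_forward <- function(params, enc, noisy_coords, cfg,
                                   prefix = "heads") {
  g <- function(nm) params[[paste0(prefix, ".", nm)]]
  s <- enc$single; z <- enc$pair; Tn <- enc$Tn
  satoms <- s[-1, , drop = FALSE]
  type_logits <- satoms %*% g("Wt") + rep(g("bt"), each = Tn - 1)
  tidx <- .pair_transpose_idx(Tn)
  zsym <- (z + z[tidx, , drop = FALSE]) / 2
  Hd <- zsym %*% g("Wd1") + rep(g("bd1"), each = Tn * Tn)
  Gd <- gelu(Hd)
  rawd <- Gd %*% g("Wd2") + g("bd2")[1]
  dist <- matrix(softplus_(rawd), Tn, Tn)
  Hc <- satoms %*% g("Wc1") + rep(g("bc1"), each = Tn - 1)
  Gc <- gelu(Hc)
  delta <- Gc %*% g("Wc2") + rep(g("bc2"), each = Tn - 1)
  coords <- noisy_coords + delta
  list(type_logits = type_logits, dist = dist, coords = coords,
       cache = list(satoms = satoms, zsym = zsym, Hd = Hd, Gd = Gd,
                    rawd = rawd, Hc = Hc, Gc = Gc, tidx = tidx, Tn = Tn))
}

# ---- Pretraining loss + full backward ------------------------------------

#' Three-task pretraining loss and gradients for one corrupted molecule
#'
#' Featurizes the noisy coordinates, encodes, runs the heads, and returns
#' the masked-type cross-entropy, smooth-L1 distance loss (over real-atom
#' pairs, off-diagonal), smooth-L1 coordinate loss, their weighted total,
#' and the gradient of the total w.r.t. all encoder + head parameters.
#'
#' @param params Combined encoder + head parameter list.
#' @param corrupted A [corrupt_molecule()] sample.
#' @param cfg Encoder config.
#' @param loss_weights Named weights `type`, `dist`, `coord`.
#' @param scheme Binning scheme.
#' @param structure_mode Structural ablation flag.
#' @param prefix,head_prefix Parameter prefixes.
#' @param vocab Token vocabulary.
#' @param want_grads Compute gradients (set FALSE for evaluation).
#' @return List with `loss`, `components`, `grads`.
#' @export
pretrain_loss <- function(params, corrupted, cfg,
                          loss_weights = c(type = 1, dist = 1, coord = 1),
                          scheme = binning_scheme(),
                          structure_mode = "full",
                          prefix = "enc", head_prefix = "heads",
                          vocab = atom_vocabulary(), want_grads = TRUE) {
  m <- nrow(corrupted$noisy_coords)
  mol_in <- list(atom_types = corrupted$input_types,
                 coords = corrupted$noisy_coords)
  pf <- pair_features(mol_in, include_cls = TRUE, scheme = scheme)
  enc <- encode_molecule(params, pf, cfg, prefix = prefix, vocab = vocab,
                         structure_mode = structure_mode)
  heads <- pretrain_heads_forward(params, enc, corrupted$noisy_coords, cfg,
                                  prefix = head_prefix)
  Tn <- enc$Tn
  # --- type loss (masked positions only)
  midx <- corrupted$mask_indices
  P <- softmax_rows(heads$type_logits[midx, , drop = FALSE])
  tgt <- match(corrupted$target_types[midx], vocab)
  picked <- P[cbind(seq_along(midx), tgt)]
  loss_type <- mean(-log(pmax(picked, 1e-12)))
  # --- distance loss (clean target incl. clean centroid [CLS])
  clean_ext <- rbind(colMeans(corrupted$clean_coords), corrupted$clean_coords)
  Dclean <- compute_distance_matrix(clean_ext)
  maskD <- matrix(0, Tn, Tn)
  maskD[2:Tn, 2:Tn] <- 1
  diag(maskD) <- 0
  sl_d <- smooth_l1(heads$dist, Dclean, maskD)
  # --- coordinate loss
  sl_c <- smooth_l1(heads$coords, corrupted$clean_coords)
  w <- loss_weights
  total <- w[["type"]] * loss_type + w[["dist"]] * sl_d$loss +
    w[["coord"]] * sl_c$loss
  out <- list(loss = total,
              components = c(type = loss_type, dist = sl_d$loss,
                             coord = sl_c$loss))
  if (!want_grads) return(out)

  g <- function(nm) params[[paste0(head_prefix, ".", nm)]]
  hc <- heads$cache
  grads <- list()
  # type head backward
  dlogits <- matrix(0, Tn - 1, length(vocab))
  dP <- P
  dP[cbind(seq_along(midx), tgt)] <- dP[cbind(seq_along(midx), tgt)] - 1
  dlogits[midx, ] <- w[["type"]] * dP / length(midx)
  grads[[paste0(head_prefix, ".Wt")]] <- crossprod(hc$satoms, dlogits)
  grads[[paste0(head_prefix, ".bt")]] <- colSums(dlogits)
  dsatoms <- tcrossprod(dlogits, g("Wt"))
  # distance head backward
  dDhat <- w[["dist"]] * sl_d$grad
  drawd <- matrix(as.vector(dDhat) * sigmoid_(as.vector(hc$rawd)), ncol = 1)
  grads[[paste0(head_prefix, ".Wd2")]] <- crossprod(hc$Gd, drawd)
  grads[[paste0(head_prefix, ".bd2")]] <- sum(drawd)
  dGd <- tcrossprod(drawd, g("Wd2"))
  dHd <- dGd * gelu_grad(hc$Hd)
  grads[[paste0(head_prefix, ".Wd1")]] <- crossprod(hc$zsym, dHd)
  grads[[paste0(head_prefix, ".bd1")]] <- colSums(dHd)
  dzsym <- tcrossprod(dHd, g("Wd1"))
  dz <- (dzsym + dzsym[hc$tidx, , drop = FALSE]) / 2
  # coordinate head backward
  ddelta <- w[["coord"]] * sl_c$grad
  grads[[paste0(head_prefix, ".Wc2")]] <- crossprod(hc$Gc, ddelta)
  grads[[paste0(head_prefix, ".bc2")]] <- colSums(ddelta)
  dGc <- tcrossprod(ddelta, g("Wc2"))
  dHc <- dGc * gelu_grad(hc$Hc)
  grads[[paste0(head_prefix, ".Wc1")]] <- crossprod(hc$satoms, dHc)
  grads[[paste0(head_prefix, ".bc1")]] <- colSums(dHc)
  dsatoms <- dsatoms + tcrossprod(dHc, g("Wc1"))
  # into the encoder
  ds <- rbind(0, dsatoms)
  grads <- c(grads, encode_molecule_backward(params, enc, ds, dz, cfg,
                                             prefix = prefix))
  out$grads <- grads
  out
}
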