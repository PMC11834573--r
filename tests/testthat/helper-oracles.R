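# Independent oracles and small fixtures used across the suite.

# Random proper rotation matrix (uses the current RNG stream).
random_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

apply_rigid <- function(coords, R, t) sweep(coords %*% t(R), 2, t, "+")

# Brute-force double-loop distance matrix.
bf_distance_matrix <- function(coords) {
  m <- nrow(coords)
  D <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    D[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
  D
}

# Analytic Lennard-Jones gradient assembled from dV/dr, with the same
# Lorentz-Berthelot combining and 0.5 A clamp as the implementation.
analytic_lj_gradient <- function(coords, types, params) {
  m <- nrow(coords)
  lk <- pairbind:::.lj_lookup(params, types)
  grad <- matrix(0, m, 3)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    sig <- (lk$sigma[i] + lk$sigma[j]) / 2
    eps <- sqrt(lk$epsilon[i] * lk$epsilon[j])
    dvec <- coords[i, ] - coords[j, ]
    r <- sqrt(sum(dvec^2))
    if (r < 0.5) next  # inside the clamp the potential is flat in r
    dVdr <- 4 * eps * (-12 * sig^12 / r^13 + 6 * sig^6 / r^7)
    grad[i, ] <- grad[i, ] + dVdr * dvec / r
  }
  grad
}

# Tie-corrected Mann-Whitney AUC via mid-ranks.
mw_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  P <- sum(labels == 1); N <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

# Brute-force binding-site labels over every (heavy atom, ligand atom) pair.
bf_site_labels <- function(protein, ligand, cutoff) {
  n <- length(protein$residue_types)
  labels <- integer(n)
  for (i in seq_len(n)) {
    h <- protein$heavy_atom_coords[[i]]
    hit <- FALSE
    for (a in seq_len(nrow(h))) for (b in seq_len(nrow(ligand$coords))) {
      if (sqrt(sum((h[a, ] - ligand$coords[b, ])^2)) < cutoff) hit <- TRUE
    }
    labels[i] <- as.integer(hit)
  }
  labels
}

# Brute-force residue-ligand contact-pair count.
bf_contact_pairs <- function(protein, ligand, cutoff) {
  total <- 0L
  for (h in protein$heavy_atom_coords) {
    for (b in seq_len(nrow(ligand$coords))) {
      dmin <- min(sqrt(rowSums(sweep(h, 2, ligand$coords[b, ])^2)))
      if (dmin < cutoff) total <- total + 1L
    }
  }
  total
}

# Tiny configs shared by encoder tests (small enough for numerical grads).
tiny_encoder_config <- function(seed = 3L) {
  encoder_config(n_layers = 2L, d_model = 8L, n_heads = 2L, d_pair = 4L,
                 d_ffn = 16L, d_embed_pair = 3L, d_pair_hidden = 6L,
                 d_head_hidden = 5L, seed = seed)
}

tiny_complex_config <- function(seed = 3L, ...) {
  complex_config(tiny_encoder_config(seed), trunk_layers = 1L, ...)
}

# Reference (oracle) vanilla transformer layer: plain multi-head
# self-attention + FFN with pre-LN, written independently of the package's
# stack; used to check the zero-bias reduction.
vanilla_layer_forward <- function(params, prefix, l, s) {
  g <- function(nm) params[[sprintf("%s.l%d.%s", prefix, l, nm)]]
  Tn <- nrow(s); d <- ncol(s)
  ln <- function(X, gam, bet) {
    t(apply(X, 1, function(r) gam * (r - mean(r)) /
              sqrt(mean((r - mean(r))^2) + 1e-5) + bet))
  }
  h1 <- ln(s, g("ln1g"), g("ln1b"))
  Q <- h1 %*% g("Wq") + rep(g("bq"), each = Tn)
  K <- h1 %*% g("Wk") + rep(g("bk"), each = Tn)
  V <- h1 %*% g("Wv") + rep(g("bv"), each = Tn)
  H <- length(g("bzb")); dk <- d / H
  O <- matrix(0, Tn, d)
  for (h in seq_len(H)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    logit <- Q[, idx] %*% t(K[, idx]) / sqrt(dk)
    A <- exp(logit - apply(logit, 1, max))
    A <- A / rowSums(A)
    O[, idx] <- A %*% V[, idx]
  }
  s1 <- s + O %*% g("Wo") + rep(g("bo"), each = Tn)
  h2 <- ln(s1, g("ln2g"), g("ln2b"))
  act <- function(x) x / (1 + exp(-1.702 * x))
  s1 + act(h2 %*% g("W1") + rep(g("b1"), each = Tn)) %*% g("W2") +
    rep(g("b2"), each = Tn)
}
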