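# Rotation/translation-invariant pair featurization: interatomic distance
# matrix, local-frame spatial-position matrix, and their discretization into
# the integer bins that seed the pair representation.

#' Interatomic distance matrix
#'
#' @param coords Numeric `m x 3` coordinate matrix (Angstrom).
#' @return Symmetric `m x m` matrix of Euclidean distances with zero diagonal.
#' @export
compute_distance_matrix <- function(coords) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (ncol(coords) != 3L) stop("coords must be m x 3")
  m <- nrow(coords)
  if (m == 1L) return(matrix(0, 1, 1))
  D <- as.matrix(stats::dist(coords))
  dimnames(D) <- NULL
  D
}

# Collinearity tolerance: sin of the angle between v1 and v2.
.collinear_sin_tol <- 1e-6

#' Local orthonormal frame for one atom
#'
#' The frame at atom `i` is built from its chain neighbours `(i-1, i, i+1)`
#' in input order: `v1 = x_i - x_{i-1}` and `v2 = x_{i+1} - x_i` are
#' Gram-Schmidt orthogonalised into the first two axes, and the third axis is
#' the right-handed cross product `u1 x u2` (the chord `v3 = v1 + v2` is a
#' linear combination of `v1` and `v2`, so its Gram-Schmidt residual vanishes
#' identically and cannot supply the third direction). Chain ends reuse the
#' nearest interior stencil: atom 1 uses atoms (1,2,3) and the last atom
#' mirrors that backwards.
#'
#' Degenerate stencils (collinear `v1`, `v2`, fewer than 3 atoms) fall back
#' to the canonical world frame and are flagged.
#'
#' @param coords `m x 3` coordinates.
#' @param i Atom index (1-based).
#' @return List with `R` (3 x 3 matrix, rows = frame axes) and `degenerate`
#'   (logical flag).
#' @export
build_local_frame <- function(coords, i) {
  coords <- as.matrix(coords)
  m <- nrow(coords)
  canonical <- list(R = diag(3), degenerate = TRUE)
  if (m < 3L) return(canonical)
  if (i < 1L || i > m) stop("atom index out of range")
  # stencil: interior (i-1, i, i+1); first atom borrows the forward pair,
  # the last atom keeps v1 = x_m - x_{m-1} and borrows v2 backwards
  if (i == 1L) {
    v1 <- coords[2L, ] - coords[1L, ]
    v2 <- coords[3L, ] - coords[2L, ]
  } else if (i == m) {
    v1 <- coords[m, ] - coords[m - 1L, ]
    v2 <- coords[m - 1L, ] - coords[m - 2L, ]
  } else {
    v1 <- coords[i, ] - coords[i - 1L, ]
    v2 <- coords[i + 1L, ] - coords[i, ]
  }
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-12 || n2 < 1e-12) return(canonical)
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  if (sqrt(sum(cr^2)) / (n1 * n2) < .collinear_sin_tol) return(canonical)
  u1 <- v1 / n1
  u2 <- v2 - sum(v2 * u1) * u1
  u2 <- u2 / sqrt(sum(u2^2))
  u3 <- c(u1[2] * u2[3] - u1[3] * u2[2],
          u1[3] * u2[1] - u1[1] * u2[3],
          u1[1] * u2[2] - u1[2] * u2[1])
  list(R = rbind(u1, u2, u3, deparse.level = 0), degenerate = FALSE)
}

#' Spatial-position matrix
#'
#' Entry `[i, j, ]` is the position of atom `j` expressed in atom `i`'s local
#' frame: `R_i (x_j - x_i)`. Because each frame is orthonormal the row norms
#' reproduce the distance matrix, and the whole tensor is invariant under
#' rigid motions of the molecule.
#'
#' @param coords `m x 3` coordinates.
#' @param frames Optional precomputed list of frames (as from
#'   [build_local_frame()]); computed when `NULL`.
#' @return List with `P` (`m x m x 3` array) and `degenerate` (logical vector
#'   flagging atoms that fell back to the canonical frame).
#' @export
compute_spatial_position_matrix <- function(coords, frames = NULL) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  m <- nrow(coords)
  if (is.null(frames)) frames <- lapply(seq_len(m), function(i) build_local_frame(coords, i))
  P <- array(0, dim = c(m, m, 3))
  for (i in seq_len(m)) {
    # degenerate frames (collinear stencils, [CLS], tiny molecules) carry no
    # well-defined orientation: their rows stay zero so the tensor remains
    # rigid-motion invariant (the distance matrix keeps their radial info)
    if (frames[[i]]$degenerate) next
    rel <- sweep(coords, 2, coords[i, ])     # m x 3, rows x_j - x_i
    P[i, , ] <- rel %*% t(frames[[i]]$R)
  }
  list(P = P, degenerate = vapply(frames, `[[`, logical(1), "degenerate"))
}

#' Binning scheme for pair-feature discretization
#'
#' Distances: uniform 0.5 Angstrom bins over `[0, 16)` plus one overflow bin
#' (33 bins, 0-based indices 0..32). Signed position components: uniform
#' 1 Angstrom bins over `[-10, 10)` with an underflow and an overflow bin
#' (22 bins, 0-based indices 0..21, index 0 = underflow).
#'
#' @param dist_max,dist_step,pos_max,pos_step Bin geometry (Angstrom).
#' @return List describing both binnings, serialisable as JSON/YAML so runs
#'   are bit-reproducible.
#' @export
binning_scheme <- function(dist_max = 16, dist_step = 0.5,
                           pos_max = 10, pos_step = 1) {
  dist_edges <- seq(0, dist_max, by = dist_step)
  pos_edges <- seq(-pos_max, pos_max, by = pos_step)
  list(dist_edges = dist_edges,
       n_dist_bins = length(dist_edges),              # interior + overflow
       pos_edges = pos_edges,
       n_pos_bins = length(pos_edges) + 1L)           # + underflow + overflow
}

#' Discretize distance and position features
#'
#' @param D `m' x m'` distance matrix.
#' @param P `m' x m' x 3` spatial-position array.
#' @param scheme Binning scheme from [binning_scheme()].
#' @return List with integer arrays `D_bins` (0-based, overflow =
#'   `n_dist_bins - 1`) and `P_bins` (0-based, underflow = 0).
#' @export
discretize_pair_features <- function(D, P, scheme = binning_scheme()) {
  if (!identical(dim(D), dim(P)[1:2]))
    stop("D and P disagree on the number of atoms")
  # snap to 1e-6 A before binning: frame construction produces components
  # that are exactly zero up to floating-point noise, and binning must not
  # flip at such edges under rigid motions
  D <- round(D, 6)
  P <- round(P, 6)
  db <- findInterval(D, scheme$dist_edges)            # 1..n for d >= 0
  db <- pmin(db - 1L, scheme$n_dist_bins - 1L)        # 0-based, clamp overflow
  D_bins <- array(as.integer(db), dim = dim(D))
  pb <- findInterval(P, scheme$pos_edges)             # 0 = underflow
  pb <- pmin(pb, scheme$n_pos_bins - 2L)              # clamp to overflow bin
  # interior indices 1..20, overflow n_pos_bins-1
  pb[P >= scheme$pos_edges[length(scheme$pos_edges)]] <- scheme$n_pos_bins - 1L
  P_bins <- array(as.integer(pb), dim = dim(P))
  list(D_bins = D_bins, P_bins = P_bins)
}

#' Full pair featurization of a molecule
#'
#' Optionally prepends the `[CLS]` token (coordinates = atom centroid,
#' canonical frame), computes the distance and spatial-position matrices,
#' and discretizes both.
#'
#' @param mol A [molecule()] (or any `m x 3` coordinate matrix with
#'   `atom_types` supplied separately).
#' @param include_cls Prepend the `[CLS]` row/column.
#' @param scheme Binning scheme.
#' @return List of class `pairbind_pair_features` with fields `D`, `P`,
#'   `D_bins`, `P_bins`, `tokens` (type sequence incl. `[CLS]` when present),
#'   `degenerate`, `scheme`, `m` (number of real atoms).
#' @export
pair_features <- function(mol, include_cls = TRUE, scheme = binning_scheme()) {
  coords <- as.matrix(mol$coords)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  types <- mol$atom_types
  m <- nrow(coords)
  out <- cpp_pair_features(coords, include_cls,
                           scheme$dist_edges[2] - scheme$dist_edges[1],
                           scheme$n_dist_bins,
                           max(scheme$pos_edges),
                           scheme$pos_edges[2] - scheme$pos_edges[1],
                           scheme$n_pos_bins)
  tokens <- if (include_cls) c(atom_cls_token(), types) else types
  structure(list(D = out$D, P = out$P,
                 D_bins = out$D_bins, P_bins = out$P_bins,
                 tokens = tokens, degenerate = out$degenerate,
                 scheme = scheme, m = m, include_cls = include_cls),
            class = "pairbind_pair_features")
}

# Reference R pipeline (parity-checked against the compiled featurizer).
pair_features_r <- function(mol, include_cls = TRUE,
                            scheme = binning_scheme()) {
  coords <- mol$coords
  types <- mol$atom_types
  m <- nrow(coords)
  frames <- lapply(seq_len(m), function(i) build_local_frame(coords, i))
  if (include_cls) {
    centroid <- colMeans(coords)
    coords <- rbind(centroid, coords, deparse.level = 0)
    types <- c(atom_cls_token(), types)
    frames <- c(list(list(R = diag(3), degenerate = TRUE)), frames)
  }
  D <- compute_distance_matrix(coords)
  sp <- compute_spatial_position_matrix(coords, frames)
  bins <- discretize_pair_features(D, sp$P, scheme)
  structure(list(D = D, P = sp$P,
                 D_bins = bins$D_bins, P_bins = bins$P_bins,
                 tokens = types, degenerate = sp$degenerate,
                 scheme = scheme, m = m, include_cls = include_cls),
            class = "pairbind_pair_features")
}
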