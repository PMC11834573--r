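# Physics-guided corruption operators for self-supervised pretraining:
# Lennard-Jones energetics, finite-difference gradients, gradient-directed
# coordinate noise and random-ratio atom-type masking.

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Load a Lennard-Jones parameter table
#'
#' The bundled UFF-like defaults cover the full atom vocabulary; a custom
#' CSV with columns `type, sigma_angstrom, epsilon_kcal_mol` may be given.
#' Pairwise parameters use Lorentz-Berthelot combining:
#' `sigma_ij = (sigma_i + sigma_j)/2`, `epsilon_ij = sqrt(epsilon_i epsilon_j)`.
#'
#' @param path Optional CSV path; defaults to the packaged table.
#' @return Object of class `pairbind_lj_params`: data frame plus lookup.
#' @export
load_lj_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lj_params.csv", package = "pairbind")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("type", "sigma_angstrom", "epsilon_kcal_mol") %in% names(tab)))
  if (any(tab$sigma_angstrom <= 0) || any(tab$epsilon_kcal_mol <= 0))
    stop("sigma and epsilon must be positive")
  structure(list(table = tab,
                 sigma = stats::setNames(tab$sigma_angstrom, tab$type),
                 epsilon = stats::setNames(tab$epsilon_kcal_mol, tab$type),
                 combining = "lorentz-berthelot"),
            class = "pairbind_lj_params")
}

.lj_lookup <- function(params, types) {
  types[!(types %in% names(params$sigma))] <- atom_unk_token()
  list(sigma = unname(params$sigma[types]),
       epsilon = unname(params$epsilon[types]))
}

#' Lennard-Jones pair potential
#'
#' `V(r) = 4 epsilon [ (sigma/r)^12 - (sigma/r)^6 ]`. Zero at `r = sigma`,
#' minimum `-epsilon` at `r = 2^(1/6) sigma`.
#'
#' @param r Interatomic distance (Angstrom), must be positive.
#' @param epsilon Well depth (kcal/mol).
#' @param sigma Zero-crossing distance (Angstrom).
#' @return Energy in kcal/mol (vectorised over `r`).
#' @export
lj_potential <- function(r, epsilon, sigma) {
  if (any(r <= 0)) stop("r must be positive")
  sr6 <- (sigma / r)^6
  4 * epsilon * (sr6^2 - sr6)
}

# Minimum-distance clamp (Angstrom) applied inside the total potential so
# corrupted/overlapping geometries cannot overflow.
.lj_r_clamp <- 0.5

# Precompute the pairwise interaction lists for a molecule.
.lj_pairs <- function(types, params) {
  m <- length(types)
  if (m < 2L) return(NULL)
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  p <- .lj_lookup(params, types)
  list(i = idx[, 1], j = idx[, 2],
       sigma = (p$sigma[idx[, 1]] + p$sigma[idx[, 2]]) / 2,
       epsilon = sqrt(p$epsilon[idx[, 1]] * p$epsilon[idx[, 2]]))
}

#' Total Lennard-Jones energy of a conformation
#'
#' Sum of the pair potential over all unordered atom pairs with
#' Lorentz-Berthelot combining; distances are clamped below at 0.5 Angstrom
#' for numerical safety.
#'
#' @param coords `m x 3` coordinates (Angstrom).
#' @param types Atom-type symbols (length m).
#' @param params [load_lj_params()] table.
#' @return Scalar energy (kcal/mol).
#' @export
total_lj_energy <- function(coords, types, params = load_lj_params()) {
  coords <- as.matrix(coords)
  pr <- .lj_pairs(types, params)
  if (is.null(pr)) return(0)
  d <- sqrt(rowSums((coords[pr$i, , drop = FALSE] -
                     coords[pr$j, , drop = FALSE])^2))
  d <- pmax(d, .lj_r_clamp)
  sum(lj_potential(d, pr$epsilon, pr$sigma))
}

#' Finite-difference gradient of the Lennard-Jones energy
#'
#' Central differences `(V(x + h e_k) - V(x - h e_k)) / (2h)` per Cartesian
#' coordinate. Only the pair terms involving the perturbed atom change, so
#' each difference is evaluated on that atom's interaction list (numerically
#' identical to differencing the full sum). Accuracy is O(h^2).
#'
#' @param coords `m x 3` coordinates.
#' @param types Atom-type symbols.
#' @param params LJ parameter table.
#' @param h Step size in Angstrom (default `1e-4`).
#' @return List with `grad` (`m x 3` matrix, kcal/mol/Angstrom) and
#'   `clamped` (logical: some pair sat below the distance clamp).
#' @export
fd_potential_gradient <- function(coords, types, params = load_lj_params(),
                                  h = 1e-4) {
  if (h <= 0) stop("h must be positive")
  coords <- as.matrix(coords)
  m <- nrow(coords)
  grad <- matrix(0, m, 3)
  if (m < 2L) return(list(grad = grad, clamped = FALSE))
  p <- .lj_lookup(params, types)
  clamped <- FALSE
  for (a in seq_len(m)) {
    others <- setdiff(seq_len(m), a)
    sig <- (p$sigma[a] + p$sigma[others]) / 2
    eps <- sqrt(p$epsilon[a] * p$epsilon[others])
    rel <- sweep(coords[others, , drop = FALSE], 2, coords[a, ])
    for (k in 1:3) {
      dp <- rel; dp[, k] <- dp[, k] - h
      dm <- rel; dm[, k] <- dm[, k] + h
      rp <- pmax(sqrt(rowSums(dp^2)), .lj_r_clamp)
      rm_ <- pmax(sqrt(rowSums(dm^2)), .lj_r_clamp)
      if (any(rp == .lj_r_clamp) || any(rm_ == .lj_r_clamp)) clamped <- TRUE
      grad[a, k] <- (sum(lj_potential(rp, eps, sig)) -
                     sum(lj_potential(rm_, eps, sig))) / (2 * h)
    }
  }
  list(grad = grad, clamped = clamped)
}

#' Gradient-directed coordinate noise
#'
#' `x_noisy = x + eta * grad / ||grad||_F + xi`, with `xi` i.i.d.
#' `Normal(0, xi_std^2)` per coordinate. The normalisation uses the global
#' Frobenius norm of the gradient, so `eta` is the total displacement budget
#' in Angstrom; when the gradient is numerically zero the directed term is
#' dropped.
#'
#' @param coords `m x 3` clean coordinates.
#' @param gradient `m x 3` potential gradient.
#' @param eta Directed displacement scale (Angstrom, >= 0).
#' @param xi_std Isotropic noise standard deviation (Angstrom, >= 0).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return `m x 3` noisy coordinates.
#' @export
apply_gradient_noise <- function(coords, gradient, eta, xi_std, seed = NULL) {
  coords <- as.matrix(coords)
  gradient <- as.matrix(gradient)
  if (!identical(dim(coords), dim(gradient)))
    stop("gradient shape must match coords")
  if (eta < 0 || xi_std < 0) stop("eta and xi_std must be non-negative")
  gnorm <- sqrt(sum(gradient^2))
  out <- coords
  if (eta > 0 && gnorm >= 1e-12)
    out <- out + eta * gradient / gnorm
  if (xi_std > 0) {
    xi <- with_seed_(seed, matrix(stats::rnorm(length(coords), 0, xi_std),
                                  nrow(coords), 3))
    out <- out + xi
  }
  out
}

#' Random-ratio atom-type masking
#'
#' A masking ratio is drawn uniformly from `ratio_range`, then
#' `k = max(1, round(ratio * m))` atom indices are chosen uniformly without
#' replacement and their types replaced by `[MASK]`.
#'
#' @param types Atom-type symbols (length m >= 1).
#' @param ratio_range `c(lo, hi)` with `0 <= lo <= hi <= 1`.
#' @param seed Optional integer seed.
#' @return List with `masked_types` and `mask_indices` (1-based).
#' @export
mask_atom_types <- function(types, ratio_range = c(0.1, 0.5), seed = NULL) {
  m <- length(types)
  if (m < 1L) stop("empty molecule")
  lo <- ratio_range[1]; hi <- ratio_range[2]
  if (lo < 0 || hi > 1 || lo > hi) stop("invalid ratio_range")
  with_seed_(seed, {
    ratio <- stats::runif(1, lo, hi)
    k <- max(1L, as.integer(round(ratio * m)))
    idx <- sample.int(m, k)
    masked <- types
    masked[idx] <- atom_mask_token()
    list(masked_types = masked, mask_indices = sort(idx))
  })
}

#' Corrupt a molecule for the three denoising tasks
#'
#' Applies atom-type masking and Lennard-Jones-gradient-directed coordinate
#' noise; the clean structure is kept as the denoising target.
#'
#' @param mol A [molecule()].
#' @param params LJ parameter table.
#' @param eta_range `eta` is drawn uniformly from this range per molecule
#'   (Angstrom).
#' @param xi_std Isotropic noise std (Angstrom).
#' @param mask_ratio_range Masking ratio range.
#' @param h Finite-difference step.
#' @param seed Optional integer seed.
#' @return List of class `pairbind_corrupted` with `noisy_coords`,
#'   `clean_coords`, `input_types`, `target_types`, `mask_indices`,
#'   `noise_meta` (eta, xi_std, gradient Frobenius norm, clamped flag).
#' @export
corrupt_molecule <- function(mol, params = load_lj_params(),
                             eta_range = c(0.1, 0.5), xi_std = 0.05,
                             mask_ratio_range = c(0.1, 0.5), h = 1e-4,
                             seed = NULL) {
  with_seed_(seed, {
    msk <- mask_atom_types(mol$atom_types, mask_ratio_range, seed = NULL)
    eta <- stats::runif(1, eta_range[1], eta_range[2])
    g <- fd_potential_gradient(mol$coords, mol$atom_types, params, h = h)
    noisy <- apply_gradient_noise(mol$coords, g$grad, eta, xi_std, seed = NULL)
    structure(list(noisy_coords = noisy, clean_coords = mol$coords,
                   input_types = msk$masked_types,
                   target_types = mol$atom_types,
                   mask_indices = msk$mask_indices,
                   noise_meta = list(eta = eta, xi_std = xi_std,
                                     grad_norm = sqrt(sum(g$grad^2)),
                                     clamped = g$clamped)),
              class = "pairbind_corrupted")
  })
}
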