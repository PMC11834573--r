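# Synthetic fixtures and benchmarks: plausible bond-length conformers from a
# self-avoiding walk, toy protein chains with a planted ligand pocket, and
# affinity labels from a known contact-count rule (for parameter recovery).

#' Default atom-type sampling distribution
#'
#' Drug-like composition concentrated on organic elements, with a small
#' probability spread across the rest of the vocabulary.
#' @return Named probability vector over the 26 element types.
#' @export
default_atom_type_probs <- function() {
  vocab <- atom_vocabulary()
  vocab <- vocab[!vocab %in% c("[UNK]", "[MASK]", "[CLS]")]
  p <- stats::setNames(rep(0.002, length(vocab)), vocab)
  p[c("C", "H", "N", "O", "S", "F", "Cl", "P", "Br")] <-
    c(0.40, 0.18, 0.12, 0.15, 0.04, 0.03, 0.02, 0.01, 0.016)
  p / sum(p)
}

#' Specification for synthetic data generation
#'
#' @param n_complexes Number of complexes for dataset helpers.
#' @param atom_count_range Ligand size range (atoms).
#' @param type_probs Atom-type distribution.
#' @param bond_step Mean self-avoiding-walk step (Angstrom).
#' @param min_atom_sep Minimum allowed interatomic distance (Angstrom).
#' @param protein_len_range Residue-count range for toy chains.
#' @param pocket_radius Max ligand-centroid offset from the pocket C-alpha.
#' @param affinity_a,affinity_b Affinity rule `pK = a * contacts + b + noise`.
#' @param noise_sd Gaussian label noise (pK units).
#' @param site_cutoff Binding-site labeling cutoff (Angstrom).
#' @return List of class `pairbind_synth_spec`.
#' @export
synthetic_spec <- function(n_complexes = 100L,
                           atom_count_range = c(10L, 30L),
                           type_probs = default_atom_type_probs(),
                           bond_step = 1.5,
                           min_atom_sep = 1.0,
                           protein_len_range = c(20L, 60L),
                           pocket_radius = 2.0,
                           affinity_a = 0.05,
                           affinity_b = 4.0,
                           noise_sd = 0.25,
                           site_cutoff = 6.0) {
  structure(list(n_complexes = as.integer(n_complexes),
                 atom_count_range = as.integer(atom_count_range),
                 type_probs = type_probs,
                 bond_step = bond_step, min_atom_sep = min_atom_sep,
                 protein_len_range = as.integer(protein_len_range),
                 pocket_radius = pocket_radius,
                 affinity_a = affinity_a, affinity_b = affinity_b,
                 noise_sd = noise_sd, site_cutoff = site_cutoff),
            class = "pairbind_synth_spec")
}

# Self-avoiding 3D random walk; returns k x 3 coordinates or NULL on failure.
.saw_walk <- function(k, step_mean, step_sd, min_sep, max_tries = 100L) {
  pos <- matrix(0, k, 3)
  for (t in seq_len(k)[-1]) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      len <- max(stats::rnorm(1, step_mean, step_sd), min_sep)
      cand <- pos[t - 1, ] + len * u
      d2 <- rowSums(sweep(pos[seq_len(t - 1), , drop = FALSE], 2, cand)^2)
      if (min(d2) >= min_sep^2) { pos[t, ] <- cand; placed <- TRUE; break }
    }
    if (!placed) return(NULL)
  }
  pos
}

#' Generate a random conformer
#'
#' A self-avoiding random walk with step length `Normal(bond_step, 0.1)`
#' Angstrom, rejecting any atom pair closer than `min_atom_sep`; atom types
#' are drawn from the spec distribution.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Optional integer seed.
#' @param n_atoms Optional fixed atom count (default drawn from the spec
#'   range).
#' @return A [molecule()].
#' @export
generate_conformer <- function(spec = synthetic_spec(), seed = NULL,
                               n_atoms = NULL) {
  with_seed_(seed, {
    if (is.null(n_atoms)) {
      r <- spec$atom_count_range
      n_atoms <- sample(r[1]:r[2], 1)
    }
    coords <- NULL
    for (attempt in 1:20) {
      coords <- .saw_walk(n_atoms, spec$bond_step, 0.1, spec$min_atom_sep)
      if (!is.null(coords)) break
    }
    if (is.null(coords)) stop("conformer rejection budget exceeded")
    types <- sample(names(spec$type_probs), n_atoms, replace = TRUE,
                    prob = spec$type_probs)
    molecule(types, coords, id = sprintf("synth%06d",
                                         sample.int(999999L, 1)))
  })
}

# Toy protein: self-avoiding C-alpha walk at ~3.8 A steps, 1-4 heavy atoms
# per residue (first one the C-alpha itself).
.generate_toy_protein <- function(spec) {
  r <- spec$protein_len_range
  n <- sample(r[1]:r[2], 1)
  ca <- NULL
  for (attempt in 1:20) {
    ca <- .saw_walk(n, 3.8, 0.2, 3.4)
    if (!is.null(ca)) break
  }
  if (is.null(ca)) stop("protein walk rejection budget exceeded")
  heavy <- lapply(seq_len(n), function(i) {
    k <- sample(1:4, 1)
    extra <- if (k > 1) {
      dirs <- matrix(stats::rnorm(3 * (k - 1)), k - 1, 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      sweep(dirs * stats::runif(k - 1, 1.0, 2.2), 2, ca[i, ], "+")
    } else NULL
    rbind(ca[i, ], extra, deparse.level = 0)
  })
  types <- sample(residue_vocabulary()[1:20], n, replace = TRUE)
  protein_input(types, heavy, ca,
                id = sprintf("prot%06d", sample.int(999999L, 1)))
}

#' Generate a toy protein-ligand complex with a planted pocket
#'
#' The protein is a self-avoiding C-alpha walk (3.8 Angstrom steps) with 1-4
#' pseudo heavy atoms per residue. The pocket is the most buried residue
#' (C-alpha closest to the chain centroid) -- mimicking ligands binding in
#' cavities, and, importantly, making the pocket location a deterministic
#' function of the protein structure alone. The ligand conformer is centred
#' at that C-alpha plus a random offset shorter than `pocket_radius`.
#' Binding-site labels come from [label_binding_sites()] at the spec cutoff,
#' and the affinity label follows the planted rule
#' `pK = a * contacts + b + Normal(0, noise_sd)` clipped to `[0, 14]`, where
#' `contacts` is [count_contact_pairs()] at the same cutoff.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Optional integer seed.
#' @return List of class `pairbind_complex_sample` with `protein`, `ligand`,
#'   `site_labels`, `pK`, `contacts`, `pocket_residue`, `id`.
#' @export
generate_toy_complex <- function(spec = synthetic_spec(), seed = NULL) {
  with_seed_(seed, {
    for (attempt in 1:20) {
      prot <- .generate_toy_protein(spec)
      lig <- generate_conformer(spec)
      centroid <- colMeans(prot$ca_coords)
      pocket <- which.min(rowSums(sweep(prot$ca_coords, 2, centroid)^2))
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      target <- prot$ca_coords[pocket, ] +
        u * stats::runif(1, 0, spec$pocket_radius)
      shift <- target - colMeans(lig$coords)
      lig$coords <- sweep(lig$coords, 2, shift, "+")
      labels <- label_binding_sites(prot, lig, spec$site_cutoff)
      if (sum(labels) >= 1) {
        contacts <- count_contact_pairs(prot, lig, spec$site_cutoff)
        pk <- spec$affinity_a * contacts + spec$affinity_b +
          stats::rnorm(1, 0, spec$noise_sd)
        pk <- min(max(pk, 0), 14)
        id <- sprintf("cplx%06d", sample.int(999999L, 1))
        lig$id <- id; prot$id <- id
        return(structure(list(protein = prot, ligand = lig,
                              site_labels = labels, pK = pk,
                              contacts = contacts, pocket_residue = pocket,
                              id = id),
                         class = "pairbind_complex_sample"))
      }
    }
    stop("failed to generate a complex with at least one contact")
  })
}

#' Generate a list of toy complexes
#'
#' @param n Number of complexes.
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed (sequential generation under one RNG stream).
#' @return List of `pairbind_complex_sample`.
#' @export
generate_complex_dataset <- function(n, spec = synthetic_spec(), seed = 1L) {
  with_seed_(seed, lapply(seq_len(n), function(i) generate_toy_complex(spec)))
}

#' Generate a list of ligand conformers (pretraining corpus stand-in)
#'
#' @param n Number of molecules.
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return List of [molecule()].
#' @export
generate_molecule_dataset <- function(n, spec = synthetic_spec(), seed = 1L) {
  with_seed_(seed, lapply(seq_len(n), function(i) generate_conformer(spec)))
}

#' Materialise a synthetic benchmark on disk
#'
#' Writes per-complex SDF ligands and PDB proteins, an affinity label CSV,
#' train/val/test split files and a JSON manifest recording the spec and
#' seed, in exactly the formats the I/O module reads.
#'
#' @param spec A [synthetic_spec()] (`n_complexes` complexes are generated).
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param fractions Train/val/test fractions (must sum to 1).
#' @param force Overwrite an existing directory.
#' @return Invisibly, the manifest list.
#' @export
make_benchmark <- function(spec = synthetic_spec(), out_dir, seed = 1L,
                           fractions = c(train = 0.7, val = 0.15, test = 0.15),
                           force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop("output directory exists; use force = TRUE to overwrite")
  dir.create(file.path(out_dir, "ligands"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "proteins"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "splits"), showWarnings = FALSE)
  samples <- generate_complex_dataset(spec$n_complexes, spec, seed = seed)
  ids <- vapply(samples, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {  # ids are random draws; disambiguate
    ids <- sprintf("%s_%03d", ids, seq_along(ids))
    for (i in seq_along(samples)) {
      samples[[i]]$id <- ids[i]
      samples[[i]]$ligand$id <- ids[i]
      samples[[i]]$protein$id <- ids[i]
    }
  }
  for (s in samples) {
    write_ligand_sdf(s$ligand, file.path(out_dir, "ligands",
                                         paste0(s$id, ".sdf")))
    write_protein_pdb(s$protein, file.path(out_dir, "proteins",
                                           paste0(s$id, ".pdb")))
  }
  write_affinity_labels(data.frame(id = ids,
                                   pK = vapply(samples, `[[`, numeric(1),
                                               "pK")),
                        file.path(out_dir, "labels.csv"))
  n <- length(ids)
  n_train <- round(fractions[["train"]] * n)
  n_val <- round(fractions[["val"]] * n)
  assign_ids <- with_seed_(seed + 1L, sample(ids))
  split_ids <- list(train = assign_ids[seq_len(n_train)],
                    val = assign_ids[n_train + seq_len(n_val)],
                    test = assign_ids[(n_train + n_val + 1):n])
  for (nm in names(split_ids))
    write_split_file(split_ids[[nm]],
                     file.path(out_dir, "splits", paste0(nm, ".txt")))
  manifest <- list(spec = unclass(spec), seed = seed,
                   n_complexes = n, splits = lapply(split_ids, length),
                   package = "pairbind")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load a benchmark directory written by [make_benchmark()]
#'
#' @param dir Benchmark directory.
#' @return List with `samples` (named list of complexes, site labels
#'   recomputed from the structures) and `splits` (ID vectors).
#' @export
load_benchmark <- function(dir) {
  labels <- read_affinity_labels(file.path(dir, "labels.csv"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cutoff <- manifest$spec$site_cutoff
  samples <- lapply(seq_len(nrow(labels)), function(i) {
    id <- labels$id[i]
    lig <- read_ligand_sdf(file.path(dir, "ligands", paste0(id, ".sdf")))
    prot <- read_protein_pdb(file.path(dir, "proteins", paste0(id, ".pdb")))
    structure(list(protein = prot, ligand = lig,
                   site_labels = label_binding_sites(prot, lig, cutoff),
                   pK = labels$pK[i], id = id),
              class = "pairbind_complex_sample")
  })
  names(samples) <- labels$id
  splits <- lapply(c(train = "train", val = "val", test = "test"),
                   function(nm) read_split_file(
                     file.path(dir, "splits", paste0(nm, ".txt"))))
  list(samples = samples, splits = splits, manifest = manifest)
}
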