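# Structure readers/writers, affinity unit conversions, binding-site
# labeling and cross-validation split handling.

#' Construct a protein input
#'
#' @param residue_types Length-n one-letter residue codes (unknowns -> "X").
#' @param heavy_atom_coords List of `k_i x 3` heavy-atom coordinate matrices,
#'   one per residue (each residue needs at least one heavy atom).
#' @param ca_coords `n x 3` C-alpha coordinates.
#' @param id Identifier.
#' @return Object of class `pairbind_protein`.
#' @export
protein_input <- function(residue_types, heavy_atom_coords, ca_coords,
                          id = "protein") {
  ca_coords <- as.matrix(ca_coords)
  n <- length(residue_types)
  if (n < 1L) stop("protein needs at least one residue")
  if (length(heavy_atom_coords) != n || nrow(ca_coords) != n)
    stop("residue_types, heavy_atom_coords and ca_coords disagree on n")
  if (any(vapply(heavy_atom_coords, nrow, integer(1)) < 1L))
    stop("every residue needs at least one heavy atom")
  known <- residue_vocabulary()
  residue_types <- ifelse(residue_types %in% known, residue_types, "X")
  structure(list(residue_types = residue_types,
                 heavy_atom_coords = lapply(heavy_atom_coords, function(x) {
                   x <- as.matrix(x); storage.mode(x) <- "double"; x
                 }),
                 ca_coords = ca_coords, id = as.character(id)),
            class = "pairbind_protein")
}

#' @export
print.pairbind_protein <- function(x, ...) {
  cat(sprintf("<protein %s: %d residues>\n", x$id, length(x$residue_types)))
  invisible(x)
}

# ---- SDF (V2000) ----------------------------------------------------------

.parse_sdf_block <- function(lines, offset) {
  if (length(lines) < 4)
    stop(sprintf("SDF block starting at line %d is truncated", offset))
  counts <- lines[4]
  m <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  if (is.na(m))
    stop(sprintf("unparsable counts line at line %d: '%s'", offset + 3, counts))
  if (m == 0L) stop(sprintf("zero atoms in SDF block at line %d", offset))
  if (length(lines) < 4 + m)
    stop(sprintf("SDF block at line %d declares %d atoms but ends early",
                 offset, m))
  atom_lines <- lines[5:(4 + m)]
  x <- suppressWarnings(as.numeric(substr(atom_lines, 1, 10)))
  y <- suppressWarnings(as.numeric(substr(atom_lines, 11, 20)))
  z <- suppressWarnings(as.numeric(substr(atom_lines, 21, 30)))
  sym <- trimws(substr(atom_lines, 32, 34))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | sym == "")
  if (length(bad) > 0)
    stop(sprintf("unparsable atom record at line %d", offset + 3 + bad[1]))
  id <- trimws(lines[1])
  if (id == "") id <- "mol"
  coords <- cbind(x, y, z)
  dimnames(coords) <- NULL
  molecule(normalize_atom_types(sym), coords, id = id, validate = FALSE)
}

#' Read ligand(s) from an SDF (V2000) file
#'
#' Element symbols are mapped onto the 26-type vocabulary (`[UNK]` for
#' anything else, with a warning); coordinates are taken as Angstrom.
#'
#' @param path SDF file.
#' @param index Which molecule block to return (default first).
#' @param keep_hydrogens Retain H atoms (default TRUE).
#' @return A [molecule()].
#' @export
read_ligand_sdf <- function(path, index = 1L, keep_hydrogens = TRUE) {
  mols <- read_ligand_sdf_all(path, keep_hydrogens = keep_hydrogens)
  if (index < 1L || index > length(mols))
    stop(sprintf("file has %d molecule(s); index %d out of range",
                 length(mols), index))
  mols[[index]]
}

#' @rdname read_ligand_sdf
#' @export
read_ligand_sdf_all <- function(path, keep_hydrogens = TRUE) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty SDF file")
  seps <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, seps + 1L)
  ends <- c(seps - 1L, length(lines))
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  blocks <- Map(function(s, e) lines[s:e], starts, ends)
  nonempty <- vapply(blocks, function(b) any(nzchar(trimws(b))), logical(1))
  blocks <- blocks[nonempty]; starts <- starts[nonempty]
  if (length(blocks) == 0) stop("no molecule blocks found")
  mols <- Map(.parse_sdf_block, blocks, starts)
  if (!keep_hydrogens) {
    mols <- lapply(mols, function(mol) {
      keep_at <- mol$atom_types != "H"
      if (!any(keep_at)) stop("molecule has only hydrogens")
      molecule(mol$atom_types[keep_at], mol$coords[keep_at, , drop = FALSE],
               id = mol$id, validate = FALSE)
    })
  }
  unname(mols)
}

#' Write ligand(s) to an SDF (V2000) file
#'
#' Molecules are written bond-less (conformer sets carry no bond
#' perception); coordinates use the standard fixed-width `%10.4f` fields, so
#' round-trips preserve them to 1e-4 Angstrom.
#'
#' @param mols A [molecule()] or list of molecules.
#' @param path Output file.
#' @export
write_ligand_sdf <- function(mols, path) {
  if (inherits(mols, "pairbind_molecule")) mols <- list(mols)
  out <- unlist(lapply(mols, function(mol) {
    m <- nrow(mol$coords)
    sym <- ifelse(mol$atom_types %in% c(atom_unk_token(), atom_mask_token()),
                  "Xx", mol$atom_types)
    c(mol$id,
      "  pairbind",
      "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", m, 0L),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              mol$coords[, 1], mol$coords[, 2], mol$coords[, 3], sym),
      "M  END",
      "$$$$")
  }))
  writeLines(out, path)
}

# ---- PDB ------------------------------------------------------------------

#' Read a protein from a PDB file
#'
#' Uses `bio3d::read.pdb`: first model, `ATOM` records only (HETATM
#' excluded), heavy atoms only. Alternate locations are resolved per atom by
#' highest occupancy, ties broken in favour of altloc `A`. Residues are kept
#' in chain order; insertion-code residues are distinct; residues missing a
#' C-alpha are dropped with a warning.
#'
#' @param path PDB file.
#' @return A [protein_input()].
#' @export
read_protein_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records found")
  elesy <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                 substr(trimws(at$elety), 1, 1), at$elesy)))
  at <- at[elesy != "H", , drop = FALSE]
  if (nrow(at) == 0) stop("no heavy atoms found")
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  # altloc: per (residue, atom name) keep highest occupancy, tie -> 'A'/first
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  at$o[is.na(at$o)] <- 1
  pick <- tapply(seq_len(nrow(at)), key, function(ii) {
    if (length(ii) == 1) return(ii)
    occ <- at$o[ii]
    best <- ii[occ == max(occ)]
    pa <- best[at$alt[best] %in% c("A", "")]
    if (length(pa) > 0) pa[1] else best[1]
  })
  at <- at[sort(unname(unlist(pick))), , drop = FALSE]
  rkey <- paste(at$chain, at$resno, at$insert, sep = "|")
  rorder <- unique(rkey)
  res_list <- split(seq_len(nrow(at)), factor(rkey, levels = rorder))
  types <- character(0); heavy <- list(); ca <- NULL; dropped <- 0L
  for (ii in res_list) {
    ca_row <- ii[trimws(at$elety[ii]) == "CA"]
    if (length(ca_row) == 0) { dropped <- dropped + 1L; next }
    aa1 <- suppressWarnings(bio3d::aa321(at$resid[ii[1]]))
    if (is.na(aa1) || !(aa1 %in% residue_vocabulary())) aa1 <- "X"
    types <- c(types, aa1)
    heavy <- c(heavy, list(cbind(at$x[ii], at$y[ii], at$z[ii])))
    ca <- rbind(ca, c(at$x[ca_row[1]], at$y[ca_row[1]], at$z[ca_row[1]]))
  }
  if (dropped > 0)
    warning(sprintf("dropped %d residue(s) without a C-alpha", dropped),
            call. = FALSE)
  if (length(types) == 0) stop("no residues with a C-alpha found")
  protein_input(types, heavy, ca,
                id = sub("\\.pdb$", "", basename(path), ignore.case = TRUE))
}

#' Write a protein to a PDB file
#'
#' Heavy atoms are emitted as ATOM records (first atom of each residue named
#' CA, further pseudo-atoms CB/CG/CD, all element C for synthetic chains
#' unless real names are known).
#'
#' @param protein A [protein_input()].
#' @param path Output file.
#' @export
write_protein_pdb <- function(protein, path) {
  n <- length(protein$residue_types)
  names4 <- c("CA", "CB", "CG", "CD", "CE", "CZ", "CH", "CK")
  xyz <- NULL; resno <- integer(0); elety <- character(0); resid <- character(0)
  for (i in seq_len(n)) {
    h <- protein$heavy_atom_coords[[i]]
    k <- nrow(h)
    xyz <- rbind(xyz, h)
    resno <- c(resno, rep(i, k))
    elety <- c(elety, names4[seq_len(k)])
    r3 <- suppressWarnings(bio3d::aa123(protein$residue_types[i]))
    if (is.na(r3)) r3 <- "UNK"
    resid <- c(resid, rep(r3, k))
  }
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                   resno = resno, resid = resid, elety = elety,
                   chain = rep("A", length(resno)))
}

# ---- Affinity unit conversions -------------------------------------------

#' Convert a binding constant to pK
#'
#' The default (`"literal"`) convention computes
#' `pK = -log10(K / 1e9)`, i.e. treats the supplied numeral as
#' nanomolar-equivalent; `"molar"` computes `-log10(K)` for constants given
#' in molar units.
#'
#' @param K Positive binding constant (Kd/Ki/IC50 numeral).
#' @param convention `"literal"` or `"molar"`.
#' @return pK value.
#' @export
pk_from_affinity <- function(K, convention = c("literal", "molar")) {
  convention <- match.arg(convention)
  if (any(K <= 0)) stop("K must be positive")
  if (convention == "literal") -log10(K / 1e9) else -log10(K)
}

# Gas constant in kcal/(mol K)
.R_kcal <- 1.98720425864083e-3

#' Convert binding free energy to a binding constant
#'
#' `K = exp(-dG / (R T))` with `R = 1.9872e-3` kcal/(mol K); inverse of
#' `dG = -RT ln K`.
#'
#' @param delta_G Binding free energy (kcal/mol).
#' @param T Temperature (Kelvin, > 0).
#' @return Binding constant K (dimensionless/molar by convention).
#' @export
k_from_dg <- function(delta_G, T = 298.15) {
  if (T <= 0) stop("T must be positive")
  exp(-delta_G / (.R_kcal * T))
}

#' @rdname k_from_dg
#' @param K Binding constant.
#' @export
dg_from_k <- function(K, T = 298.15) {
  if (T <= 0) stop("T must be positive")
  -.R_kcal * T * log(K)
}

# ---- Binding-site labeling ------------------------------------------------

#' Label binding-site residues
#'
#' A residue is a binding site iff the minimum distance between any of its
#' heavy atoms and any ligand atom is strictly below `cutoff`.
#'
#' @param protein A [protein_input()].
#' @param ligand A [molecule()].
#' @param cutoff Distance threshold in Angstrom (default 6; 4 and 8 used in
#'   sensitivity analyses).
#' @return Integer 0/1 vector of length n.
#' @export
label_binding_sites <- function(protein, ligand, cutoff = 6) {
  if (cutoff <= 0) stop("cutoff must be positive")
  md <- residue_ligand_min_dists(protein, ligand)
  as.integer(md < cutoff)
}

# n-vector of min heavy-atom distance from each residue to any ligand atom
residue_ligand_min_dists <- function(protein, ligand) {
  lig <- ligand$coords
  vapply(protein$heavy_atom_coords, function(h) {
    # pairwise squared distances residue-heavy x ligand
    cross <- h %*% t(lig)
    d2 <- outer(rowSums(h^2), rowSums(lig^2), "+") - 2 * cross
    sqrt(max(0, min(d2)))
  }, numeric(1))
}

#' Count residue-ligand contact pairs
#'
#' Number of (residue, ligand-atom) pairs whose heavy-atom distance is
#' strictly below `cutoff`; the quantity driving the synthetic affinity rule.
#'
#' @inheritParams label_binding_sites
#' @return Integer count.
#' @export
count_contact_pairs <- function(protein, ligand, cutoff = 6) {
  lig <- ligand$coords
  total <- 0L
  for (h in protein$heavy_atom_coords) {
    cross <- h %*% t(lig)
    d2 <- outer(rowSums(h^2), rowSums(lig^2), "+") - 2 * cross
    # per ligand atom: is any heavy atom of this residue within cutoff?
    total <- total + sum(apply(d2, 2, min) < cutoff^2)
  }
  total
}

# ---- Splits ---------------------------------------------------------------

#' Build k-fold cross-validation splits
#'
#' IDs are shuffled once under `seed` and partitioned into `k` folds whose
#' sizes differ by at most one. Round `r` uses fold `r` as test, fold
#' `r %% k + 1` as validation and the remaining `k - 2` folds as training.
#'
#' @param ids Character vector of unique complex IDs.
#' @param k Number of folds (>= 3).
#' @param seed Integer seed.
#' @return List of class `pairbind_splits` with `folds` (list of ID vectors)
#'   and `rounds` (list of `train`/`val`/`test` ID vectors).
#' @export
make_cv_folds <- function(ids, k = 10L, seed = 1L) {
  if (anyDuplicated(ids)) stop("duplicate IDs")
  if (k < 3L) stop("k must be >= 3")
  if (length(ids) < k) stop("need at least k IDs")
  shuffled <- with_seed_(seed, sample(ids))
  fold_of <- rep(seq_len(k), length.out = length(shuffled))
  fold_of <- sort(fold_of)                      # sizes differ by <= 1
  folds <- split(shuffled, fold_of)
  names(folds) <- paste0("fold", seq_len(k))
  rounds <- lapply(seq_len(k), function(r) {
    test <- r; val <- r %% k + 1L
    list(train = unname(unlist(folds[-c(test, val)])),
         val = folds[[val]], test = folds[[test]])
  })
  structure(list(folds = folds, rounds = rounds, k = k, seed = seed,
                 provenance = "pairbind::make_cv_folds"),
            class = "pairbind_splits")
}

#' Read / write split files (one complex ID per line)
#' @param path File path.
#' @return Character vector of IDs.
#' @export
read_split_file <- function(path) {
  ids <- trimws(readLines(path, warn = FALSE))
  ids[nzchar(ids)]
}

#' @rdname read_split_file
#' @param ids Character IDs.
#' @export
write_split_file <- function(ids, path) writeLines(ids, path)

#' Read / write affinity label tables (CSV with columns `id`, `pK`)
#' @param path CSV path.
#' @return Data frame with `id` and `pK`.
#' @export
read_affinity_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "pK") %in% names(df)))
  df
}

#' @rdname read_affinity_labels
#' @param labels Data frame with `id`, `pK`.
#' @export
write_affinity_labels <- function(labels, path) {
  utils::write.csv(labels[, c("id", "pK")], path, row.names = FALSE,
                   quote = FALSE)
}

#' Write affinity / binding-site predictions as TSV
#'
#' Affinity: columns `complex_id`, `predicted_pK`. Sites: columns
#' `complex_id`, `residue_index` (0-based), `probability`.
#'
#' @param pred Data frame in one of the two layouts above.
#' @param path Output TSV.
#' @export
write_predictions_tsv <- function(pred, path) {
  utils::write.table(pred, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
}
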