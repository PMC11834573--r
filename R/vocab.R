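# Atom and residue vocabularies shared by the featurizer, the corruption
# operators and the encoders.

#' Ligand atom-type vocabulary
#'
#' The featurizer recognises 26 common element types; anything else maps to
#' the `[UNK]` token. `[MASK]` is the substitution token used by the
#' self-supervised masking task and `[CLS]` is the synthetic summary token
#' whose coordinates are the molecule centroid.
#'
#' @return Character vector of the 26 element symbols followed by the three
#'   special tokens `[UNK]`, `[MASK]`, `[CLS]`.
#' @export
atom_vocabulary <- function() {
  c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I",
    "B", "Si", "Se", "Na", "K", "Mg", "Ca", "Zn", "Fe", "Mn",
    "Cu", "Ni", "Co", "Li", "Al", "As",
    "[UNK]", "[MASK]", "[CLS]")
}

#' @rdname atom_vocabulary
#' @export
atom_unk_token <- function() "[UNK]"

#' @rdname atom_vocabulary
#' @export
atom_mask_token <- function() "[MASK]"

#' @rdname atom_vocabulary
#' @export
atom_cls_token <- function() "[CLS]"

#' Residue vocabulary (20 amino acids + unknown + `[CLS]`)
#'
#' @return Character vector of one-letter residue codes plus special tokens.
#' @export
residue_vocabulary <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V",
    "X", "[CLS]")
}

# Map raw element symbols onto the vocabulary; unknown symbols become [UNK].
normalize_atom_types <- function(symbols, warn = TRUE) {
  vocab <- atom_vocabulary()
  # element symbols are case-normalised: first letter upper, rest lower
  sym <- vapply(symbols, function(s) {
    s <- trimws(s)
    if (nchar(s) == 0) return(s)
    paste0(toupper(substr(s, 1, 1)), tolower(substring(s, 2)))
  }, character(1), USE.NAMES = FALSE)
  out <- ifelse(sym %in% vocab, sym, atom_unk_token())
  n_unk <- sum(out == atom_unk_token() & sym != atom_unk_token())
  if (warn && n_unk > 0) {
    warning(sprintf("%d atom symbol(s) outside the vocabulary mapped to %s",
                    n_unk, atom_unk_token()), call. = FALSE)
  }
  out
}

#' Construct a ligand molecule
#'
#' @param atom_types Character vector of element symbols (normalised against
#'   [atom_vocabulary()]; unknown symbols become `[UNK]`).
#' @param coords Numeric `m x 3` matrix of Cartesian coordinates in Angstrom.
#' @param id Identifier string.
#' @param validate Check structural invariants (finite coordinates, minimum
#'   interatomic separation 0.5 Angstrom).
#' @return An object of class `pairbind_molecule` with fields `atom_types`,
#'   `coords`, `id`.
#' @export
molecule <- function(atom_types, coords, id = "mol", validate = TRUE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L)
    stop("coords must be an m x 3 matrix")
  if (length(atom_types) != nrow(coords))
    stop("length(atom_types) must equal nrow(coords)")
  if (nrow(coords) < 1L)
    stop("a molecule needs at least one atom")
  if (!all(is.finite(coords)))
    stop("coordinates must be finite")
  atom_types <- as.character(atom_types)
  mol <- structure(list(atom_types = atom_types, coords = coords,
                        id = as.character(id)),
                   class = "pairbind_molecule")
  if (validate) validate_molecule(mol)
  mol
}

validate_molecule <- function(mol, min_sep = 0.5) {
  m <- nrow(mol$coords)
  if (m >= 2L) {
    d <- stats::dist(mol$coords)
    if (min(d) < min_sep)
      stop(sprintf("atoms closer than %.2f Angstrom (min %.3f)",
                   min_sep, min(d)))
  }
  invisible(mol)
}

#' @export
print.pairbind_molecule <- function(x, ...) {
  cat(sprintf("<molecule %s: %d atoms (%s)>\n", x$id, nrow(x$coords),
              paste(utils::head(x$atom_types, 8), collapse = " ")))
  invisible(x)
}
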