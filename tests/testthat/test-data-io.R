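test_that("SDF write/read round-trips types and coordinates", {
  mol <- generate_conformer(synthetic_spec(), seed = 3, n_atoms = 7)
  path <- withr::local_tempfile(fileext = ".sdf")
  write_ligand_sdf(mol, path)
  back <- read_ligand_sdf(path)
  expect_identical(back$atom_types, mol$atom_types)
  expect_equal(back$coords, unname(mol$coords), tolerance = 1e-4)
  expect_identical(back$id, mol$id)
  # multi-molecule files and indexing
  mols <- generate_molecule_dataset(3, synthetic_spec(), seed = 4)
  write_ligand_sdf(mols, path)
  all3 <- read_ligand_sdf_all(path)
  expect_length(all3, 3)
  expect_equal(read_ligand_sdf(path, index = 2)$coords,
               unname(mols[[2]]$coords), tolerance = 1e-4)
  expect_error(read_ligand_sdf(path, index = 9), "out of range")
})

test_that("unknown elements map to [UNK] with a warning", {
  lines <- c("weird", "  src", "",
             "  2  0  0  0  0  0  0  0  0  0999 V2000",
             "    0.0000    0.0000    0.0000 C   0  0",
             "    1.5000    0.0000    0.0000 Xq  0  0",
             "M  END", "$$$$")
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(lines, path)
  expect_warning(mol <- read_ligand_sdf(path), "UNK")
  expect_identical(mol$atom_types, c("C", atom_unk_token()))
})

test_that("malformed SDF blocks error with a line reference", {
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("m", "", "", "  0  0  0  0  0  0  0  0  0  0999 V2000",
               "M  END", "$$$$"), path)
  expect_error(read_ligand_sdf(path), "zero atoms")
  writeLines(c("m", "", "", "  3  0  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    0.0000 C   0  0",
               "M  END", "$$$$"), path)
  expect_error(read_ligand_sdf(path), "line")
})

test_that("PDB reading keeps chain order, drops HETATM and hydrogens", {
  pdb <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1      12.919   6.898  -5.040  1.00  0.00           C",
    "ATOM      4  H   ALA A   1      10.204   5.700  -6.600  1.00  0.00           H",
    "ATOM      5  N   GLY A   2      10.720   6.590  -3.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2      11.063   6.617  -1.580  1.00  0.00           C",
    "HETATM    7  O   HOH A 101      20.000  20.000  20.000  1.00  0.00           O",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, path)
  prot <- read_protein_pdb(path)
  expect_length(prot$residue_types, 2)
  expect_identical(prot$residue_types, c("A", "G"))
  # ALA: N, CA, CB heavy atoms (H dropped); GLY: N, CA
  expect_equal(vapply(prot$heavy_atom_coords, nrow, integer(1)), c(3L, 2L))
  expect_equal(prot$ca_coords[1, ], c(11.639, 6.071, -5.147))
})

test_that("insertion-code residues stay distinct; missing CA dropped", {
  pdb <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  SER A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  SER A   2A      7.600   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CB  LEU A   3      11.400   0.000   0.000  1.00  0.00           C",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, path)
  expect_warning(prot <- read_protein_pdb(path), "C-alpha")
  expect_length(prot$residue_types, 3)   # 1, 2, 2A kept; 3 dropped (no CA)
  expect_identical(prot$residue_types, c("A", "S", "S"))
})

test_that("synthetic protein PDB write/read round-trips", {
  spec <- synthetic_spec(protein_len_range = c(8, 10))
  smp <- generate_toy_complex(spec, seed = 5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_protein_pdb(smp$protein, path)
  back <- read_protein_pdb(path)
  expect_length(back$residue_types, length(smp$protein$residue_types))
  expect_equal(back$ca_coords, unname(smp$protein$ca_coords),
               tolerance = 1e-3)
  expect_equal(vapply(back$heavy_atom_coords, nrow, integer(1)),
               vapply(smp$protein$heavy_atom_coords, nrow, integer(1)))
})

test_that("pK conversion follows the nanomolar-numeral convention", {
  expect_equal(pk_from_affinity(1e9), 0)
  expect_equal(pk_from_affinity(1), 9)
  expect_equal(pk_from_affinity(50), 9 - log10(50), tolerance = 1e-12)
  expect_equal(pk_from_affinity(1e-6, convention = "molar"), 6)
  expect_error(pk_from_affinity(0), "positive")
  expect_error(pk_from_affinity(-2), "positive")
})

test_that("free-energy conversion round-trips through its inverse", {
  expect_equal(k_from_dg(0), 1)
  R <- 1.98720425864083e-3
  expect_equal(k_from_dg(-R * 298.15 * log(10), T = 298.15), 10,
               tolerance = 1e-9)
  set.seed(9)
  for (dg in runif(20, -15, 0)) {
    K <- k_from_dg(dg)
    expect_equal(dg_from_k(K), dg, tolerance = 1e-12 * max(1, abs(dg)))
  }
})

test_that("binding-site labels equal the brute-force oracle, strict at the cutoff", {
  spec <- synthetic_spec(protein_len_range = c(10, 15),
                         atom_count_range = c(5, 10))
  for (s in 1:5) {
    smp <- generate_toy_complex(spec, seed = 200 + s)
    for (cutoff in c(4, 6, 8)) {
      expect_identical(label_binding_sites(smp$protein, smp$ligand, cutoff),
                       bf_site_labels(smp$protein, smp$ligand, cutoff))
    }
  }
  # residue exactly at the cutoff is NOT a binding site; just below is
  prot <- protein_input("A", list(matrix(c(6, 0, 0), 1, 3)),
                        matrix(c(6, 0, 0), 1, 3))
  lig <- molecule("C", matrix(0, 1, 3))
  expect_identical(label_binding_sites(prot, lig, cutoff = 6), 0L)
  prot59 <- protein_input("A", list(matrix(c(5.9, 0, 0), 1, 3)),
                          matrix(c(5.9, 0, 0), 1, 3))
  expect_identical(label_binding_sites(prot59, lig, cutoff = 6), 1L)
  # far-away ligand: all zero
  spec2 <- synthetic_spec(protein_len_range = c(10, 12))
  smp2 <- generate_toy_complex(spec2, seed = 300)
  farlig <- smp2$ligand
  farlig$coords <- farlig$coords + 100
  expect_true(all(label_binding_sites(smp2$protein, farlig, 6) == 0L))
})

test_that("contact-pair counts equal the brute-force oracle", {
  spec <- synthetic_spec(protein_len_range = c(10, 15),
                         atom_count_range = c(5, 10))
  for (s in 1:4) {
    smp <- generate_toy_complex(spec, seed = 400 + s)
    expect_identical(count_contact_pairs(smp$protein, smp$ligand, 6),
                     bf_contact_pairs(smp$protein, smp$ligand, 6))
  }
})

test_that("cross-validation folds partition the IDs with balanced sizes", {
  ids <- sprintf("c%02d", 1:10)
  sp <- make_cv_folds(ids, k = 10, seed = 3)
  for (r in seq_len(10)) {
    rd <- sp$rounds[[r]]
    expect_length(rd$test, 1)
    expect_length(rd$val, 1)
    expect_length(rd$train, 8)
    expect_setequal(c(rd$train, rd$val, rd$test), ids)
  }
  tests <- unlist(lapply(sp$rounds, `[[`, "test"))
  expect_setequal(tests, ids)          # each ID tested exactly once
  expect_length(tests, 10)
  sp23 <- make_cv_folds(sprintf("c%02d", 1:23), k = 10, seed = 3)
  sizes <- unname(vapply(sp23$folds, length, integer(1)))
  expect_equal(sort(sizes, decreasing = TRUE), c(3, 3, 3, rep(2, 7)))
  expect_identical(make_cv_folds(ids, 10, seed = 5),
                   make_cv_folds(ids, 10, seed = 5))
  expect_error(make_cv_folds(c("a", "a", "b"), k = 3), "duplicate")
  expect_error(make_cv_folds(ids, k = 2), "k must be")
})

test_that("split files and label CSVs round-trip", {
  ids <- c("a1", "b2", "c3")
  path <- withr::local_tempfile(fileext = ".txt")
  write_split_file(ids, path)
  expect_identical(read_split_file(path), ids)
  lab <- data.frame(id = ids, pK = c(5.5, 7.25, 9))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_affinity_labels(lab, csv)
  expect_equal(read_affinity_labels(csv), lab)
})
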