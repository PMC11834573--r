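Package: pairbind
Title: Protein-Ligand Binding Affinity and Binding-Site Prediction with
    Pair-Biased Transformers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts protein-ligand binding affinity (pK) and per-residue
    binding sites from 3D structures without pocket priors. Ligands are
    featurized into rotation- and translation-invariant distance and
    local-frame spatial-position pair features that seed an attention-bias
    pair representation; a transformer encoder is pretrained with
    physics-guided self-supervision (atom-type masking plus coordinate
    noising directed along Lennard-Jones potential gradients, with
    classification, distance and coordinate denoising heads). Ligand and
    protein representations are concatenated with a zero-padded
    block-diagonal pair representation and refined by a pair-biased
    transformer trunk with affinity regression and binding-site
    classification heads. Includes SDF/PDB readers, affinity unit
    conversions, evaluation metrics, cross-validation drivers, and a
    synthetic complex generator for desk-scale benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    bio3d,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
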