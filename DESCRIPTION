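Package: cssr
Title: Secondary-Structure Assignment for Coarse-Grained RNA 3D Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Assigns canonical RNA secondary structure (Watson-Crick and
    wobble base pairs) to three-dimensional structures with arbitrarily
    missing atoms, down to a single atom per nucleotide.  Candidate
    nucleotide pairs are scored by the agreement of pseudo-bond distances,
    angles and dihedrals built from up to ten backbone/glycosidic atom
    types against calibrated Gaussian geometry statistics, then filtered
    by a greedy, pseudoknot-capable conflict-resolution step.  Includes
    calibration of the geometry model from annotated structures, PDB and
    mmCIF input, dot-bracket/CT/BPSEQ output, base-pair evaluation metrics
    (precision, recall, F1, MCC), and a synthetic-fixture generator for
    ideal and noise-perturbed helices, hairpins and pseudoknots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
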