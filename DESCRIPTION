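Package: exposite
Title: Active-Site Prediction from Normal-Mode Solvent Exposure Changes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structure-based prediction of enzyme active sites from the
    change of solvent-accessible surface area (SASA) along low-frequency
    elastic-network normal modes. Residues whose per-residue |dSAS| between
    the two opposite extremes of a mode falls in a tuned window mark the
    active site; the centroid of their C-alpha coordinates is the predicted
    site, and LIGSITE-style geometric pockets are ranked by proximity to it.
    Includes a PDB reader/writer, a Tirion elastic-network mode engine, a
    deterministic Shrake-Rupley SASA implementation, grid-based pocket
    detection via protein-solvent-protein scanning, evaluation against
    known catalytic residues or bound ligands, a threshold sweep utility,
    and deterministic synthetic fixtures (hinge, slab-with-well, helix)
    with built-in ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
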