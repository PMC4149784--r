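Package: feregulon
Title: Regulon Fingerprinting and Copper-Ionophore Biophysics for Yeast
    Iron Homeostasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for chemical-biology studies that use a
    copper ionophore to impose functional iron deficiency on
    Saccharomyces cerevisiae. Computes replicate fold changes from RPKM
    expression matrices with a one-standard-deviation significance rule,
    assembles two-condition regulon fingerprints with per-regulon
    best-fit lines, nominates candidate Aft1/2 and Cth2 target genes by
    joining expression calls with degenerate consensus motif scans
    (PyPuCACCCPu promoter sites, AU-rich 3'-UTR elements), and estimates
    the Fra2-dependent fraction of each gene's induction. Supporting
    biophysics covers 2:1 metal-ligand titration isotherms with
    saturation-breakpoint stoichiometry fitting, metal quantification
    arithmetic, and bis-chelate coordination geometry (bite angles,
    chelate-plane dihedral) from small-molecule coordinates. A
    synthetic-data module generates every input with known ground truth
    so each stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
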