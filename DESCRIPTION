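Package: phosphoswap
Title: Kinase-Dependent Phosphopeptidome Discovery from Label-Swap
    Quantitative Phosphoproteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for identifying the phosphopeptidome generated
    by a single protein kinase in a forward/reverse stable-isotope
    (dimethyl) labeled in-vitro kinase assay. Parses peptide-spectrum-match
    tables, filters by q-value, orients and caps treated/control ratios,
    averages technical replicates, calibrates a significance threshold from
    the non-phosphopeptide ratio distribution, maps selected phosphopeptides
    to unique protein phosphosites, computes two-sample-logo motif statistics
    against random S/T proteome background windows, matches kinase consensus
    patterns, and cross-references sites against curated phosphosite
    annotations. Includes in-silico tryptic digestion and a synthetic
    experiment generator with a position-specific kinase preference model so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    graphics,
    grDevices,
    jsonlite,
    rlang,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
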