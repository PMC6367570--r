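Package: phosphoscreen
Title: SILAC Phosphoproteomics Screening for Kinase Substrates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate substrates of an analog-sensitive kinase
    from SILAC phosphoproteomics experiments. Reads phosphosite and protein
    abundance tables (a simple native dialect or the MaxQuant
    Phospho(STY)Sites dialect), orients heavy/light ratios by the
    per-replicate label design, normalizes phosphopeptide changes to protein
    abundance, applies a localization-probability filter, aggregates
    replicates with a protein-normalized-first precedence rule, classifies
    sites into nested stringency tiers with a wild-type control exclusion,
    ranks candidates by fold-decrease, matches sequence windows to the
    NDR/LATS consensus motif (HxR/H/KxxS/T), and computes hypergeometric
    term enrichment. Includes a synthetic-data generator with planted
    substrates for end-to-end validation, and estimators for rod-shaped cell
    growth (cylinder-plus-hemispheres volume), secreted acid-phosphatase
    activity, and FRAP recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
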