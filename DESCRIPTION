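Package: paralogPhen
Title: Genotype-to-Phenotype Comparison of Duplicated Sodium-Channel Paralogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparing duplicated voltage-gated
    sodium-channel paralogs (such as the zebrafish scn1laa/scn1lab pair)
    against a reference ortholog (human SCN1A): affine-gap global protein
    alignment, per-domain percent-identity conservation scoring with
    differential-conservation flagging, CRISPR knockout-allele consequence
    prediction (frameshift and premature stop codons), local field potential
    preprocessing, power spectra and spike detection with light-stimulus
    locking, and locomotor burst/activity analysis with an exact
    Mann-Whitney U test. A synthetic-data module generates protein families,
    LFP traces and locomotor cohorts with known ground truth so every stage
    is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
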