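Package: pulseUTR
Title: Differential Analysis of Pulsed SILAC Nascent Proteomes and
    5'-UTR Translational Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing pulsed metabolic-labelling (AHA-SILAC)
    proteomics experiments that compare newly synthesised proteomes
    between two genotypes. Provides replicate-detection filtering,
    label-swap orientation and per-protein t-testing of SILAC ratio
    tables; secretory-pathway targeting enrichment from signal-peptide
    and transmembrane annotations with chi-square testing; extraction of
    5'-UTRs from transcript records and computation of translational
    features (length, GC content, upstream open reading frames under a
    Kozak-context rule, and a minimum-free-energy folding proxy);
    variant-proportional aggregation of features to proteins with binned
    chi-square and permutation group comparisons; and a metabolite
    peak-table screen with median normalisation, presence calls and
    medium uptake/secretion classification. A synthetic-data module
    generates every input with planted ground truth so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
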