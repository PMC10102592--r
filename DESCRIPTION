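Package: phosphopair
Title: Paired Proteome and Phosphoproteome Differential Analysis with
    Kinase-Substrate Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential analysis of label-free quantitative proteomics and
    phosphoproteomics from paired tumor and adjacent-normal tissues. Reads
    MaxQuant-style proteinGroups and Phospho(STY)Sites tables, performs
    median-based global normalization in log2 space, applies a three-criterion
    paired screen (Welch t-test p-value, mean fold change, concordant-pair
    fraction), filters phosphosites by localization probability, aggregates
    site-level fold changes to protein-level phosphorylation fold changes,
    classifies cross-subtype quadrants and protein-phosphorylation discordance
    groups, and infers kinase activity by kinase-substrate enrichment analysis
    (KSEA z-scores) with kinome-group annotation. Includes a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
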