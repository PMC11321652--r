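Package: bescreen
Title: Base-Editor Variant Screening and Editing-Outcome Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for engineering and evaluating adenine base editors (ABEs)
    with a library-assisted eukaryotic screen. Enumerates saturation-mutagenesis
    deaminase variant libraries and Golden-Gate-ready oligos, models a
    stop-codon EGFP sort-seq reporter and scores variant enrichment between
    input and sorted pools, quantifies amplicon sequencing reads into
    allele tables of co-occurring edits with per-position substitution
    frequencies and editing windows, classifies editing outcomes into
    precise / bystander-missense / wild-type categories with codon-level
    consequence annotation, and compares on- versus off-target editing.
    Includes simulators for amplicon reads with joint edit structure and
    for FACS-gated screen pools, so every analysis is reproducible from
    synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
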