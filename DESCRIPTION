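Package: codonuse
Title: Codon Usage Bias Analysis for Viral Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tidy analysis of synonymous codon usage in protein-coding
    sequences, built around the index set used in studies of baculovirus
    (nuclear polyhedrosis virus) envelope glycoprotein genes: relative
    synonymous codon usage (RSCU), Wright's effective number of codons
    (ENC), the codon adaptation index (CAI), and positional GC / silent
    third-position base composition. Provides mutation-versus-selection
    diagnostics (ENC plots against the mutational-pressure curve,
    neutrality-plot regression of GC12 on GC3, Pearson correlation
    tables), correspondence analysis of RSCU matrices, codon-usage-based
    hierarchical clustering and neighbor-joining trees with Newick
    output, a synthetic CDS cohort generator with controlled GC3,
    within-family bias and mutation- or selection-dominated regimes, and
    an end-to-end pipeline that writes all report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
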