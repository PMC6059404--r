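Package: gpcralign
Title: Conservation, Covariation and Association Statistics on
    Generic-Numbered GPCR Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Position-wise sequence statistics over structure-informed
    multiple sequence alignments of G protein-coupled receptor (GPCR)
    transmembrane helices indexed by Ballesteros-Weinstein generic
    position numbers. Provides residue and motif occurrence frequencies
    with physicochemical one-character wildcards, Shannon entropy of
    single positions or position tuples scaled to [0,1], covariation
    scoring of position pairs by OMES (observed minus expected squared)
    and average-product-corrected mutual information (MIp) with Z-scores
    and p-values against an all-pairs background, motif association by
    odds ratios with Woolf 95% confidence intervals, snake-plot SVG
    rendering with two-channel conservation shading, and a deterministic
    generator of synthetic GPCR-like alignment sets for testing and
    benchmarking. A command-line interface exposes every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
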