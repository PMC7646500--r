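Package: SangerHLA
Title: Sequence-Based HLA Typing from Sanger Chromatograms
Version: 0.1.0
Authors@R: person("SangerHLA", "Developers", email = "sangerhla@example.org",
    role = c("aut", "cre"))
Description: A headless engine for Sanger sequence-based typing (SBT) of
    highly polymorphic loci such as the human leukocyte antigen (HLA)
    genes. Reads ABIF chromatograms, classifies trace positions as
    homozygous or heterozygous from peak geometry, aligns the resulting
    degenerate sequences to an allele reference with a semi-global scheme
    that scores every column as a comparison of diploid allele pairs,
    enumerates and ranks candidate allele pairs by mismatched sites, and
    resolves ambiguous pairs with group-specific sequencing primer (GSSP)
    reads. A simulator renders diploid electropherograms so the whole
    pipeline can be validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
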