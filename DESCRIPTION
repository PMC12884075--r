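Package: attbscout
Title: Bioprospecting Native attB Landing Pads and Cognate Integrases
Version: 0.1.0
Authors@R:
    person("attbscout", "developers", email = "attbscout@example.org",
           role = c("aut", "cre"))
Description: Identifies unoccupied, high-quality attB attachment sites in a
    target prokaryotic genome, together with the site-specific integrases
    predicted to act on them, so that the native sites can serve as landing
    pads for single-step integration of genetic cargo. Builds a reference
    database of genomic-island-derived attB/integrase pairs with
    domain-integrity filtering of tyrosine and serine integrases,
    deduplicates attachment sites, ranks reference genomes against the
    target by MinHash sketch distance, locates edit-bounded matches of full
    attB sites and their half sites, infers island-occupied loci from
    half-site separation (including across contigs), applies refining
    filters, and reports ranked candidates. Includes a synthetic-data
    module that generates genomes, reference databases and planted-truth
    fixtures for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
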