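Package: shipgen
Title: Historical Shipping Networks and Population-Genomic Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs inter-regional shipping networks from daily ship
    positions (port-call inference from a distance threshold to an indexed
    port list, directed travel-event extraction, binning into 50-year
    period x region x region count tensors), computes population-genomic
    summaries from diploid biallelic SNP genotypes (observed and expected
    heterozygosity, the inbreeding coefficient F_IS, private alleles, and
    pairwise multilocus Weir-Cockerham F_ST), and correlates region-level
    mean F_ST with shipping intensity by Spearman rank correlation. A
    seeded synthetic-data generator produces vessel trajectories with
    planted port calls and genotypes under the Balding-Nichols drift
    model, optionally coupled to a shipping matrix, so the whole analysis
    chain runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
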