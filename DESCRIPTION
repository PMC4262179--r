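Package: contactzone
Title: Transgressive Segregation, Contact-Zone Genetics and Mate Choice
    in Cichlid Lineage Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for demonstrating phenotypic novelty arising from
    secondary contact between allopatric lineages, built around the
    riverine cichlid Astatotilapia calliptera study system. Implements
    landmark-based geometric morphometrics (TPS input, generalized
    Procrustes alignment, relative warps, centroid-size allometry
    correction), a bootstrap range-extension test of transgressive
    segregation in hybrid crosses, contact-zone population genetics
    (alignment site filtering, haplotype collapsing, minimum-spanning
    haplotype networks, in-silico diagnostic restriction screening,
    Weir-Cockerham FST with permutation tests), exclusion-based paternity
    assignment with exact binomial assortative-mating tests, and
    synthetic-data generators that emulate every input so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
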