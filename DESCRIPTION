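Package: pollenprint
Title: Microbial Fingerprints of Flower-Visiting Insects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers which insect taxa have visited a flower from the microbial
    community left on its surface. Implements the full analysis chain for
    16S OTU tables: chloroplast exclusion and read-depth filtering,
    total-sum standardization, Bray-Curtis dissimilarity, non-metric
    multidimensional scaling, permutation (PERMANOVA-style) tests for
    community shifts, a signature-taxon ("unique OTU") detector based on
    fold-change and coefficient-of-variation criteria, and ranking of
    candidate pollinators by their mean dissimilarity to flower samples
    with comparison against direct visitation observations. Also provides
    epifluorescence cell counting on DAPI-stained micrographs with
    per-individual scaling and body-weight regression, and a synthetic
    insect-to-flower microbial-transfer simulator with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    vegan,
    igraph,
    jsonlite,
    withr,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
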