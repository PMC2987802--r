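Package: intronscape
Title: Landscape and Dynamics of Mitochondrial cox1 Group I Introns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of mitochondrial cox1 group I introns:
    extraction of gene models from annotated GenBank records, detection of
    intron-encoded open reading frames and integrity calling of homing
    endonuclease genes (intact, eroded or absent), detection of chimeric
    invader endonuclease genes, projection of intron insertion sites onto a
    reference COX1 protein frame, clustering of sites into named position
    classes, construction of species-by-position-class landscape matrices,
    and fitting of a logarithmic intron-count decay model. Includes a
    phylogeny-driven synthetic-data generator that plants intron gain, loss,
    endonuclease erosion and chimerism on a tree with full ground truth, so
    every pipeline stage can be validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
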