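Package: crystkit
Title: Comparative Sequence and Structure Analysis of Lens Crystallins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of the chordate beta/gamma-crystallin
    superfamily: amino-acid composition statistics (cysteine and methionine
    content, Lys/Arg and Ala/Cys ratios), additive Gladstone-Dale refractive
    index increment (dn/dc) prediction, global pairwise and progressive
    multiple alignment with percent-identity dissimilarity matrices, Ward
    (ward.D2) hierarchical clustering, codon-threaded nucleotide alignments,
    Neighbor-Joining phylogenies with bootstrap supports, Shrake-Rupley
    solvent-accessible surface area, per-domain cysteine exposure
    classification against a buried-control baseline, and Asp-Cys (DCDCDC)
    motif based subfamily classification. Includes seeded synthetic-data
    generators (sequence families, coding sequences, additive distance
    matrices, toy structures) so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
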