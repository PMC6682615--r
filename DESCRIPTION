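Package: spatgeno
Title: Spatial-Genomic Distance Analysis for Multiregion Tumor Biopsies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how genomic divergence within a tumor scales with the
    physical separation of stereotactic biopsy sites. Computes Euclidean
    distances between 3D biopsy coordinates (with a fixed-offset convention for
    shallow/deep needle splits), three genomic distances between intra-patient
    sample pairs (a continuous Jaccard/Tanimoto distance on somatic-mutation
    allele-frequency profiles, a Canberra distance on unified copy-number
    segment log2 ratios, and an L1 distance on the most variable methylation
    beta values), and summarizes the spatial-genomic relationship per modality
    by Pearson correlation and ordinary least squares, with derived
    per-10-mm and mm-per-unit equivalence constants. Includes a
    seed-reproducible synthetic multi-site cohort generator so the full
    pipeline runs without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
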