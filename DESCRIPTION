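Package: eeinet
Title: Exon-Exon Interaction Networks from Protein Complex Structures and
    Paired Tumor Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds exon-exon interaction (EEI) networks by mapping exon
    boundaries onto residues at heterodimeric protein-complex interfaces,
    derives patient-specific network perturbations from paired healthy/tumor
    exon expression (TMM-normalized CPM thresholding), and identifies
    survival-associated edges with Kaplan-Meier logrank scans and a dual
    permutation null for biomarker calling. Includes hypergeometric pathway
    enrichment over exon sets and synthetic-data generators that emulate the
    full input stack (structures, annotation, counts, clinical tables) for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    edgeR,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    survival,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
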