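Package: tricontrast
Title: Three-Contrast Differential Expression and Perturbation
    Classification for Interferon-Treated Macrophage RNA-Seq
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a bulk RNA-seq analysis pipeline for paired
    interferon comparisons in M1/M2 monocyte-derived macrophages:
    trimmed-mean-of-M-values (TMM) normalization, a negative-binomial
    exact conditional test per contrast, signed fold-change reporting,
    and a decision scheme that combines the three contrasts
    (IFN-lambda3 vs NT, IFN-lambda4 vs NT, IFN-lambda4 vs IFN-lambda3)
    to classify each gene as perturbed or unperturbed by each
    interferon, including reciprocally regulated genes. Includes
    three-set Venn accounting, hypergeometric over-representation
    analysis against GMT gene-set collections, PCA and top-table
    reporting, a negative-binomial count simulator with planted gene
    archetypes, and a deterministic fixture builder for the
    classification algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    fgsea,
    stats,
    utils
Suggests:
    cluster,
    edgeR,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
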