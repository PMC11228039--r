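Package: hemocoord
Title: Hemoglobin-Subunit Coordination and Disorder Along the Visual-Hippocampal Brain Pathway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for hemoglobin-subunit (HBB, HBA1, HBA2)
    expression along the five-region Visual-Hippocampal brain pathway
    (OVC, MTG, ITG, PHG, HC) across Alzheimer's disease stages.
    Implements differential-expression screening (fold change and the
    limma moderated t), per-sample hemoglobin expression vectors with
    size, proportion (cosine) and synthesized (inner-product)
    coordination statistics paired with neurofibrillary-tangle burden,
    an eigenvalue-spectrum Shannon entropy of the subunit correlation
    matrix with its Gibbs free-energy differential, and a synthetic
    multi-region cohort generator so the whole pipeline runs end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
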