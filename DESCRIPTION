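Package: mfclone
Title: Clonality, Phylogeny and Homolog Phasing for Multifocal Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-sample somatic-evolution analysis for multifocal tumors
    sequenced against a matched normal: strict somatic-call filtering with
    whitelist relaxed recall, pairwise shared-SNV matrices and small-overlap
    classification, maximum-parsimony phylogenies with bootstrap support and
    per-branch mutation counts, 96-channel mutational-signature refitting,
    window-based copy-number segmentation with germline-SNP homolog phasing,
    a binomial homolog-concordance test, chromothripsis detection, and a
    fully parameterised synthetic multifocal-tumor cohort generator used to
    validate every stage against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
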