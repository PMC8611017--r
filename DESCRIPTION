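Package: mrclone
Title: Multi-Region Tumour Clonality, Haplotype-Specific Copy Number and
    Clonal Phylogeny Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of intratumour heterogeneity from multi-region and
    multi-timepoint bulk sequencing of a patient's tumour. Provides somatic
    SNV calling against a beta-binomial panel-of-normals error model with
    clonal / subclonal / subclonal-specific stratification, sample purity
    estimation and binomial-mixture clustering of multi-sample variant
    allele frequencies, rule-based clone-tree reconstruction, joint
    segmentation and multi-region haplotype phasing of allele-specific
    copy-number profiles with detection of mirrored subclonal allelic
    imbalance (MSAI), per-cytoband clonality summaries, minimum-event
    copy-number phylogenies with ancestral reconstruction and jackknife
    branch support, and per-biopsy ultra-high-risk (UHR) molecular
    classification. A synthetic multi-region cohort generator with known
    ground truth (planted clone tree, cellular fractions, haplotype-specific
    copy-number events, purity, read counts) supports end-to-end testing
    without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
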