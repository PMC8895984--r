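Package: magicqtl
Title: Multiparent (MAGIC) QTL Mapping with Founder and Ancestral Haplotype Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of multiparent advanced generation
    intercross (MAGIC) populations of doubled haploid lines. Provides a
    forward simulator of funnel-plus-intercross crossing schemes, a hidden
    Markov model for reconstructing founder ancestry probabilities along
    each line's genome, construction of ancestral haplotype blocks from
    pairwise identity-by-descent between founders, and genome scans for
    quantitative trait loci under three allelic models (bi-allelic SNP,
    founder, and ancestral haplotype) fitted with a linear mixed model
    using leave-one-chromosome-out kinship and permutation-based
    genome-wide significance thresholds. Includes population diagnostics:
    founder-representation chi-squared tests against a simulation null,
    linkage disequilibrium structure, permutation gene-set enrichment,
    and epistasis scans around a focal locus.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    igraph,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
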