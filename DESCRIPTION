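Package: eqtlens
Title: Ensemble Integration of Tissue eQTLs with GWAS via Bayesian Gene
    Scores and Bipartite Network Communities
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrating expression quantitative trait loci
    (eQTLs) mapped in a case-control tissue cohort with genome-wide
    association study (GWAS) summary statistics. Provides a vectorized
    covariate-adjusted linear-model eQTL scan with cis/trans window
    assignment and Benjamini-Hochberg FDR, hypergeometric enrichment of
    eQTL SNPs among suggestive GWAS hits, Wakefield-style log Bayes
    factor gene scores with empirical p-values from phenotype-permutation
    null GWAS summaries, bipartite eSNP-eGene network construction with
    Barber-modularity (BRIM) community detection, and community-level
    validation by Fisher meta-analysis of differential expression and
    DNA methylation. A synthetic-cohort simulator with LD-blocked
    genotypes, planted cis/trans eQTLs, genotype-driven disease liability
    and case-control methylation shifts supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
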