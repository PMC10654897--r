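Package: vaultgwas
Title: Multivariate GWAS of 3D Cranial Vault Shape in Admixed Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A joint multi-ancestry, global-to-local genome-wide association
    pipeline for 3D cranial vault shape. Registered surface meshes are
    symmetrized, aligned by generalized Procrustes analysis, adjusted for
    covariates by partial least squares regression, and segmented by
    hierarchical spectral clustering into a four-level hierarchy of vault
    segments; each segment is phenotyped by principal components retained via
    parallel analysis. Per SNP and segment, shape is adjusted for local
    genomic ancestry and tested by canonical correlation analysis with a
    chi-squared statistic. The package further provides permutation-based
    estimation of the effective number of tests, genomic inflation on
    normalized statistics, LD-based locus clumping, Weir-Cockerham FST
    enrichment with MAF/LD-matched nulls, ancestry-partitioned
    heterogeneity-of-effect likelihood-ratio tests, latent-trait replication,
    the transmission disequilibrium test, and block-averaged Spearman
    genetic-sharing statistics, together with simulators for admixed
    genotypes, local ancestry tracts, vault-like shape cohorts with planted
    effects, and case-parent trios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    mixOmics,
    jsonlite
Config/testthat/edition: 3
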