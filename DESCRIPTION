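Package: gxegreml
Title: Multivariate GREML Estimation of Genotype-by-Environment Interaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates SNP-based genetic variance and covariance across
    discrete environmental groups with multivariate genomic restricted
    maximum likelihood (AI-REML), and tests whether cross-environment
    genetic correlations differ from one as evidence of
    genotype-by-environment interaction. Includes genotype simulation with
    known genetic architecture, PLINK and GCTA-format input/output,
    genotype quality control and genomic-relationship-matrix construction,
    phenotype adjustment and rank-based inverse normal transformation,
    permutation tests, closed-form truncated-selection theory, GBLUP
    cross-environment genomic prediction, and single-SNP association scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
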