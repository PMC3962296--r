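Package: radpopgen
Title: Population Genomics of RAD-Seq SNP Panels: Filtering, Structure,
    Assignment, Linkage-Aware Ne, and Selection Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for SNP-based population genetics of high-gene-flow
    species genotyped by restriction-site-associated DNA (RAD)
    sequencing. Provides Genepop input/output and a shared genotype data
    model; an ordered, audited SNP quality-control cascade (call rate,
    minor allele frequency, RAD tag position, one SNP per tag,
    haploid-panel paralog screening, Hardy-Weinberg exact tests, linkage
    disequilibrium pruning, and duplicate-individual detection);
    Weir-Cockerham F-statistics, heterozygosities, permutation tests of
    differentiation, hierarchical AMOVA, and PCA with permutation
    significance; Bayesian leave-one-out individual assignment;
    linkage-disequilibrium effective population size estimation with
    removal of physically linked locus pairs identified from a linkage
    map, parametric confidence intervals, and Ne-to-census ratios; and a
    sliding-window FST genome scan with a bootstrap null to flag
    candidate genomic regions under divergent selection. A synthetic-data
    module generates genotype datasets with the statistical structure the
    analyses assume, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
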