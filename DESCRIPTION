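Package: herdvar
Title: Pedigree and Genomic Genetic Diversity Analysis for Managed Livestock Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the joint pedigree-based and genomic characterisation of
    genetic diversity in closed or semi-closed livestock populations such as
    horse studbooks. Implements pedigree validation and completeness indices,
    equivalent generations, generation intervals, probability-of-gene-origin
    statistics (effective numbers of founders and ancestors, a50), two pedigree
    inbreeding estimators (Meuwissen-Luo and a recursive estimator that imputes
    cohort-average inbreeding to unknown parents), average relatedness,
    realised effective population size from individual rates of inbreeding,
    PLINK-format genotype input with marker quality control, excess-homozygosity
    and runs-of-homozygosity (ROH) genomic inbreeding, linkage-disequilibrium
    based historical effective population size, admixture-style ancestry via
    masked non-negative matrix factorisation, allele-sharing population
    networks, ROH-island scans for selection signatures, and a gene-dropping
    simulator producing pedigrees and linked genotypes with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
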