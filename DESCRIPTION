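Package: patmix
Title: Empirical-Bayes Mixture Modeling of Joint Association Patterns
    Across GWAS and Omics QTL Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates J sets of SNP-level association summary statistics
    (e.g. one GWAS and several omics QTL studies, possibly computed from
    overlapping samples) under an empirical-Bayes mixture model over all 2^J
    joint association patterns.  Per-study null and alternative marginal
    densities are estimated from moderated t-statistics (variance shrinkage
    in the style of limma) or from -2 log P statistics with a scaled
    chi-squared tail fit; inter-study correlation induced by sample overlap
    is estimated from null-like statistics.  The package reports per-SNP
    posterior probabilities over association patterns, mixing proportions
    estimated by EM, posterior-probability-based estimated FDR for collapsed
    pattern groups, and an LD-aware conditional association analysis that
    discounts signals driven by linkage with lead SNPs in a region.  A
    simulation module generates synthetic summary statistics, genotypes and
    phenotypes with sample overlap, and LD blocks with confounding SNPs for
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    limma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
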