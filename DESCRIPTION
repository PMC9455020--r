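Package: indelpop
Title: Population Genetics and Kinship Analysis for Biallelic InDel Marker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for individual identification, parentage screening and basic
    population genetics with small panels of biallelic insertion/deletion (InDel)
    markers typed on agarose gels. Implements per-locus diversity statistics
    (observed and unbiased expected heterozygosity, polymorphic information
    content), exact and Markov-chain Hardy-Weinberg tests, Weir & Cockerham
    ANOVA estimators of FIS and FST with permutation significance tests,
    multi-locus non-exclusion probabilities for identity and parentage,
    exhaustive identity matching, a pedigree-aware genotype concordance-rate
    procedure with empirical and normal-theory thresholds, principal component
    analysis of genotype dosages, and a seeded simulator of structured and
    pedigreed populations for calibration experiments. Ships the published
    red-crowned crane (Grus japonensis) 11-marker genotype tables as plain-text
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
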