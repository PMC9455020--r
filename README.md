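# indelpop

Population genetics and kinship screening for small panels of biallelic
insertion/deletion (InDel) markers typed on agarose gels.

## The problem

Endangered-species monitoring often has to identify individuals from blood,
muscle or feather samples with cheap lab equipment. Panels of long (≥ 20 bp)
InDel polymorphisms are attractive because the two alleles of each locus are
resolvable as distinct PCR fragment lengths on an ordinary 3 % agarose gel —
no sequencer needed. `indelpop` implements the complete statistical chain
such a panel requires, and ships, as plain-text fixtures, the published
11-marker genotype tables for red-crowned cranes (*Grus japonensis*) from
eastern Hokkaido: 39 non-kin individuals sampled evenly from the Kushiro,
Nemuro and Tokachi regions, and 39 members of 12 known families (66 unique
birds in the union).

Each locus is strictly biallelic with a wild allele W and a variant allele V
(an insertion or a deletion); genotypes are WW, WV, VV. The package covers:

- **Diversity**: observed heterozygosity `Ho`, unbiased expected
  heterozygosity `He = 2n/(2n−1) · (1 − p²_W − p²_V)`, and polymorphic
  information content `PIC = 1 − Σp²ᵢ − Σᵢ<ⱼ 2p²ᵢp²ⱼ`.
- **Hardy–Weinberg tests**: the exact conditional test for a biallelic locus
  (enumeration of heterozygote counts given allele counts), and a seeded
  Markov-chain variant with the classic dememorisation/batch schedule;
  Bonferroni correction across the panel.
- **F-statistics**: Weir & Cockerham (1984) ANOVA variance components
  `(a, b, c)`; multi-locus `θ = Σa / Σ(a+b+c)` and `f = 1 − Σc / Σ(b+c)` by
  ratio of sums; permutation tests (individuals among groups for θ, gene
  copies within groups for f).
- **Non-exclusion probabilities** from the allele-frequency moments
  `aₘ = Σpᵢᵐ`: identity `2a₂² − a₄`, first parent
  `1 − (1 − 4a₂ + 2a₂² + 4a₃ − 3a₄)`, second parent and parent pair, combined
  across loci by multiplication — every closed form is tested against an
  exhaustive Mendelian enumeration oracle.
- **Identity and kinship screening**: exhaustive scan for genotype-identical
  pairs; the concordance rate `100 · (matching loci) / (compared loci)`;
  pedigree-aware pair classes (twin, parent–offspring, full sibling,
  grandparent–grandchild, non-kin); empirical-quantile and normal-theory 5 %
  screening thresholds; Wilcoxon rank-sum comparisons with midranks and tie
  correction.
- **Structure**: PCA of variant-allele dosages with contribution ratios and a
  deterministic sign convention.
- **Simulation**: seeded generator of Hardy–Weinberg populations with tunable
  inbreeding F, Balding–Nichols multi-population structure with tunable FST,
  Mendelian pedigrees (including dizygotic twins and grandparent chains),
  missingness and dialect-typo noise — used by the calibration test suites.

## Worked example

```r
library(indelpop)

nk <- crane_nonkin_table()      # 39 birds x 11 markers, parsed from TSV
ls <- locus_summary(nk)
ls[, c("marker_id", "p_v", "ho", "he", "pic", "hwe_p")]
#>    marker_id    p_v     ho    he   pic  hwe_p
#> 1      Id-01 0.1026 0.2051 0.186 0.167 1.0000
#> 2      Id-02 0.3205 0.3333 0.441 0.341 0.1502
#> 3      Id-03 0.3462 0.2821 0.459 0.350 0.0298
#> ...
attr(ls, "mean_he")
#> [1] 0.3154

exclusion_summary(nk)$combined_ne_identity
#> [1] 0.000918

find_identical_pairs(nk)
#>   id_a id_b n_compared_loci n_mismatching_loci
#> 1   89  127              11                  0

fstat_permutation_test(nk, "f_st", nk$samples$region, n_perm = 999, seed = 1)
#> FST = 0.01214  (permutation p = 0.376 , 999 permutations, seed 1 )
```

Only one pair of the 741 among the non-kin birds (cranes 89 and 127) shares
all 11 genotypes, and the combined non-exclusion probability of identity is
≈ 0.001: a random pair of cranes has a one-in-a-thousand chance of matching
by luck, so the panel identifies individuals with ≈ 99.9 % confidence. The
mean expected heterozygosity of 0.32 is low, and the regional FST values
(−0.006 to 0.033) show no significant differentiation across eastern
Hokkaido.

`run_full_reproduction(out_dir)` executes the whole chain (diversity,
F-statistics, exclusion, identity, kinship concordance with thresholds and
rank-sum tests, PCA) and writes one TSV per stage plus a manifest.

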