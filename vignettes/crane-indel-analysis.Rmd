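---
title: "Methods: population genetics and kinship screening with a biallelic InDel panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genetics and kinship screening with a biallelic InDel panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelpop)
```

`indelpop` reimplements, as a tested library, the statistical chain of a
gel-electrophoresis InDel marker study of red-crowned cranes in eastern
Hokkaido: per-locus diversity, Hardy–Weinberg testing, Weir & Cockerham
F-statistics with permutation nulls, multi-locus non-exclusion probabilities,
exhaustive identity matching, a concordance-rate kinship screen, and genotype
PCA. This vignette records the models, the conventions the package fixes
where the original analysis left them open, and what the test suite does and
does not demonstrate.

## Data model

A locus is strictly biallelic: a wild allele W and one variant allele V
(insertion or deletion, per the marker definition). Genotypes are stored as
variant-allele dosages 0/1/2 with `NA` for missing calls. The text dialect of
the published tables ("W Homo", "WD Hetero", "WI Hetero", "D Homo",
"I Homo") is parsed case-sensitively; the typographic variants that occur in
the published tables ("WD Heter", "W Heter", "W Hetero") always sit in
heterozygote context and are normalised to heterozygote calls, each
normalisation logged (4 cells in the non-kin table, 2 in the kin table, all
at Id-10). Any other token is an error naming the row and column: silent
coercion of genotype data is never acceptable.

Missing-data policy is complete-case per locus throughout: allele
frequencies, heterozygosities, variance components and pair concordances all
drop a locus for exactly the individuals (or pairs) untyped there, so
`n_typed` may differ across loci.

Gel band prediction is fragment-length arithmetic: the W allele amplifies at
the marker's wild-product length, the V allele at that length minus (deletion)
or plus (insertion) the InDel size; heterozygotes are flagged for a possible
heteroduplex band (a slower artefact band formed by mismatched-strand
annealing — a diagnostic hint, not a third allele). For the single insertion
marker the published product length could name either allele;
`predict_band_pattern(..., product_refers_to = "variant")` exposes the
alternative reading. Band prediction is injective over {WW, WV, VV} for any
marker with positive InDel size, which the tests assert panel-wide.

## Diversity statistics

Observed heterozygosity is the fraction of heterozygous individuals among
those typed. Expected heterozygosity defaults to the unbiased estimator
$H_e = \frac{2n}{2n-1}(1 - p_W^2 - p_V^2)$ — the convention of the standard
parentage software this field uses — with the plug-in gene diversity behind
`unbiased = FALSE`. PIC uses the usual double-sum form. Panel-level values
are arithmetic means over loci, not pooled counts, matching the granularity
of the published summary tables. Monomorphic loci report zero diversity and
a degenerate Hardy–Weinberg p of 1 rather than propagating `NaN`.

The exact Hardy–Weinberg test conditions on the observed allele counts and
sums the probabilities of all heterozygote counts at most as probable as the
one observed. The conditional distribution is evaluated in log space from
factorials; the test is validated against an oracle that enumerates every
equally-likely placement of the variant gene copies onto the $2n$ allele
slots. The Markov-chain variant runs a seeded Metropolis walk on the
heterozygote count with the classic schedule (dememorisation 1000, 100
batches of 1000 iterations) and reports a batch standard error; it exists
because the original analysis used a chain-based tester, but exact
enumeration is the default for biallelic loci, where it is cheap and exact.
On the bundled non-kin table only Id-03 falls below 0.05 before correction
and nothing survives Bonferroni, so the HWE assumption behind the exclusion
formulas stands.

## F-statistics

`wc_components()` returns the Weir & Cockerham (1984) ANOVA components per
locus — among populations $a$, among individuals within populations $b$,
within individuals $c$ — summed over the two alleles. Multi-locus estimates
are strictly ratio-of-sums: $\hat\theta = \sum_\ell a_\ell / \sum_\ell
(a_\ell+b_\ell+c_\ell)$ and $\hat f = 1 - \sum_\ell c_\ell / \sum_\ell
(b_\ell+c_\ell)$, never means of per-locus ratios (the tests check
invariance under locus duplication). Negative estimates are reported as
computed; truncation at zero would bias the small values this data produces.
A second, algebraically different mean-squares implementation of the same
estimator serves as the test oracle.

Two conventions were genuinely open:

- **Scope of the headline FIS.** Every per-region estimate in the published
  summary is the single-population $f$ of that region (the Kushiro and
  Tokachi rows reproduce exactly under it), so the package default treats
  the pooled 39 non-kin birds the same way (`fis_scope =
  "single_population"`, giving 0.098); the three-region structured variant
  (0.090) is one argument away. Neither rounds to the originally reported
  0.095 — see *Fixture fidelity* below.
- **Permutation scheme.** For $\theta$, individuals are permuted among
  groups; for $f$, gene copies are re-paired at random within each group,
  which preserves allele frequencies while destroying departures from random
  mating. P-values are two-sided via absolute value with the add-one
  correction, so a permutation p is never exactly zero and is bit-stable
  given the seed. The originally reported permutation p-values are not
  asserted anywhere: the original scheme is under-specified, and a
  permutation p is a random variable. Instead the suite checks calibration:
  on exchangeable synthetic data the p-values are approximately uniform and
  the 5 % rejection rate stays at its nominal level.

## Non-exclusion probabilities

All formulas are moment polynomials in $a_m = \sum_i p_i^m$ and assume
Hardy–Weinberg equilibrium and independent loci (hence the prior HWE test
and the multiplicative combination). Identity: $2a_2^2 - a_4$. First parent
(other parent unknown): $1 - (1 - 4a_2 + 2a_2^2 + 4a_3 - 3a_4)$, which is
$1 - 2p^2q^2$ for a biallelic locus. Second parent (other parent known) and
parent pair use the corresponding classical exclusion polynomials. Every
closed form is required by the tests to match an exhaustive enumeration over
HWE genotypes and Mendelian transmission to within $10^{-12}$ on a frequency
grid — the enumeration oracles were written before the closed forms were
wired in, and they are the ground truth if the two ever disagree. Allele
frequencies feeding these formulas come from the non-kin sample only:
family-based sampling would bias them.

## Identity and kinship screening

Identity matching scans all unordered pairs and reports those with at most
`max_mismatch` disagreeing loci (default 0). On the fixtures it finds
exactly one perfect pair among the 741 non-kin pairs (cranes 89/127) and two
among the 2145 pairs of the 66-bird union (89/127 and 331/388).

The concordance rate of a pair is $100 \times$ matched genotype states over
mutually typed loci — state-level matching, not allele sharing, because the
screen is meant to be computable straight from gel patterns. Pairs are
classed from the banding-record pedigree with precedence twin >
parent–offspring > full sibling > grandparent–grandchild; full-sibling pairs
are derived as pairs sharing a recorded parent (plus any explicit edges);
same-family pairs with no recorded relation (e.g. mates) are `unknown` and
excluded from group comparisons; cross-family pairs are non-kin. Twins in
this system are dizygotic — independent meioses of the same parents — which
the one genotyped twin pair (315/316, differing at several loci) confirms.

Screening thresholds come in two flavours: empirical quantiles (95th of
non-kin, 5th of parent–offspring and of full siblings) under a configurable
interpolated order-statistic convention, and normal-theory
$\mu \pm 1.645\sigma$. The package default is `stats::quantile` type 7, the
linear-interpolation rule of common spreadsheet software, since the original
kin analysis was run in a spreadsheet; the `quantile_type` argument reaches
every other standard convention. The Wilcoxon rank-sum statistic is reported
as the rank sum W of the kin group with midranks, tie-corrected normal
p-values, and exact enumeration at small sizes; `stats::wilcox.test` (which
reports the shifted Mann–Whitney U instead) is the cross-check oracle in the
tests.

## PCA

Genotypes are encoded as variant-allele dosages (missing calls mean-imputed
per locus), column-centred and decomposed by SVD; scaling is off by default,
the default of the standard R decomposition the original analysis used.
Constant columns are dropped with a warning — near-monomorphic loci go
constant in subgroups — and each component's sign is fixed so its
largest-magnitude loading is positive, making score tables reproducible
run-to-run. Contribution ratios are normalised eigenvalues and must sum to 1.

## The simulator

`simulate_population()` and `simulate_pedigree()` generate data with exactly
the structure the estimators assume: independent biallelic loci,
Hardy–Weinberg genotypes with inbreeding $P(WV) = 2pq(1-F)$,
population-specific frequencies from the Balding–Nichols Beta law whose
single parameter is the expected FST (a modelling convenience mapping one
dial to the quantity under test, not a claim about crane history), Mendelian
transmission through two-parent families with optional dizygotic twins and
grandparent chains, and optional missingness plus dialect-typo noise at the
serialisation layer to exercise the parser. Everything is seeded and
bit-reproducible.

What passing calibration therefore shows: the estimators are unbiased and
the tests are correctly sized *under the assumed model*. What it cannot
show: robustness to linked loci, genotyping error, null alleles or
population history deviating from the island model — real gel data can
violate all of these.

The suite's calibration scales, chosen to keep the default run inside a few
minutes while leaving Monte-Carlo error well below the asserted margins:
HWE size at $n=39$, $p=0.3$ over 1000 replicates (rate must not exceed the
nominal 5 % beyond binomial error; the exact test is conservative because
the null is discrete); FIS bias at the fixture's 11 allele frequencies over
500 replicates (zero within three standard errors); $\theta$ recovery of
FST ∈ {0.05, 0.1, 0.2} with two populations of 50 and 100 loci over 200
replicates (±0.02); Mendelian allele-sharing in every simulated pedigree;
PC1 separation (positive silhouette) at FST = 0.2 with 60–80 loci.

## Fixture fidelity and known irreproducibilities

The genotype fixtures are the published tables transcribed verbatim,
including their typographic variants. Running the chain on them reproduces
most of the originally reported results exactly: the Tokachi diversity row,
the pairwise FST values −0.006 (Tokachi–Kushiro) and 0.033
(Tokachi–Nemuro), the per-region FIS for Kushiro (0.108) and Tokachi
(0.069), the combined identity non-exclusion probability (0.001), both
identity-pair counts, and the Id-03-only HWE signal.

A cluster of Nemuro-linked quantities does not reproduce at the last printed
digit: the package computes Nemuro Ho/He 0.287/0.316 (reported 0.294/0.320),
total Ho/He 0.284/0.315 (0.287/0.316), FIS 0.098 (0.095), global FST 0.012
(0.013), Kushiro–Nemuro FST 0.008 (0.009), first-parent and parent-pair
non-exclusion 0.522/0.080 (0.518/0.077). These discrepancies are mutually
consistent with a single heterozygote in the Nemuro sample being printed as
a homozygote at Id-05: making that one edit reproduces every affected
diversity figure exactly. The package nevertheless computes from the tables
as published and reports what they give.

The kin-table thresholds are more deeply irreproducible. The 25
parent–offspring concordances computed from the published kin table are
{27.3×1, 45.5×2, 54.5×2, 63.6×4, 72.7×8, 81.8×4, 90.9×4}; no standard
quantile convention places their lower 5 % point at the originally reported
72.7 % (all nine give 27.3–45.5). The published kin table also contains two
Mendelian impossibilities (offspring homozygous for an allele their recorded
mother lacks at Id-03), and neither the reported 366 non-kin pairs (652
cross-family pairs exist) nor the 21 full-sibling pairs (the derived set has
27; 21 matches one seven-chick brood alone) can be reconstructed
unambiguously. The thresholds, rank sums and grandparent summaries are
therefore reported as computed, with the pair-set definitions configurable,
and are asserted only qualitatively (kin classes separate with p < 0.001).

## Limitations

- Strictly biallelic loci; no multi-allelic generalisation, no linkage
  disequilibrium statistics.
- Non-exclusion probabilities, not likelihood-based parentage assignment
  with simulated confidence.
- Identity matching has a mismatch-tolerance dial but no explicit
  genotyping-error model.
- Two-level F-statistics only (individuals within populations).
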