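---
title: "Detecting digenic variant combinations by co-carrier depletion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting digenic variant combinations by co-carrier depletion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digenica)
```

## The model

In a digenic disease model, pathogenic variants at two distinct loci are
jointly required to cause a phenotype. If a candidate combination is
truly pathogenic with penetrance $f$, then a fraction $f$ of its
co-carriers -- individuals carrying at least one alternate allele at
*both* variants -- develop disease and are therefore missing from a
healthy population cohort. The signature of pathogenicity is thus a
*depletion* of co-carriers relative to random expectation.

Write $q_1, q_2$ for the alternate-allele frequencies of the two
variants (reference frequencies $p_i = 1 - q_i$). Under Hardy-Weinberg
equilibrium the per-locus carrier probabilities are

$$c_i \;=\; 2 p_i q_i + q_i^2 \;=\; 1 - (1-q_i)^2 ,$$

and, assuming the two loci are unlinked (linkage equilibrium), the
expected numbers of individuals in a cohort of size $N$ over the four
collapsed categories are

| category | expected count |
|---|---|
| co-carriers (Aa/aa + Bb/bb) | $c_1 c_2 N$ |
| carriers of variant 1 only (Aa/aa + BB) | $c_1 (1 - c_2) N$ |
| carriers of variant 2 only (AA + Bb/bb) | $(1 - c_1) c_2 N$ |
| non-carriers (AA + BB) | $(1 - c_1)(1 - c_2) N$ |

These sum to $N$ exactly. Observed counts are compared to these
expectations with a Pearson chi-squared goodness-of-fit test,

$$X^2 = \sum_{k} \frac{(O_k - E_k)^2}{E_k},$$

referred to a $\chi^2$ distribution with 1 degree of freedom for the
collapsed 4-category table, or 6 degrees of freedom when all nine
two-locus genotype classes are kept (in both cases: categories minus one
minus the two estimated allele frequencies). No continuity correction is
applied. The test is two-sided through the $\chi^2$ distribution -- an
*excess* of co-carriers also rejects -- so results carry the signed
difference `observed - expected` and callers can filter to depletion.

### Assumptions

* **Autosomal diploid, biallelic sites.** Every genotype is one of
  0, 1 or 2 copies of the requested alternate allele.
* **HWE at each locus** in the reference (healthy) population. Cohorts
  that failed ancestry/relatedness QC violate this; QC is the user's
  responsibility and out of scope here.
* **Linkage equilibrium between the pair.** The joint genotype
  distribution is the product of per-locus HWE proportions. Pairs in
  strong LD (e.g. nearby variants in *cis*) must be excluded by the
  user; the package deliberately does not estimate LD.
* **Phase is irrelevant.** Co-carrier status is cross-locus
  co-occurrence within one individual, regardless of haplotype.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_expected_cocarriers` | 5 | individuals | the usual chi-squared validity rule applied to the category of interest; pairs below it are flagged untestable rather than tested by another method |
| `alpha` | 0.05 | probability | conventional significance level used in the power definition and the report stars |
| `mode` | `"collapsed"` | -- | the 4-category, 1-df test is the primary method; `"full"` (9 classes, 6 df) is provided as a cross-check |
| `multiple_testing` | `"none"` (tests), `"benjamini-hochberg"` (screening) | -- | a handful of hand-picked pairs needs no correction; screening many pairs does |
| `iterations` | 1000 | replicates | Monte-Carlo resolution of the power estimates; binomial standard error $\sqrt{p(1-p)/1000} \le 0.016$ |

The `require_all_expected` option extends the minimum-expected rule to
every category; it is off by default because the co-carrier cell is the
stated criterion and the non-carrier cell is always huge.

## The power simulator

Per replicate:

1. build the 9-class HWE distribution at the generating $q_1, q_2$;
2. multiply the four co-carrier classes (`AaBb`, `Aabb`, `aaBb`,
   `aabb`) by $1 - f$, leave the five other classes untouched, and
   renormalize all nine to sum to 1 (penetrance-scaled removal);
3. draw one multinomial cohort of size $N$ from the adjusted
   distribution -- the pre-sampling population is treated as infinite,
   since no finite source-population size is part of the stated
   procedure;
4. re-estimate $\hat q_1, \hat q_2$ from the drawn cohort by allele
   counting (removal changes the population allele frequencies, so
   expectations must be rebuilt from the sample itself);
5. rebuild HWE expected counts at $\hat q_1, \hat q_2$ for the same
   $N$, collapse (or not), and run the chi-squared test.

Power is the fraction of replicates with $p < \alpha$. Replicates that
are monomorphic at either locus, or fall below an enabled
minimum-expected threshold, count as **non-significant** (and are
tallied separately): dropping them would bias power upward exactly where
the test is weakest. The minimum-expected rule itself is *disabled* by
default in power runs (`min_expected = 0`), because the simulation
procedure does not include the screening filter; pass `min_expected = 5`
to reproduce screening behaviour.

Seeding: a scenario seed deterministically draws one 32-bit sub-seed per
replicate, and each replicate re-seeds the RNG from its sub-seed, so
estimates are reproducible and grids can be recomputed cell by cell
(each grid cell gets its own derived seed, recorded in the output
table).

```{r power}
estimate_power(power_scenario(0.06, 0.06, penetrance = 0.3, N = 38341,
                              iterations = 200, seed = 1))
```

Default grid presets span penetrance 0.1--1.0, frequencies below 1%
through above 5%, and $N \in \{38341, 100000, 500000\}$ (38,341 being a
realistic currently-available cohort of unrelated samples); all axes are
fully configurable, and both variants share the frequency axis value in
grid presets.

## Summary-level testing

When only the two allele frequencies, $N$ and the observed co-carrier
count are known (the typical situation when re-testing published
combinations against a cohort's summary statistics),
`test_from_summary()` imputes the three remaining observed cells: the
single-carrier cells absorb the co-carrier deficit in proportion to
their expected sizes, and the non-carrier cell keeps its expectation.
This is an approximation -- the true single-carrier counts are unknown
-- and results carry a note saying so. Because the displaced mass lands
in cells that are orders of magnitude larger than the co-carrier cell,
the statistic is dominated by the co-carrier term and the approximation
is mild; it is the reason only significance calls, not exact p-values,
should be compared across implementations.

```{r summary-test}
test_from_summary(0.0415, 0.0013, N = 38341, observed_cocarriers = 2)
```

## The synthetic cohort generator

`generate_cohort()` emulates exactly the world the model assumes: a
diploid cohort drawn from the two-locus HWE distribution at known
$q_1, q_2$, with optional penetrance-scaled co-carrier removal and
independent per-genotype missingness, written as a GT-only VCFv4.2 file
plus a JSON truth sidecar (generating parameters, seed, drawn and
realized counts). What it deliberately does **not** emulate: LD between
the pair, population structure, relatedness, genotyping error beyond
missingness, and more than two variants of interest. A green round-trip
or recovery test therefore establishes correctness of the counting and
testing machinery under the model's own assumptions -- not robustness to
the QC problems of real cohorts.

Default missingness is 0 (the model's stated world); the generator's
defaults otherwise mirror the simulation scenarios ($N = 38341$,
penetrance 0).

## Numerical choices

* Expected counts stay real-valued throughout; rounding (4 decimals)
  happens only in report formatting.
* `chi2_gof()` refuses tables with a zero expected cell (naming the
  cell) and tables whose totals disagree beyond $10^{-6}$ relative.
* Genotype-frequency vectors are validated to sum to 1 within
  $10^{-12}$ after penetrance renormalization.
* Monomorphic loci ($\hat q \in \{0, 1\}$) make a pair untestable; no
  fallback exact test is attempted (a deliberate non-goal).
* Individuals missing a genotype at either site are excluded pairwise,
  so each pair has its own effective $N$; how missingness was handled in
  the original cohort analyses is unstated, and pairwise exclusion is
  this package's choice.
* CLI config files are JSON (flags override file values; the effective
  configuration is logged).

## Known limitations

* The imputed single-carrier cells in `test_from_summary()` make its
  p-values approximate (see above).
* Power estimates carry Monte-Carlo noise of up to ~1.6 percentage
  points at 1000 iterations; grid-derived quantities (e.g. the minimal
  penetrance reaching 80% power) inherit it.
* No support for X-linked or haploid genotypes, no LD modelling, no
  all-pairs genome-wide scans (pair lists are explicit), and no variant
  or sample QC.
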