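---
title: "Cross-study outcome signatures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-study outcome signatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrhosig)
```

# The model

`rrhosig` addresses a recurring failure mode of tumor-expression
meta-analysis: independent cohorts, profiled on different microarray
platforms and split into favorable-outcome (FO) and poor-outcome (PO)
survival classes, rarely agree on a differential gene list when each study
is reduced to its "significant" genes by a fold-change/p-value cutoff. The
package implements the threshold-free alternative — rank-rank
hypergeometric overlap — end to end, from expression matrices to a
validated outcome classifier.

## Signed ranked profiles

Each cohort is summarized by one number per gene,

$$s_g = \mathrm{sign}(\bar{x}^{FO}_g - \bar{x}^{PO}_g)\,
        \bigl(-\log_{10} p_g\bigr),$$

with $p_g$ the two-sided p-value of the classical (equal-variance) Student
two-sample t-test. Sorting by $s_g$ descending puts the most significantly
FO-overexpressed genes at rank 1 and the most PO-overexpressed at rank $N$.
Choices worth making explicit:

* **Equal-variance t by default.** The pooled-variance Student test is the
  stated analysis convention for this design; Welch is available via
  `var_equal = FALSE` everywhere the statistic is computed.
* **Base 10.** "Log-transformed p-value" is taken as $\log_{10}$; any base
  gives the same rank order, base 10 makes scores read directly as decades
  of significance, and `p = 10^(-|score|)` round-trips (a tested property).
* **Degenerate rows.** Zero pooled variance with equal means scores 0; with
  unequal means it scores $\pm\infty$, a sentinel ranked outermost
  (`+Inf` first, `-Inf` last, ties among sentinels by gene symbol). Finite
  ties are broken by $|t|$ descending, then symbol — rankings are
  deterministic by construction.
* **Offset invariance.** Scores depend on within-platform contrasts only,
  so an additive platform offset does not move a single rank (tested as an
  invariant; it is the reason cross-platform comparison on ranks is sound
  without normalization).

## Rank-rank hypergeometric overlap

Given two ranked lists over the *same* gene universe (datasets are first
collapsed to genes and restricted to their common universe), every rank
threshold pair $(i, j)$ on a step grid is scored by the upper tail of the
hypergeometric distribution,

$$p(i,j) = P(X \ge k_{ij}), \qquad
  X \sim \mathrm{Hypergeom}(N, i, j),$$

where $k_{ij}$ is the observed overlap of the top-$i$ and top-$j$ prefixes.
The map of $-\log_{10} p$ is the RRHO heatmap; its maximum inside a
direction quadrant locates the most significant conserved gene set.

Implementation notes:

* **Log-space tails.** Cells are computed via `phyper(..., log.p = TRUE)`;
  at $N \sim 2 \times 10^4$ a perfect half-list overlap has
  $p \sim 10^{-6000}$, far below double underflow, yet its $-\log_{10} p$
  must still be finite (tested at that size).
* **Counting in $O(N + \text{cells})$.** Each gene contributes its rank
  pair once to a 2-D histogram; prefix overlaps are the 2-D cumulative sum.
  No per-cell set intersection.
* **Grid.** `step` defaults to `max(1, floor(N/100))` (≈100×100 cells); the
  grid always contains $(N, N)$ and never a zero threshold. The published
  analyses this design follows do not state their step; at default
  resolution threshold maxima are reported to the nearest `step` ranks.
* **Quadrants.** The FO-FO quadrant is the set of cells with both
  thresholds at or below the last positive-score rank of the respective
  list; PO-PO is the suffix analog, implemented by reversing both lists
  (scores negated) and scanning the same kind of prefix region, so its
  reported thresholds count from the PO end. Discordant quadrants reverse
  one list. Ties at the maximum resolve to the smallest $i$, then smallest
  $j$.
* **Nominal p-values.** Map cells are not multiple-testing corrected: the
  quantity displayed and maximized is the nominal $-\log_{10}$
  hypergeometric p, matching how such maps are conventionally printed. No
  across-cell family-wise calibration of the maximum is attempted (a known
  limitation: map maxima are biased upward as selection statistics and
  should be read as descriptive, not inferential).
* **Only over-enrichment.** The under-enrichment (lower-tail) coloring some
  RRHO variants draw is out of scope.

## The conserved signature

For every unordered pair of cohorts the package restricts both lists to the
pair's common universe, finds the FO-FO maximum, extracts the overlap
genes, and finally intersects the pairwise sets. By default the pipeline
intersects *all* platforms' universes before ranking (`joint_universe =
TRUE`), which matches the reading that all comparisons should live on the
genes present everywhere; per-pair universes are available
(`joint_universe = FALSE`) since per-pair Venn counts are also of interest.
Intersection is by exact gene symbol (case-sensitive, trimmed). The
signature's gene order is the total rank across input lists — deterministic
and roughly "most consistently FO-enriched first".

The cutoff baseline (`cutoff_overlap`, |FC| > 1.5 and p < 0.05 per
direction) is included because the interesting empirical claim is the
contrast: on correlated-but-noisy cohorts the cutoff intersection collapses
while RRHO's does not. Matrices are log2-intensity by microarray
convention, so the fold-change bound is $|\Delta\text{mean}| >
\log_2 1.5$; a different log base would only rescale the constant.

## Lymph-node contamination filter

Metastases resected from lymph nodes can carry lymphoid tissue whose
expression masquerades as a favorable immune signal. The filter fits, per
cohort, the maximum PO-group expression of six lymph-node classifier genes
("the range of the PO group", with only the upper side relevant to "above
the range"), then excludes FO samples strictly exceeding that bound on
`min_votes = 3` or more classifiers. PO samples are never excluded (they
define the range). The rule is idempotent and monotone in `min_votes`
(tested invariants). The six classifier genes are an input — real analyses
take them from a tissue-enrichment database; synthetic runs use the
generator's planted list.

With strict exceedance of a PO maximum over $n$ PO samples, a *clean* FO
value exceeds one classifier with probability $1/(n+1)$ under
exchangeability, so at $n = 10$ a clean sample trips ≥3 of 6 classifiers
with probability ≈1.2%. Recovery tests therefore demand that every planted
contaminated sample is caught in every run, and that the excluded set is
*exactly* the planted set in the median run — demanding zero chance
exclusions across dozens of small cohorts would test the binomial tail,
not the filter.

## Weighted gene voting

The classifier is deliberately simple (a reproduction of classic weighted
voting): per signature gene, weight
$W_g = (\mu^{alive}_g - \mu^{dead}_g)/(\sigma^{alive}_g +
\sigma^{dead}_g)$, and for a sample with value $S$,

$$\text{vote}_g = W_g\,\bigl(S - b_g\bigr), \qquad
  b_g = \tfrac{1}{2}(\mu^{alive}_g + \mu^{dead}_g).$$

The vote sum's sign predicts the class; exactly zero predicts PO (the
negative class — a documented tie rule that matters only on degenerate
inputs). FO/"alive" is the positive class in every metric.

* **Midpoint vs half-difference.** The source description of this method is
  self-contradictory: the prose says the sample value is compared to "the
  average of the mean expression values in the two classes"
  ($\tfrac12(\mu_a + \mu_d)$, the decision midpoint, and what the cited
  weighted-voting method uses), while the printed formula has
  $\tfrac12(\mu_a - \mu_d)$. The midpoint is the default; the printed
  variant is preserved behind `strict_formula = TRUE`. The half-difference
  version shifts every gene's boundary away from the data midline and is
  almost certainly a typographical slip, but the flag keeps the strict
  reading reproducible.
* **Leave-one-out.** The held-out sample is removed from *both* the means
  and the standard deviations (the self-consistent reading; a
  `loo_means_only = TRUE` mode reproduces the literal "only the mean was
  recomputed" text). LOO integrity — perturbing a held-out sample cannot
  change the statistics used to score it — is a tested invariant.
* **Standard deviations** use the unbiased $n-1$ denominator. Genes whose
  class-stdev sum is zero are skipped with a logged count, as are signature
  genes missing from a validation platform (dropped, not imputed).
* **Evaluation.** Confusion metrics are the textbook identities
  (property-tested); AUC is the Mann–Whitney rank statistic with ties at
  ½ (equal to the brute-force pairwise fraction, tested); the survival
  split applies the standard two-group log-rank test (via the `survival`
  package, checked in the tests against a direct observed-minus-expected
  enumeration oracle) between *predicted* classes.

# The synthetic world

The generator exists so the full pipeline is testable without downloads; it
states one fixed world rather than a tuning surface:

| parameter | default | why |
|---|---|---|
| platforms | 3 | the discovery design is three cohorts |
| genes/platform | 5000 | desk-scale stand-in for ~2–5×10^4 probes |
| shared fraction | 0.5 | overlapping-but-unequal universes; joint core = 2500 |
| planted signature | 200 genes | the conserved-signature scale reported in this literature |
| effect size | 2 SD | strong but not separable at n = 10+10; recovery is nontrivial |
| noise | Gaussian, SD 1, log-intensity | microarray convention; no distribution is stated upstream |
| platform offset | +2·(platform−1) | nuisance the rank pipeline must ignore (tested) |
| samples | 10 FO + 10 PO | small-cohort regime of the emulated studies |
| lymph classifiers | 6 | the filter's stated design |
| contamination boost | +6 units | ≥3-of-6 exceedances for planted samples by construction |
| survival | Exp(mean 60 FO / 12 PO months), 20% censored | favorable-vs-poor survival gap; uniform right-censoring |

Survival censoring draws a `censor_fraction` subset and replaces each
censored time by a Uniform(0, T) fraction of its event time — independent
right-censoring, the simplest mechanism consistent with "a fraction of
samples is censored".

What the generator does **not** emulate: real probe naming and
multi-probe genes (one probe per gene; probe collapse is exercised by
hand-built fixtures), intensity-dependent variance, gene–gene correlation,
batch structure beyond the additive offset, or cohort-specific inclusion
rules. A green recovery test therefore establishes that the pipeline
recovers a planted additive signal across platforms with heterogeneous
universes and offsets — not that it reproduces any published cohort's gene
list, which would require the original downloads and their (partially
unstated) curation.

All generators are seeded and restore the caller's RNG state; identical
configurations are bit-identical (tested).

# Numerical and degenerate-input decisions

* Hypergeometric tails in log space (`phyper(log.p = TRUE)`); exact
  enumeration agreement to 1e-12 relative error for all feasible
  $(k, i, j, N \le 30)$ is an acceptance criterion.
* Probe collapse keeps the probe with the largest |differential score| per
  gene (no collapse rule is stated upstream; the argmax rule preserves the
  strongest signal and keeps ranking self-consistent), ties to the
  lexicographically smallest probe id.
* Empty quadrant (all scores one sign) is an error with a diagnostic, not
  an empty result — a one-signed profile means the quadrant question is
  ill-posed for that comparison.
* Exceed-the-range, above-threshold (ES > 700) and vote-0 comparisons are
  all strict, as the source rules are phrased ("above", ">", "positive
  sums").
* `sample_classes` admits exactly `FO`/`PO`; richer outcome schemes must be
  mapped by the caller.

# Known limitations

* No multiple-testing correction of RRHO maps (available literature is
  split; the emulated analysis prints nominal values). A corrected map was
  considered and deliberately not implemented to keep the map definition
  single-valued; correction would not change any argmax-based result in
  this package's tests.
* No moderated-variance (limma-style) statistics — plain t is the point of
  comparison.
* No normalization/batch correction: inputs are assumed preprocessed, as
  public series matrices are.
* The classifier offers LOO-within-cohort only; no train/test machinery.
* Published headline numbers from the emulated analysis (signature size,
  pairwise overlap sizes, map maxima, validation counts) are not reproduced
  here: they require external cohort downloads and curation details not in
  the public record. The package's empirical claims are exactly those its
  tests compute on the synthetic world.
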