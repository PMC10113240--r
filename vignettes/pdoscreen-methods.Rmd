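---
title: "Methods: genomic concordance and drug-screen analytics for bladder-cancer organoids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic concordance and drug-screen analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdoscreen)
```

## Scope and model

`pdoscreen` implements the quantitative core of a matched patient-derived
organoid (PDO) study in bladder cancer: given allele-specific copy-number
segmentations, somatic SNV tables, gene-set collections and drug-screen
plates for matched parental-tumor (PT) / organoid pairs, it quantifies how
faithfully organoids reproduce the tumor genome and which genomic features
track drug response. Upstream read processing, variant calling, and
annotation are out of scope: the package starts from segment tables and
annotated SNV calls.

## Copy-number indices and similarity

For a sample's segments $s$ with lengths $w_s$ and allele-specific copy
numbers $cnA(s) \ge cnB(s) \ge 0$:

- **Allele-specific ploidy**
  $asP = \sum_s (cnA(s)+cnB(s))\,w_s \big/ \sum_s w_s$ — proportional to
  DNA content per cell (2 when diploid).
- **Genomic burden** $GB$ — the length-weighted fraction of the genome
  with $(cnA,cnB)\neq(1,1)$. A uniformly triploid or tetraploid genome has
  $GB = 1$ by construction; the two indices are linked by
  $asP = 2(1-GB) + \bar c_{ab}\,GB$ with $\bar c_{ab}$ the mean total copy
  number over aberrant territory, which the tests use as an internal
  consistency check.

Sample-to-sample similarity works on gene-level discrete copy numbers:
each panel gene takes the $(cnA,cnB)$ of the segment containing its
midpoint. The midpoint rule (rather than a length-weighted mode over
overlapping segments) is deterministic and order-independent; continuous
calls are discretized by rounding half away from zero with a floor at 0,
so integral synthetic data is reproduced exactly. Genes uncovered in *any*
sample are dropped cohort-wide, keeping every pairwise comparison on the
same gene vector. The distance between samples is the Euclidean distance
of the concatenated $(cnA, cnB)$ vectors; distances are min–max rescaled
over all off-diagonal pairs and similarity is $s = 1 - d'$. Whether one
should rescale over all pairs or only cross-patient pairs is genuinely
open; all off-diagonal pairs is used because it reproduces the arithmetic
of a 26-sample cohort with 13 matched pairs being tested against the
remaining $\binom{26}{2}-13 = 312$ pairings.

The matched-versus-random comparison is a two-sided rank-sum test of
matched-pair similarities against all remaining pairings. Rank-sum tests
everywhere in the package are exact (enumeration-equivalent) when both
groups have at most 10 untied values and fall back to the tie- and
continuity-corrected normal approximation otherwise. Dendrograms use
average linkage on the distance matrix; the linkage is not dictated by the
scientific model, and average linkage was chosen for its monotone merge
heights and robustness to the compact polyploid block that dominates such
cohorts. Ordinal trends of per-sample indices across the ordered classes
NMIBC-LG < NMIBC-HG < MIBC use tie-corrected Kendall $\tau_B$.

## SNV filtering, burden, concordance and clonality

High-quality SNVs satisfy, inclusively: tumor coverage $\ge 20$, allelic
fraction $\ge 0.08$, tumor alternative reads $\ge 5$, and zero alternative
reads in the matched normal. Tumor mutational burden is the filtered count
per megabase of sequenced territory; the territory (default 30 Mb, exome
scale) is configurable because design size and covered bases can
legitimately differ. Deleterious variants are those with `HIGH` or
`MODERATE` annotation impact.

A matched pair's deleterious SNVs are partitioned by the
`(chrom, pos, ref, alt)` key into shared and per-side private sets;
shared-versus-private counts are compared with a 2x2 chi-squared test
without continuity correction (counts in this setting are large), and
allelic-fraction distributions with the rank-sum test.

Clonality uses a standard cancer-cell-fraction correction. With purity
$p$, local total copy number $CN_t$ and allelic fraction $AF$:
$m = \mathrm{clamp}\!\left(\mathrm{round}\!\left(AF\,\frac{p\,CN_t + 2(1-p)}{p}\right),\,1,\,\max(cnA,cnB)\right)$,
$CCF = AF\,\frac{p\,CN_t + 2(1-p)}{p\,m}$. The upstream tool that produced
the original study's clonality values does not publish its exact formula,
so this correction is an explicit, documented stand-in with the expected
closed-form limits (a clonal heterozygous SNV in a pure diploid sample has
$CCF = 1$). Raw values are retained (capped at 1.25) next to the reported
$\min(CCF, 1)$.

Longitudinal pairs (baseline/relapse) are compared with a paired rank test
over shared SNVs when any exist — otherwise unpaired with a warning — and
the SNVs lost at relapse are tested for lower baseline clonality than the
conserved ones.

## Over-representation and recurrence

Per-sample enrichment of deleterious-mutation genes against a gene-set
collection is a one-sided hypergeometric test, with Benjamini–Hochberg
q-values across the sets tested within the sample ("Q-value" is not tied
to any other estimator here, and the choice is recorded). The default
background is the union of all collection genes and can be overridden with
a capture-design list; which universe the original analysis used is not
stated, and the union is the conservative reproducible choice. Terms are
shortlisted when $q < 0.2$ in at least $\lceil 0.2\,n \rceil$ of the
included samples — the ceiling makes "at least 20%" deterministic — with
longitudinal relapse samples excluded from numerator and denominator so no
patient is double-counted.

## Drug screen normalization and hit calling

Plate readouts (luminescence) are normalized per sample:
$z = (X_s - \bar X_v)/SD_v$ against the vehicle wells of the condition's
vehicle class (H2O for platinum-based conditions, DMSO otherwise).
$SD_v$ is the sample (n−1) standard deviation, which makes vehicle wells
standardize exactly to mean 0 and SD 1 and leaves z-scores invariant under
affine rescaling of the whole plate. Growth inhibition is
$1 - X_s/\bar X_v$.

Hits require both an effect size and significance: mean $z \le -1.5$ and
Dunnett-adjusted $p \le 0.05$ from a one-way ANOVA across the conditions
sharing a vehicle class (inclusive thresholds). The Dunnett many-to-one
adjustment integrates a multivariate t and is computed with a fixed
internal seed, so repeated runs agree to about $10^{-4}$. Conditions with
a single replicate are excluded from testing with a warning, never
imputed.

## Pharmacogenomic association

Binary genomic features — deleterious-SNV status per gene, copy-number
categories (homo-deletion $(0,0)$, hemi-deletion $(1,0)$, gain: total CN
above the sample's rounded $asP$ baseline, amplification: at least
baseline + 3), and per-sample pathway enrichment — are related to
replicate-level z-scores with a linear mixed model
`z ~ feature + (1 | sample)` fitted by REML. The effect is the fixed
coefficient in z-score units. The coefficient test is a two-sided
Wald-type t with Satterthwaite denominator degrees of freedom: at cohort
sizes of one to two dozen samples a plain normal Wald test has a true
type-I error near 0.08, while the Satterthwaite version stays at the
nominal 5% (the test suite verifies calibration over 500 null cohorts).
Gain/amplification cutoffs are configurable because the upstream caller's
category boundaries are not published. With one replicate per sample, or
when the random-intercept variance degenerates to zero, the model reduces
to an ordinary linear model on per-sample means — in the one-replicate
case the coefficient is exactly the two-group mean difference. Features
with fewer than two samples per level are reported untestable rather than
forced. FDR control is Benjamini–Hochberg within a per-drug family across
features (the natural family when many pathways are screened against one
drug), flagged at 10%.

## The synthetic cohort

`generate_cohort()` emulates the study conditions so that every stage is
testable without controlled-access patient data: matched pairs share a
segment backbone with a 6% per-segment discordance rate; a configurable
fraction of pairs (default 0.25) is polyploid with near-universal gains
(GB ≈ 1, asP > 3); purity is uniform on [0.55, 0.95] (cohort mean 0.75,
matching reported PT and PDO means of 0.73–0.78); 73% of each sample's
SNVs are shared with its partner; private mutations have their cancer cell
fraction scaled by 0.4, making them subclonal; observed allelic fractions
follow the purity/copy-number model above with Poisson(80) coverage and
binomial alternative reads; plates have 7 vehicle and 3 treated replicates
with ~7% technical CV, and planted genotype–drug effects (z-units) are
applied to carrier samples chosen per pair. All draws derive from
per-stage sub-seeds of one global seed. The default of 300 SNVs per sample
is a free parameter (per-sample counts are not published); it yields a TMB
of ~10/Mb over the 30 Mb default territory.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: mutational signatures and realistic
per-gene mutation rates (300 SNVs over a 200-gene panel makes chance
recurrent mutation of a given gene far more common than in an exome, so
gene-level association tests on synthetic cohorts are noisier than their
real-data counterparts and end-to-end recovery tests use the generator's
truth record for the genotype); read-level artifacts that the quality
filters exist to remove (synthetic calls are clean somatic events);
spatial plate effects; and dose–response structure (single-dose screen).
One consequence worth knowing: because the AF/alt-read filters truncate
subclonal private mutations, the post-filter shared fraction sits
0.03–0.05 above the planted generative value; the recovery tests
therefore measure the shared fraction on deleterious calls, where the
estimate is unbiased.

## Numerical choices and problem sizes

Exact rank-sum enumeration only below 10-per-group; BH is the `p.adjust`
step-up; the Dunnett integration tolerance is ~1e-4 with a fixed seed;
round-half-away-from-zero (not banker's rounding) for copy-number
discretization; clonality raw values capped at 1.25. Test and acceptance
simulations use 6–8 pairs, 300 SNVs per sample, and 200–500 replicate
model fits — sizes at which every property asserted (recovery bands,
power ≥ 80% for a −2 z-unit effect at 12 samples × 3 replicates, type-I
calibration) is stable across seeds while the whole suite runs in well
under a minute of model fitting.

The package is an analysis library rather than a shell tool: its users
drive cohorts through R scripts like the ones in the README, so no
command-line wrapper is shipped; readers who need batch execution can wrap
the exported functions in an Rscript of a few lines.

## Known limitations

- The clonality formula is a stand-in for an unpublished upstream
  definition; absolute CCF values may differ from that tool's output even
  though orderings and correlations are preserved.
- Gene-level projection by midpoint ignores intra-gene breakpoints (a gene
  spanning two segments takes one state).
- The similarity rescaling is cohort-relative: adding or removing samples
  changes $d'$ and $s$ for all pairs, so similarities are only comparable
  within one cohort.
- Dunnett adjustment assumes homoscedastic conditions within a vehicle
  class; strongly variance-heterogeneous plates would need a robust
  variant.
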