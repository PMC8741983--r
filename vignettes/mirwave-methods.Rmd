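---
title: "Methods: models, parameters and design choices in mirwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in mirwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirwave)
```

mirwave implements the computational core of a developmental small-RNA/mRNA
study design: seven embryonic time-points sampled with four small-RNA
replicates and two mRNA replicates each, spanning the maternal-zygotic
transition (MZT). This vignette explains each model, its assumptions, the
parameters that matter, and the choices made where the design was open.

## MicroRNA candidate filtering

Predicted precursor hairpins are post-filtered on their read stacks with
three rules, all inclusive (`>=`):

* **arm support** — at least 10 reads on both the 5p and the 3p mature arm;
* **loop length** — at least 8 nt between the mature intervals;
* **5' homogeneity** — at least 50% of each arm's reads sharing one 5' end
  (precise 5' processing is the hallmark of genuine Drosha/Dicer products).

Candidates that are confidently annotated homologs in other species are
rescued even when a rule fails (`conserved_flag`). Reads are assigned to an
arm when they overlap its mature interval by at least half the read length;
reads overlapping neither arm sufficiently (e.g. loop-spanning fragments)
are excluded from both arms' statistics — the behaviour for such reads is
not standardised anywhere, and majority-overlap is the common convention.
The modal 5' fraction of an arm with zero assigned reads is defined as 0 so
that the arm-support failure dominates. Hairpin secondary-structure scoring
is out of scope: candidates enter as annotated hairpins.

## Relative arm usage and arm switching

Arm usage per precursor and sample is `rau = log2((N5 + 1)/(N3 + 1))`. The
pseudocount of 1 on both arms keeps the statistic finite and exactly
antisymmetric when an arm has zero reads. Replicates are summed within a
time-point before the ratio is formed. A time-point is called dominant for
an arm at `|rau| >= 1` (twofold); the band below that is "codominant" — a
chosen convention, since no numeric criterion for near-equal arm usage is
standard. A developmental switch requires dominance on both sides of zero
within one profile. Cross-species comparisons use whole-dataset pooled
counts per species and flag pairs whose arm usage differs by at least
log2(10) — the tenfold boundary conventionally drawn in such comparisons.

## Homology search and family profiling

`search_genome()` is a seed-and-extend local aligner: exact 4-mer seeds on
both strands nominate regions that are scanned by Smith-Waterman alignment
(match +2, mismatch −3; a gap of length L costs 5 + 2L, the affine
convention of common pairwise aligners). Alignments are extracted
best-first and non-overlapping; a hit needs score ≥ 20, identity ≥ 30%
over the aligned columns and coverage of at least half the query. These
deterministic thresholds replace database-dependent e-value statistics.
With 4-mer seeds virtually every position is nominated, so the procedure
behaves as an exhaustive local alignment — which is exactly what the test
suite checks it against. At identity near the 30%-ends of the scale the
maximal local alignment of a degraded homolog can split into sub-alignments
that individually fail the coverage rule; this is a property of local
alignment, not of the seeding.

Families are assigned in two stages: matures aligning to a reference
catalog at ≥ 70% identity over the mature length adopt that family
(conserved); the rest are grouped by identical extended seed (nt 2–8).
The family × species matrix counts non-overlapping hit loci (overlapping
hits collapse to the best score — multi-mapping copies may represent
heterozygosity or assembly artifacts, so one locus is counted once).
Species are clustered on presence/absence (or copy number) with Euclidean
distance and complete linkage, the defaults of the heatmap tools used for
such matrices; columns are ordered lexicographically first so ties break
deterministically. The conservation summary classifies families as
present-in-other-species, clade-restricted, core (present elsewhere and
not clade-restricted) and unique-to-self.

## Normalization and expression dynamics

Size factors follow the median-of-ratios definition: the median, over
features with nonzero counts in all samples, of the count over that
feature's geometric mean. Two properties are worth stating precisely:
scaling one of m samples by c shifts the geometric-mean reference by
c^(1/m), so that sample's factor scales by c^(1−1/m) — not c — while
normalized values change only by a global constant; and the estimator
assumes most features do not change, so library-size multipliers are an
estimand of technical resequencing. The recovery experiment therefore
emulates resequencing a flat library at different depths (Poisson noise
only); at biological dispersion α = 0.1 the per-sample median has a
standard error around 6% on 50 features for any method.

Expressed features are those reaching 10 normalized counts (replicate
mean) in at least one time-point, inclusively. Time-point correlation uses
Spearman's rank correlation with average ranks; z-score profiles
standardise the per-time-point means, with constant features zeroed and
excluded from clustering.

**Fuzzy c-means** is the standard Bezdek alternating optimization:
memberships `u_ij = 1 / sum_l (d_ij/d_il)^(2/(m−1))` with fuzzifier m = 2,
random row-stochastic initial memberships under a caller-provided seed,
convergence when memberships move by less than 1e-6, at most 1000
iterations. Membership updates are computed on distances scaled by the
row minimum, which is overflow-safe for fuzzifiers close to 1; a feature
coinciding with a center receives membership 1 there. The number of
clusters is chosen by the elbow of the objective curve, operationalised
as the maximum second difference of the **log** objective across k. The
log scale matters: it is scale-invariant, and on four-archetype data the
raw-scale curvature always peaks at the first cheap merge (maternal vs
early-zygotic profiles are correlated) and selects k−1. Membership ≥ 0.6
marks high-confidence cluster members.

Cluster composition (newly annotated vs conserved members) is tested per
cluster with a chi-squared statistic against expectations from the
population ratio, df = 1, no continuity correction; expected cells below
1 are flagged rather than suppressed.

## Differential expression and the two waves of ZGA

Adjacent time-points are contrasted with a simplified negative-binomial
Wald test: `log2FC = log2((mean_b + 0.5)/(mean_a + 0.5))` on normalized
counts, a delta-method standard error under `var = mu + alpha mu^2`,
two-sided normal p-values and Benjamini-Hochberg adjustment within the
contrast. Features with zero counts in both groups are excluded from
testing and from the BH denominator. Dispersion is estimated per feature
by the method of moments and then — by default — fully shrunk to a trend
over the mean (bin means of the un-floored estimates, interpolated).
With four replicates the per-feature estimator has roughly six degrees of
freedom and gives t-like Wald tails; the trend restores calibrated,
uniform null p-values (verified by simulation: KS p > 0.01, type-I within
[0.044, 0.062] at nominal 0.05). `dispersion = "per_feature"` disables the
shrinkage. The full DESeq2 machinery (trended prior MAP estimates, Cook's
filtering, independent filtering, LFC shrinkage) is intentionally not
reproduced; the scientific content here is the contrast design and the
thresholds log2FC ≥ 1.5, padj ≤ 0.001.

`classify_waves()` summarises the two adjacent-stage contrasts per feature
class: a class up-regulated only in the first contrast is "wave1", only in
the second "wave2", in both "both". The MZT signature this package is
built around is mRNAs activated in both waves while microRNA activation is
confined to the second.

## Target prediction and enrichment

Canonical seed sites are exact reverse complements of miRNA nt 2–7 in the
UTR, typed as 6mer, 7mer-A1 (A opposite nt 1), 7mer-m8 (Watson-Crick match
to nt 8) or 8mer; G:U pairs never count in site typing. Duplex free energy
is a dynamic programme over intermolecular pairings only: Watson-Crick
stacks use the Xia et al. (1998) 37 °C nearest-neighbour table; stacks
involving G:U wobbles use reduced approximate values (−1.2 kcal/mol mixed,
−0.5 tandem) — adequate here because no filtering decision in the tested
scenarios rides on a specific wobble stack; interior loops/bulges cost
4.0 + 0.5 kcal/mol per unpaired base with arms capped at 8 nt; there is no
initiation term, so a duplex with any stacked pair is stabilising and an
unpaired configuration scores 0.

Interactions are filtered conjunctively: site energy strictly below
−10 kcal/mol (a site at exactly −10.0 fails), at least 2 surviving sites
per miRNA/UTR pair ("targeted more than once", read as post-energy-filter),
and both partners expressed at ≥ 10 normalized counts in some time-point.
Co-expression at the same time-point is deliberately not required — the
marginal-expression reading — since microRNA repression can act on
pre-existing transcripts. Cluster enrichment of targeted mRNAs uses
hypergeometric tails (upper for over-, lower for under-enrichment, the
smaller tail reported) with Bonferroni adjustment across clusters; burden
comparisons (distinct miRNAs per mRNA, sites per UTR) use two-sided
Mann-Whitney tests, computed by exact permutation enumeration whenever
`choose(n1+n2, n1) <= 20000` (ties handled by half-counting, two-sided
p as the probability of a U at least as far from n1·n2/2), and a
tie-corrected normal approximation otherwise; Bonferroni across cluster
pairs per metric.

## The synthetic-data generators

The generators produce every input the pipeline consumes, with planted
ground truth recorded in truth tables. They emulate:

* **Read stacks** — hairpins with 8-nt flanks, 22-nt arms and configurable
  loops; per-arm depths; 5'-end jitter over offsets −2..+2. The jitter
  counts follow a deterministic largest-remainder quota for the requested
  modal fraction (only the read order is random), so stacks planted at the
  0.49/0.50 homogeneity boundary realise their fraction exactly and
  planted verdicts are exact, not probabilistic.
* **Count matrices** — negative-binomial draws (`var = mu + alpha mu^2`,
  default alpha 0.1) around archetype mean trajectories: maternal decay
  (half-life one time-point), early-zygotic burst at time-point 2, a
  mid-course bump, a late rise, and a flat null. Default archetype
  proportions are 26/15/20/39%, the composition of the four microRNA
  expression clusters the package models. Planted up-regulated features
  apply the fold change multiplicatively to the mean before sampling.
  Per-sample depth multipliers are drawn from the library-size range
  (default 200k–500k; per-time-point depths are free parameters of the
  design) and recorded in the truth table.
* **Genomes** — i.i.d. uniform background with precursor copies planted at
  exact identity (`floor((1−identity)·length)` substitutions, no indels),
  either strand, non-overlapping loci.
* **UTRs** — background patched until it contains no canonical 6mer core
  for any input miRNA, then sites written in at non-overlapping positions:
  extended sites are full reverse complements (energy far below
  −10 kcal/mol), non-extended sites cover mature nt 1–8 only.

What the generators deliberately do not emulate: sequencing error,
quality strings, adapters, assembly artifacts, intramolecular RNA
structure, and realistic genome composition. Passing tests therefore
demonstrate the correctness of the statistics and algorithms under the
stated models — not robustness to the full messiness of real libraries.

## Problem sizes and numerical conventions

The test and acceptance workloads are sized for quick, repeatable runs:
500 read stacks for filter fidelity; a 100 × 100 count grid for the arm
usage oracle; twenty 10-kb genomes with homologs planted at identities
1.0/0.95/0.85/0.7; 1000 expression profiles for clustering recovery;
2000-feature null matrices and 50-seed sweeps for DE calibration and
power; populations up to 60 for exact hypergeometric checks and group
sizes up to 8 for exact Mann-Whitney enumeration. All randomness flows
from explicit integer seeds; generator sub-streams use fixed small
offsets from the configured seed. Ties break deterministically
(lexicographic species order in clustering, first-index argmax in hard
labels), memberships are row-stochastic to 1e-9, and all thresholds
are inclusive except the strict −10 kcal/mol energy cutoff.

## Known limitations

* The duplex energy scale is a nearest-neighbour approximation without
  initiation, dangling ends or accurate wobble parameters; absolute
  energies near a cutoff should not be over-interpreted.
* The NB Wald pipeline is not DESeq2; with very few replicates its power
  profile and its behaviour on outliers differ from the shrinkage-based
  estimator.
* The homology search reports local alignments; heavily degraded homologs
  may fragment below the coverage threshold (see above).
* Family assignment uses the dominant mature only; paralogs whose arms
  diverged are not split or merged by arm.
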