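---
title: "Consensus selection of RT-qPCR reference genes with NormRank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus selection of RT-qPCR reference genes with NormRank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NormRank)
```

## The problem

Relative quantification by RT-qPCR divides every measurement by the
expression of a reference gene (normalizer) assumed to be stable across
samples and conditions. In biofluids — circulating miRNAs in serum or
plasma above all — no single transcript has held up as a universal
reference, and ad hoc per-study choices make results hard to compare.
NormRank implements a consensus workflow for screening high-throughput
qPCR panels (hundreds of genes, quantification cycles Cq/Ct) for stable
single references and, more usefully, for small *combinations* of genes
whose per-sample mean is used as one normalization factor, and for a
compact reference *set* from which good combinations can be drawn across
many datasets.

Throughout, Cq is treated as what it is: approximately the negative log2
of relative template abundance at amplification efficiency 2. One cycle
is one doubling; the log2 expression ratio of gene $j$ against gene $k$
in a sample is therefore $Cq_k - Cq_j$, and no further transformation is
applied. No efficiency calibration is attempted (panel exports rarely
carry usable efficiencies).

## Four stability scorers

Every curated dataset (complete genes × samples Cq matrix) is scored by
four algorithms. All return one value per gene, lower = more stable.

**GeNorm M.** For gene $j$, let $V_{jk}$ be the standard deviation over
samples of the pairwise log ratio $Cq_k - Cq_j$. Then
$M_j = \frac{1}{N-1}\sum_{k \ne j} V_{jk}$. A gene that keeps a constant
ratio to every other gene gets $M = 0$; for a two-gene table
$M_A = M_B$ by symmetry. `genormScores(x, mode = "iterative")`
additionally reproduces the classical stepwise procedure: the gene with
the highest M is removed and M recomputed until two genes remain; the
final two share the last step. The single-pass M (first iteration) is
what enters the consensus ranking, so that every gene's score comes from
the same context.

**NormFinder, grouped.** The model-based estimator decomposes log-scale
expression into a gene-by-group effect, a sample effect and noise. With
$k$ genes, groups $g$ of size $n_g$: per group, sample means (over
genes) are subtracted; $a_{ig}$ is gene $i$'s average residual and
$s^2_{ig}$ its residual variance. Because subtracting the sample mean
mixes all genes' noise, $E[s^2_{ig}] = (1 - 2/k)\,\sigma^2_{ig} +
T_g/k^2$ with $T_g$ the summed true variances; the corrected
$\hat\sigma^2_{ig}$ inverts this (floored at zero; the inversion needs
$k \ge 3$ and is skipped for $k = 2$). Intergroup differences
$d_{ig} = a_{ig} - \bar a_{i\cdot}$ are shrunk towards zero by the
empirical-Bayes factor $\gamma^2 / (\gamma^2 + \hat\sigma^2_{ig}/n_g)$,
where $\gamma^2$ is a moment estimate of the variance of true group
differences over all genes and groups, floored at zero. The stability
value is the practical one-dimensional reduction of the posterior:
$|\tilde d_{ig}|$ plus the posterior SD, averaged over groups. This is
the simplified closed form of the published estimator; the fully
Bayesian variant is out of scope. If $\gamma^2$ estimates to zero (no
detectable group structure anywhere) all grouped stabilities degenerate
to zero and the ranking ties — group labels carrying no signal carry no
discrimination either; the ungrouped variant still separates genes.

**NormFinder, ungrouped.** All samples form one group; after removing
gene and sample effects each gene's corrected residual SD is its
stability value.

**BestKeeper.** The sample SD of each gene's Cq across samples. The
original BestKeeper also builds an index (per-sample geometric mean,
i.e. the arithmetic mean of Cq) and per-gene correlations with it;
`bestkeeperDiagnostics()` exposes these as descriptive output, but only
the SD enters the ranking.

The sample SD (denominator $n - 1$) is used everywhere, stated once here
and applied consistently.

## Fractional ranking and the final normalization score

Raw stability values from different algorithms live on incomparable
scales, so each algorithm's scores are reduced to the fractional dataset
ranking $(p - 1)/n$, where $p$ is the 1-based place in the ascending
sort and $n$ the number of entries; every rank lies in $[0, 1)$. Ties
receive the mean of their would-be ranks, which keeps the rank multiset
sum invariant (the tie rule is this package's choice; any tie-aware rule
is defensible). The **final normalization score** of an entry is the
arithmetic mean of its available fractional ranks: four when group
labels exist (GeNorm, both NormFinder variants, BestKeeper), three
otherwise (the grouped NormFinder variant is undefined without groups).
Lower is better. Equal final scores sort lexicographically by entry id
so report files are reproducible.

Across datasets, `aggregateRankings()` averages final scores (unweighted
— dataset size is deliberately ignored so one large series cannot
dominate) over entries present in strictly more than 80% of datasets.

## Combinations by sequential augmentation

GeNorm and BestKeeper cannot natively score a multi-gene factor, so a
combination of 2–3 genes is represented by its per-sample arithmetic
mean of Cq values (the geometric mean on the linear scale) and appended
to the dataset as *one* extra entry. All scorers and the final score run
over the $N + 1$ entries; the combination's score and place are
recorded; the entry is removed before the next combination is attached.
Appending all combinations at once would swamp the dataset with
correlated pseudo-genes and distort every variance-based scorer, which
is why augmentation is strictly sequential. `place = 1` means the
combination's final score is the minimum among the $N+1$ entries; ties
at the minimum all count as first, so several combinations can be
"first" in one dataset. The place is computed among all $N+1$ entries,
not among combinations only, because each combination is evaluated in
the context of the whole dataset. Combinations beyond $k = 3$ are
rejected: the enumeration cost grows combinatorially while reported
stability gains plateau around 3–4 members.

Because only the augmented entry changes between iterations, the
pairwise-SD matrix of the base genes and their BestKeeper SDs are
computed once and reused; GeNorm updates are
$M_j^{aug} = ((N-1) M_j + V_{j,c})/N$ and NormFinder is recomputed in
full on the augmented matrix (already linear in the table size). The
fast path is numerically identical to naive recomputation —
equivalence is asserted at $10^{-12}$ on random tables in the test
suite — and `fastPath = FALSE` forces the naive route.

## Choosing a reference set

`collectFirstPlace()` indexes all first-place pairs and triples per
dataset. `minimalCoverSet()` then finds, by exact depth-first
branch-and-bound (branching on the dataset with fewest first-place
pairs, bounding on the incumbent size), the smallest gene set containing
at least one first-place pair of every dataset; all minimal solutions
are returned rather than an arbitrary one, since the final choice among
them (e.g. excluding genes with known disease-labile serum expression,
supplied as an exclusion list) is a judgment call, not an algorithm.
`validateSetWithTriples()` checks whether a chosen set also contains a
first-place triple in every dataset.

The pairwise **normalizing affinity** of two genes counts their
co-occurrences in first-place triples, each triple weighted by
$1/T_d$ ($T_d$ = number of first-place triples in its dataset) so every
dataset contributes total weight 3 regardless of how many ties it
produced. The phrase "combinations containing the counted combination"
admits a second reading — normalizing by the number of triples
containing the *pair* — which is exposed as `mode = "per_pair"`; the
per-dataset normalization is the default because it matches the stated
goal of equalizing dataset influence.

## Monte-Carlo validation

A candidate set of $m$ genes is summarized by the mean final score of
all $\binom{m}{3}$ derived triples. `randomSetDistribution()` draws
(default) 2000 random same-size gene sets from the dataset and computes
the same mean for each, giving an empirical null distribution;
`percentileOfCandidate()` reports the fraction of random sets whose
mean is *strictly* greater than the candidate's (ties conservatively
count as not surpassed — the convention is this package's choice). The
complement is a Monte-Carlo p-value. Triple scores are memoized across
replicates: overlapping random sets re-derive the same triples, and a
triple's score is a pure function of the base table.

## The synthetic generator

`simulateCqDataset()` emulates a curated qPCR panel:

$$Cq_{gs} = \text{baseline}_g + \text{shift}_s +
  \text{groupEffect}_{g,\,group(s)} + \varepsilon_{gs}$$

| parameter | default | meaning |
|---|---|---|
| `baselineCqRange` | 15–35 cycles | uniform per-gene abundance baselines over the informative qPCR range |
| `stableSd` | 0.1 cycles | noise SD of planted reference genes (a well-behaved assay replicates within ~0.1–0.2 cycles) |
| `unstableSdRange` | 0.5–3.0 cycles | noise SD of the remaining genes, spanning mildly to strongly variable transcripts |
| `groupEffectSd` | 1.0 cycles | SD of per-group shifts on non-stable genes (a twofold group difference is one cycle) |
| `sampleShiftSd` | 0.5 cycles | global per-sample offset mimicking loading/extraction differences |
| `missingRate` | 0 | non-detect rate; missing-at-random by default, optionally biased towards high Cq |

Planted stable genes have zero group effect and `stableSd` noise; their
identities are the ground truth for recovery tests. Gaussian noise on
the Cq (log) scale is the standard qPCR error model and the simplest
defensible choice. What the generator does **not** emulate: correlated
gene families, probe-specific efficiency differences, hemolysis or
degradation gradients, batch structure within groups, or the heavy-tailed
missingness of real panels. Tests passing on these tables therefore
demonstrate correctness of the machinery and sensible behavior under a
clean error model — not performance guarantees on real serum data.

Notably, in this homogeneous model the global-mean normalizer (the
per-sample mean of *all* genes) is a strong factor, usually placing
first — it nearly coincides with the sample effect every scorer tries to
isolate. Its unreliability on real data stems from heterogeneity the
generator only reproduces when strong group effects are configured, and
one test pins exactly such a counterexample.

## Numerical and design choices

- Duplicate gene ids at curation keep the first occurrence (the merge
  rule for discordant duplicate probes is unspecified territory;
  first-occurrence retention is deterministic and order-stable), and
  every removal is logged with a reason.
- The inclusion gate (≥ 170 genes, ≥ 5 samples, missingness strictly
  below 20%) reports rather than refuses: `runWorkflow()` warns by
  default and errors under `strict`, because the gate exists to select
  datasets, not to forbid computation.
- The detection ceiling is off by default; only explicit non-detect
  tokens become missing unless a Cq cutoff is configured.
- GeNorm's final two genes share the last exclusion step; ranking ties
  break lexicographically by gene id.
- Degenerate inputs: scoring needs ≥ 2 genes and ≥ 2 samples; iterative
  GeNorm ≥ 3 genes; grouped NormFinder ≥ 2 groups of ≥ 2 samples;
  single-member classes report `NA` SD in summaries.
- All randomness (simulation, Monte-Carlo) flows through explicit seed
  arguments; seeded code restores the caller's RNG state.

## Problem sizes

The test suite and the acceptance script run the full pipeline at sizes
chosen to finish in minutes while leaving every code path exercised:
oracle equivalence on 200 random 6×6 tables (GeNorm) and 100 random
grouped tables (NormFinder); recovery over 20 seeded 200-gene × 12-sample
tables; the combination study on five 30-gene datasets (4 060 triples
each) with naive-vs-fast equivalence on 15-gene tables; Monte-Carlo
checks at 200 replicates instead of the 2000 default. These sizes are
the package's own validation choices; production runs on full panels
simply take longer.

## Limitations

- Exact parity with the historical NormFinder Excel plug-in or the
  original GeNorm VBA implementation cannot be asserted offline; the
  guarantee provided is exact agreement with independently coded
  transcriptions of the published estimators.
- BestKeeper is reduced to SD ranking; the full index/correlation
  machinery is descriptive only.
- Statistical comparison of factor classes (Kruskal–Wallis, post hoc) is
  out of scope; `summarizeFactorClasses()` emits descriptive tables.
- The minimal-cover search is exact and exponential in the worst case;
  it is intended for the small universes that first-place pairs produce,
  not for arbitrary set-cover instances.
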