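# NormRank

Consensus selection of stable endogenous reference genes (normalizers)
for high-throughput RT-qPCR data — single genes, 2–3-gene combinations,
and compact reference sets validated by Monte-Carlo sampling.

## Why

Relative quantification by qPCR stands or falls with the reference gene,
and in biofluids (circulating serum/plasma miRNAs in particular) no
single universal reference exists. NormRank screens Cq/Ct panels with
four established stability algorithms and combines them into one
consensus score:

- **GeNorm M** — for gene *j*, the mean over all other genes *k* of the
  SD of the pairwise log2 ratio (on Cq input, `Cq_k − Cq_j`);
- **NormFinder** — the model-based inter-/intragroup variance estimator,
  in grouped and ungrouped variants (stability = |shrunk group
  difference| + posterior SD, or residual SD without groups);
- **BestKeeper** — the per-gene Cq standard deviation across samples.

Each algorithm's scores are reduced to the fractional dataset ranking
`(place − 1) / n ∈ [0, 1)` and averaged into the **final normalization
score** (lower = better). Multi-gene normalization factors — per-sample
arithmetic means of 2 or 3 genes — are scored by *sequential
augmentation*: one combination at a time is appended to the dataset as
an extra entry, ranked in the context of all N+1 entries, and removed
again. On top sit cross-dataset rank aggregation, an exact minimal-cover
search for a small reference set spanning the first-place combinations
of every dataset, a pairwise "normalizing affinity" matrix, and
Monte-Carlo validation of a candidate set against random same-size sets.

## Worked example

```r
library(NormRank)

sim <- simulateCqDataset(nGenes = 30, nSamples = 10, nGroups = 2,
                         nStable = 3, seed = 42)
x <- curateCqSet(sim$dataset)
sim$truth$stable_gene_ids
#> [1] "miR-001" "miR-005" "miR-017"

head(finalScores(x), 5)
#>    entry_id rank_genorm rank_normfinder_grouped rank_normfinder_ungrouped
#> 17  miR-017      0.0000                  0.0000                    0.0000
#> 1   miR-001      0.0333                  0.0333                    0.0333
#> 5   miR-005      0.0667                  0.0667                    0.0667
#> 2   miR-002      0.1000                  0.1333                    0.1000
#> 10  miR-010      0.1333                  0.1000                    0.1667
#>    rank_bestkeeper final_score place
#> 17          0.0333     0.00833     1
#> 1           0.0667     0.04167     2
#> 5           0.0000     0.05000     3
#> 2           0.1333     0.11667     4
#> 10          0.1000     0.12500     5
```

The three planted low-variability genes occupy the top of the ranking:
each `rank_*` column is that algorithm's fractional rank and
`final_score` their mean, so `miR-017` — best or near-best under all
four algorithms — scores 0.0083 and places first.

```r
pairs <- enumerateCombinations(x, k = 2)
head(pairs[order(pairs$final_score), c("members", "final_score", "place")], 3)
#>             members final_score place
#> 16  miR-001;miR-017      0.0202     1
#> 122 miR-005;miR-017      0.0202     1
#> 44  miR-002;miR-017      0.0444     2

globalMeanFactor(x)[, c("members", "final_score", "place")]
#>   members final_score place
#> 1     ALL      0.0363     2
```

Two pairs of planted genes tie for first place among all 31 entries of
their augmented tables (ties at the minimum all count as first), and the
mean-of-all-genes factor is *not* automatically the best normalizer.

```r
S <- c(sim$truth$stable_gene_ids, "miR-002", "miR-004", "miR-010")
dist <- randomSetDistribution(x, setSize = 6, nReplicates = 100, seed = 43)
percentileOfCandidate(dist, candidateMeanRanking(x, S))
#> McResult: candidate mean ranking 0.0657 surpasses 100.00% of 100 random sets
```

The candidate set's derived triples out-rank those of every random
6-gene set — the Monte-Carlo evidence that the set is better than
chance.

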