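# Synthetic qPCR data with planted reference genes. The generator emulates
# curated high-throughput Cq tables: per-gene baselines spread over the
# instrument's informative range, a global per-sample shift (loading /
# efficiency differences), group effects on non-stable genes, Gaussian
# cycle noise on the Cq (log) scale, and optional non-detects.

#' Simulate a qPCR Cq table with planted stable reference genes
#'
#' Generates `Cq(g, s) = baseline_g + shift_s + groupEffect_{g, group(s)} +
#' noise_g`. Planted stable genes have zero group effect and `stableSd`
#' noise; the remaining genes draw their noise SD uniformly from
#' `unstableSdRange` and a per-group effect from `N(0, groupEffectSd)`.
#' Missing values (non-detects) are inserted at `missingRate`, uniformly at
#' random by default or biased towards high Cq with
#' `highCqBiasedMissing = TRUE`.
#'
#' @param nGenes,nSamples table dimensions (defaults 200 x 12)
#' @param nGroups number of sample groups (default 2; 1 = no group labels)
#' @param nStable number of planted stable genes (default 3)
#' @param baselineCqRange range (cycles) for uniform per-gene baselines
#'   (default 15-35)
#' @param stableSd noise SD (cycles) of planted genes (default 0.1)
#' @param unstableSdRange noise SD range (cycles) of the other genes
#'   (default 0.5-3.0)
#' @param groupEffectSd SD (cycles) of per-group shifts applied to
#'   non-stable genes (default 1.0)
#' @param sampleShiftSd SD (cycles) of the global per-sample offset
#'   (default 0.5)
#' @param missingRate proportion of cells turned into non-detects
#'   (default 0)
#' @param highCqBiasedMissing bias non-detects towards high-Cq cells
#' @param seed integer seed; the caller's RNG state is restored
#' @return list with `dataset` (a raw [CqSet-class], `sourceTag`
#'   `"synthetic"`) and `truth` (list: `stable_gene_ids`, per-gene
#'   data.frame `genes` with `gene_id`, `baseline`, `true_sd`, `stable`,
#'   and one `group_effect.<group>` column per group).
#' @examples
#' sim <- simulateCqDataset(nGenes = 50, nSamples = 8, seed = 7)
#' sim$truth$stable_gene_ids
#' @export
simulateCqDataset <- function(nGenes = 200L, nSamples = 12L, nGroups = 2L,
                              nStable = 3L, baselineCqRange = c(15, 35),
                              stableSd = 0.1, unstableSdRange = c(0.5, 3.0),
                              groupEffectSd = 1.0, sampleShiftSd = 0.5,
                              missingRate = 0, highCqBiasedMissing = FALSE,
                              seed = NULL) {
  if (nGenes < 2L) stop("invalid 'nGenes': need >= 2")
  if (nSamples < 2L) stop("invalid 'nSamples': need >= 2")
  if (nGroups < 1L) stop("invalid 'nGroups': need >= 1")
  if (nStable < 0L || nStable > nGenes)
    stop("invalid 'nStable': must be in [0, nGenes]")
  if (stableSd < 0) stop("invalid 'stableSd': must be >= 0")
  if (any(unstableSdRange < 0) || diff(unstableSdRange) < 0)
    stop("invalid 'unstableSdRange': need 0 <= lower <= upper")
  if (groupEffectSd < 0) stop("invalid 'groupEffectSd': must be >= 0")
  if (sampleShiftSd < 0) stop("invalid 'sampleShiftSd': must be >= 0")
  if (missingRate < 0 || missingRate >= 1)
    stop("invalid 'missingRate': must be in [0, 1)")
  .withSeed(seed, {
    geneIds <- sprintf("miR-%03d", seq_len(nGenes))
    sampleIds <- sprintf("S%02d", seq_len(nSamples))
    groupOf <- rep_len(paste0("G", seq_len(nGroups)), nSamples)
    stableIdx <- sort(sample(nGenes, nStable))
    baseline <- runif(nGenes, baselineCqRange[1L], baselineCqRange[2L])
    sdGene <- runif(nGenes, unstableSdRange[1L], unstableSdRange[2L])
    sdGene[stableIdx] <- stableSd
    groupEff <- matrix(rnorm(nGenes * nGroups, sd = groupEffectSd),
                       nGenes, nGroups,
                       dimnames = list(geneIds, paste0("G", seq_len(nGroups))))
    groupEff[stableIdx, ] <- 0
    shift <- rnorm(nSamples, sd = sampleShiftSd)
    noise <- matrix(rnorm(nGenes * nSamples), nGenes, nSamples) * sdGene
    cq <- baseline +
      matrix(shift, nGenes, nSamples, byrow = TRUE) +
      groupEff[, match(groupOf, colnames(groupEff)), drop = FALSE] +
      noise
    dimnames(cq) <- list(geneIds, sampleIds)
    if (missingRate > 0) {
      nMiss <- round(missingRate * length(cq))
      prob <- if (highCqBiasedMissing) rank(cq) else NULL
      miss <- sample(length(cq), nMiss, prob = prob)
      cq[miss] <- NA_real_
    }
    genes <- data.frame(gene_id = geneIds, baseline = baseline,
                        true_sd = sdGene,
                        stable = seq_len(nGenes) %in% stableIdx)
    ge <- as.data.frame(groupEff)
    names(ge) <- paste0("group_effect.", names(ge))
    genes <- cbind(genes, ge)
    rownames(genes) <- NULL
    list(dataset = CqSet(cq,
                         groups = if (nGroups > 1L) groupOf else NULL,
                         sourceTag = "synthetic"),
         truth = list(stable_gene_ids = geneIds[stableIdx], genes = genes))
  })
}

#' Planted-gene recovery rate of the single-gene pipeline
#'
#' Runs the full single-gene workflow (simulate, curate, final
#' normalization scores) `nRuns` times with consecutive seeds and reports
#' the proportion of runs in which every planted stable gene lands within
#' the top `topK` positions of the final ranking.
#'
#' @param nRuns number of simulation runs
#' @param topK rank cutoff (must be >= the number of planted genes)
#' @param seed base seed; run i uses `seed + i - 1`
#' @param ... simulation parameters passed to [simulateCqDataset()]
#' @return proportion of successful runs in `[0, 1]`
#' @export
plantedRecoveryRate <- function(nRuns, topK, seed = 1L, ...) {
  args <- list(...)
  nStable <- if (!is.null(args$nStable)) args$nStable else 3L
  if (topK < nStable) stop("topK must be >= nStable")
  hits <- vapply(seq_len(nRuns), function(i) {
    sim <- simulateCqDataset(..., seed = seed + i - 1L)
    fs <- finalScores(curateCqSet(sim$dataset))
    all(sim$truth$stable_gene_ids %in% head(fs$entry_id, topK))
  }, logical(1L))
  mean(hits)
}
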