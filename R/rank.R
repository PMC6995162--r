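#' Fractional dataset ranking
#'
#' Converts raw stability values into the fractional ranking
#' `(place - 1) / n`, where `place` is the 1-based position in the array
#' sorted ascending by stability (lower = more stable) and `n` the number
#' of entries; all ranks lie in `[0, 1)`. Tied stability values receive the
#' mean of their would-be fractional ranks, which keeps the rank multiset
#' sum invariant.
#'
#' @param scores named numeric vector of finite stability values
#' @return named numeric vector of fractional ranks in `[0, 1)`
#' @examples
#' fractionalRank(c(A = 0.5, B = 1.2, C = 0.7))  # A=0, C=1/3, B=2/3
#' @export
fractionalRank <- function(scores) {
  if (length(scores) == 0L) stop("empty score vector")
  if (any(!is.finite(scores))) stop("stability values must be finite")
  (rank(scores, ties.method = "average") - 1) / length(scores)
}

.algoScores <- function(x, useGroups) {
  out <- list(genorm = stabilityValues(genormScores(x, "single_pass")))
  if (useGroups)
    out$normfinder_grouped <- stabilityValues(normfinderScores(x, TRUE))
  out$normfinder_ungrouped <- stabilityValues(normfinderScores(x, FALSE))
  out$bestkeeper <- stabilityValues(bestkeeperScores(x))
  out
}

# ranks: list algorithm -> named fractional-rank vector (same gene order)
.assembleRankTable <- function(ranks) {
  ids <- names(ranks[[1L]])
  rk <- vapply(ranks, function(r) unname(r[ids]), numeric(length(ids)))
  rk <- matrix(rk, nrow = length(ids),
               dimnames = list(ids, names(ranks)))
  fs <- rowMeans(rk)
  df <- data.frame(entry_id = ids, rk, final_score = unname(fs),
                   row.names = NULL, check.names = FALSE)
  names(df)[seq_along(ranks) + 1L] <- paste0("rank_", names(ranks))
  df$place <- rank(df$final_score, ties.method = "min")
  df[order(df$final_score, df$entry_id), , drop = FALSE]
}

#' Final normalization score of every gene in a dataset
#'
#' Runs all applicable stability scorers (GeNorm single-pass M, NormFinder
#' grouped and ungrouped when group labels are present, otherwise
#' ungrouped only, and BestKeeper SD), fractional-ranks each one, and
#' averages the available fractional ranks into the final normalization
#' score. Lower scores mark better normalization factors.
#'
#' @param x a curated [CqSet-class]
#' @param useGroups logical; include the grouped NormFinder variant.
#'   Defaults to `TRUE` when `x` carries group labels.
#' @return data.frame sorted ascending by `final_score` (ties broken
#'   lexicographically by `entry_id`) with one `rank_<algorithm>` column
#'   per scorer, the `final_score`, and the 1-based `place` (ties at a
#'   score share the lowest place).
#' @examples
#' sim <- simulateCqDataset(nGenes = 12, nSamples = 8, nStable = 2, seed = 1)
#' head(finalScores(curateCqSet(sim$dataset)))
#' @export
finalScores <- function(x, useGroups = !is.null(sampleGroups(x))) {
  scores <- .algoScores(x, useGroups)
  .assembleRankTable(lapply(scores, fractionalRank))
}

#' Aggregate per-dataset rankings into a combined ranking
#'
#' Entries present in more than `presenceThreshold` of the datasets are
#' retained and their per-dataset final normalization scores averaged
#' (unweighted), giving a cross-dataset consensus ranking.
#'
#' @param perDataset named list of [finalScores()]-style data.frames, one
#'   per dataset (names are dataset ids).
#' @param presenceThreshold retain entries whose presence fraction is
#'   strictly greater than this (default 0.80).
#' @return data.frame with `entry_id`, `combined_score` (mean of available
#'   final scores), `presence_fraction`, `n_datasets`, sorted ascending by
#'   `combined_score` then `entry_id`.
#' @export
aggregateRankings <- function(perDataset, presenceThreshold = 0.80) {
  stopifnot(length(perDataset) >= 1L)
  nDatasets <- length(perDataset)
  long <- do.call(rbind, lapply(perDataset, function(df)
    df[, c("entry_id", "final_score")]))
  agg <- aggregate(final_score ~ entry_id, data = long,
                   FUN = function(v) c(mean = mean(v), n = length(v)))
  df <- data.frame(entry_id = agg$entry_id,
                   combined_score = agg$final_score[, "mean"],
                   n_datasets = agg$final_score[, "n"],
                   row.names = NULL)
  df$presence_fraction <- df$n_datasets / nDatasets
  df <- df[df$presence_fraction > presenceThreshold, , drop = FALSE]
  df <- df[order(df$combined_score, df$entry_id),
           c("entry_id", "combined_score", "presence_fraction", "n_datasets")]
  rownames(df) <- NULL
  df
}

#' Descriptive summary of normalization-factor classes
#'
#' Summarises final normalization scores per factor class (single genes,
#' pairs, triples, global mean) and dataset: the mean, SD and count of the
#' class's final scores. Purely descriptive; no hypothesis testing.
#'
#' @param records data.frame with columns `dataset_id`, `class`,
#'   `final_score` (e.g. assembled from [finalScores()] and
#'   [enumerateCombinations()] outputs).
#' @return data.frame with `dataset_id`, `class`, `mean_score`, `sd_score`
#'   (`NA` for single-member classes), `n`.
#' @export
summarizeFactorClasses <- function(records) {
  stopifnot(all(c("dataset_id", "class", "final_score") %in% names(records)))
  key <- paste(records$dataset_id, records$class, sep = "\r")
  sp <- split(records$final_score, key)
  out <- do.call(rbind, lapply(names(sp), function(k) {
    v <- sp[[k]]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    data.frame(dataset_id = parts[1L],
               class = parts[2L],
               mean_score = mean(v),
               sd_score = if (length(v) > 1L) sd(v) else NA_real_,
               n = length(v))
  }))
  rownames(out) <- NULL
  out[order(out$dataset_id, out$class), , drop = FALSE]
}

#' @importFrom stats aggregate
NULL
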