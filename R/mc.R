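# Monte-Carlo validation of a candidate reference set: the empirical
# distribution of mean derived-triple rankings over random same-size gene
# sets, and where the candidate falls in it.

# closure scoring a sorted triple of gene ids, memoized across calls: the
# triples derivable from overlapping random sets repeat heavily, and every
# triple's score is a pure function of the base table.
.makeTripleScorer <- function(x, useGroups, memoize = TRUE) {
  cache <- .comboCache(x, useGroups)
  m <- cache$m
  memo <- new.env(parent = emptyenv())
  function(members) {
    key <- paste(members, collapse = ";")
    if (memoize && !is.null(memo[[key]])) return(memo[[key]])
    profile <- colMeans(m[members, , drop = FALSE])
    fs <- unname(.scoreAugmentedFast(cache, profile, "..combo..")["final_score"])
    if (memoize) memo[[key]] <- fs
    fs
  }
}

# restore the caller's RNG state after seeded sampling
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

#' Mean derived-triple ranking of a candidate set
#'
#' Enumerates all 3-gene combinations derivable from the candidate set
#' (restricted to the genes present in the dataset), scores each by
#' sequential augmentation, and returns the arithmetic mean of their final
#' normalization scores — the quantity the Monte-Carlo validation
#' compares across sets.
#'
#' @param x a curated [CqSet-class]
#' @param S character vector of candidate gene ids (genes absent from the
#'   dataset are ignored; at least 3 must remain)
#' @param useGroups include the grouped NormFinder variant
#' @return numeric scalar in `[0, 1)`
#' @export
candidateMeanRanking <- function(x, S,
                                 useGroups = !is.null(sampleGroups(x))) {
  genes <- sort(intersect(unique(S), rownames(x)))
  if (length(genes) < 3L)
    stop("fewer than 3 candidate genes present in the dataset")
  scorer <- .makeTripleScorer(x, useGroups, memoize = FALSE)
  triples <- combn(genes, 3L, simplify = FALSE)
  mean(vapply(triples, scorer, numeric(1L)))
}

#' Distribution of mean triple rankings over random gene sets
#'
#' Repeatedly samples `setSize` distinct genes uniformly without
#' replacement from the dataset and records the mean final normalization
#' score of all triples derived from each random set, building the
#' empirical null distribution against which a candidate set is judged.
#'
#' @param x a curated [CqSet-class]
#' @param setSize number of genes per random set (default 13)
#' @param nReplicates number of random sets (default 2000)
#' @param seed integer seed; the caller's RNG state is restored afterwards
#' @param useGroups include the grouped NormFinder variant
#' @return an `McDistribution`: list with `replicate_means`, `set_size`,
#'   `n_replicates`, `seed`.
#' @export
randomSetDistribution <- function(x, setSize = 13L, nReplicates = 2000L,
                                  seed = NULL,
                                  useGroups = !is.null(sampleGroups(x))) {
  genes <- rownames(x)
  if (setSize > length(genes))
    stop("setSize (", setSize, ") exceeds gene count (", length(genes), ")")
  if (setSize < 3L) stop("setSize must be >= 3")
  scorer <- .makeTripleScorer(x, useGroups, memoize = TRUE)
  means <- .withSeed(seed, {
    vapply(seq_len(nReplicates), function(i) {
      S <- sort(sample(genes, setSize))
      mean(vapply(combn(S, 3L, simplify = FALSE), scorer, numeric(1L)))
    }, numeric(1L))
  })
  structure(list(replicate_means = means, set_size = as.integer(setSize),
                 n_replicates = as.integer(nReplicates), seed = seed),
            class = "McDistribution")
}

#' @export
print.McDistribution <- function(x, ...) {
  cat(sprintf(
    "McDistribution: %d random sets of %d genes (seed %s)\n",
    x$n_replicates, x$set_size,
    if (is.null(x$seed)) "none" else x$seed))
  cat(sprintf("  mean triple ranking: median %.4f, range [%.4f, %.4f]\n",
              stats::median(x$replicate_means), min(x$replicate_means),
              max(x$replicate_means)))
  invisible(x)
}

#' Percentile of a candidate set in the Monte-Carlo distribution
#'
#' The fraction of random-set replicate means strictly greater than the
#' candidate's mean triple ranking — the share of random sets the
#' candidate surpasses, the complement of a Monte-Carlo p-value. Ties
#' count as not surpassed (conservative).
#'
#' @param dist an `McDistribution` from [randomSetDistribution()]
#' @param candidateMean output of [candidateMeanRanking()] for the
#'   candidate set
#' @return an `McResult`: list with `candidate_mean`, `fraction_surpassed`,
#'   `n_replicates`.
#' @export
percentileOfCandidate <- function(dist, candidateMean) {
  stopifnot(inherits(dist, "McDistribution"),
            length(dist$replicate_means) > 0L)
  structure(list(
    candidate_mean = candidateMean,
    fraction_surpassed = mean(dist$replicate_means > candidateMean),
    n_replicates = dist$n_replicates), class = "McResult")
}

#' @export
print.McResult <- function(x, ...) {
  cat(sprintf(
    "McResult: candidate mean ranking %.4f surpasses %.2f%% of %d random sets\n",
    x$candidate_mean, 100 * x$fraction_surpassed, x$n_replicates))
  invisible(x)
}

#' Histogram export of a Monte-Carlo distribution
#'
#' @param dist an `McDistribution`
#' @param breaks number of bins (default 30)
#' @return data.frame with `bin_left`, `bin_right`, `count`, suitable for
#'   CSV export.
#' @export
mcHistogram <- function(dist, breaks = 30L) {
  h <- graphics::hist(dist$replicate_means, breaks = breaks, plot = FALSE)
  data.frame(bin_left = h$breaks[-length(h$breaks)],
             bin_right = h$breaks[-1L], count = h$counts)
}
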