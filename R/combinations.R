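# Sequential-augmentation scoring of multi-gene normalization factors.
# Exactly one combination entry is present in the dataset at any time: the
# N-gene table becomes N+1 entries, all scorers and the final normalization
# score run on the augmented table, the combination's score and place are
# recorded, and the augmentation is discarded.

#' Per-sample profile of a gene combination
#'
#' The normalization factor of a combination is the per-sample arithmetic
#' mean of the member genes' Cq values (equivalently, the geometric mean of
#' their linear-scale abundances).
#'
#' @param x a curated [CqSet-class]
#' @param members character vector of 1-3 gene ids present in `x`
#' @return named numeric vector, one Cq value per sample
#' @export
combinationProfile <- function(x, members) {
  m <- cqValues(x)
  missing <- setdiff(members, rownames(m))
  if (length(missing))
    stop("unknown member gene(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(members)) stop("member genes must be distinct")
  colMeans(m[members, , drop = FALSE])
}

# Cached base-table statistics that do not involve the augmented entry.
# GeNorm M of gene j over the augmented table is ((N-1)*M_base_j + V_jc)/N,
# so only the N new pairwise SDs against the entry are computed per
# combination; BestKeeper base SDs are reused; NormFinder is recomputed in
# full on the augmented matrix (already linear in the table size).
.comboCache <- function(x, useGroups) {
  m <- .checkComplete(x)
  groups <- if (useGroups) sampleGroups(x) else NULL
  V <- .pairwiseSdMatrix(m)
  list(m = m, N = nrow(m), n = ncol(m), ids = rownames(m),
       Mbase = .genormM(V), sdBase = .rowSds(m), groups = groups,
       useGroups = useGroups)
}

.scoreAugmentedFast <- function(cache, profile, entryId) {
  m <- cache$m; N <- cache$N
  Vc <- .rowSds(matrix(profile, N, cache$n, byrow = TRUE) - m)
  genorm <- c(((N - 1) * cache$Mbase + Vc) / N, mean(Vc))
  bestkeeper <- c(cache$sdBase, sd(profile))
  maug <- rbind(m, profile)
  rownames(maug) <- c(cache$ids, entryId)
  ranks <- list(genorm = fractionalRank(genorm))
  if (cache$useGroups)
    ranks$normfinder_grouped <-
      fractionalRank(.nfGroupedVals(maug, cache$groups))
  ranks$normfinder_ungrouped <- fractionalRank(.nfUngroupedVals(maug))
  ranks$bestkeeper <- fractionalRank(bestkeeper)
  fs <- rowMeans(vapply(ranks, unname, numeric(N + 1L)))
  i <- N + 1L
  c(vapply(ranks, `[[`, numeric(1L), i),
    final_score = unname(fs[i]),
    place = sum(fs < fs[i]) + 1L)
}

.augmentedCqSet <- function(x, profile, entryId) {
  m <- cqValues(x)
  maug <- rbind(m, profile)
  rownames(maug) <- c(rownames(m), entryId)
  CqSet(maug, groups = sampleGroups(x), sourceTag = sourceTag(x),
        curated = TRUE, curationLog = curationLog(x))
}

#' Score one augmented combination entry
#'
#' Appends the combination profile to the dataset as a single extra entry,
#' computes all stability scorers and the final normalization score over
#' the N+1 entries, and reports the combination's fractional ranks, final
#' score and 1-based place (ties at the minimum all count as first). The
#' base table is never modified.
#'
#' @param x a curated [CqSet-class]
#' @param profile per-sample Cq profile (length `ncol(x)`), usually from
#'   [combinationProfile()]
#' @param entryId identifier for the augmented entry; must not collide
#'   with an existing gene id
#' @param useGroups include the grouped NormFinder variant (default: when
#'   group labels exist)
#' @param fastPath reuse cached base-table statistics (exactly equivalent
#'   to the naive full recomputation; set `FALSE` to force it)
#' @return one-row data.frame with `entry_id`, one `rank_<algorithm>`
#'   column per scorer, `final_score`, `place`, `n_entries`.
#' @export
scoreAugmentedEntry <- function(x, profile, entryId,
                                useGroups = !is.null(sampleGroups(x)),
                                fastPath = TRUE) {
  if (length(profile) != ncol(x))
    stop("profile length ", length(profile),
         " does not match sample count ", ncol(x))
  if (entryId %in% rownames(x))
    stop("entry id '", entryId, "' already present in the dataset")
  if (fastPath) {
    cache <- .comboCache(x, useGroups)
    v <- .scoreAugmentedFast(cache, profile, entryId)
  } else {
    fs <- finalScores(.augmentedCqSet(x, profile, entryId), useGroups)
    row <- fs[fs$entry_id == entryId, , drop = FALSE]
    rcols <- grep("^rank_", names(row), value = TRUE)
    v <- c(setNames(as.numeric(row[1L, rcols]), sub("^rank_", "", rcols)),
           final_score = row$final_score[1L], place = row$place[1L])
  }
  out <- data.frame(entry_id = entryId, t(v),
                    n_entries = nrow(x) + 1L,
                    row.names = NULL, check.names = FALSE)
  names(out) <- c("entry_id", paste0("rank_", names(v)[seq_len(length(v) - 2L)]),
                  "final_score", "place", "n_entries")
  out
}

.membersId <- function(members) paste(sort(members), collapse = ";")

#' Enumerate and score all k-gene combinations
#'
#' Scores every k-subset of the candidate pool as a normalization factor by
#' sequential augmentation: one combination at a time is appended to the
#' dataset, scored in the context of all N+1 entries, and removed again.
#' `k = 1` reduces exactly to the plain single-gene ranking (no
#' augmentation). Combinations longer than 3 are rejected; the
#' combinatorial cost grows too quickly for them to be practical.
#'
#' @param x a curated [CqSet-class]
#' @param k combination size, 1, 2 or 3
#' @param pool optional character vector restricting the candidate genes
#'   (default: all genes)
#' @param datasetId dataset label carried into the output (default: the
#'   source tag, or `"dataset"`)
#' @param useGroups include the grouped NormFinder variant
#' @param fastPath use cached base statistics (see [scoreAugmentedEntry()])
#' @return data.frame with one row per combination: `members`
#'   (semicolon-joined, sorted), `k`, `dataset_id`, per-algorithm entry
#'   ranks, `final_score`, `place`, `n_entries`.
#' @examples
#' sim <- simulateCqDataset(nGenes = 8, nSamples = 6, seed = 1)
#' x <- curateCqSet(sim$dataset)
#' nrow(enumerateCombinations(x, k = 2))  # choose(8, 2) = 28
#' @export
enumerateCombinations <- function(x, k, pool = NULL,
                                  datasetId = NULL,
                                  useGroups = !is.null(sampleGroups(x)),
                                  fastPath = TRUE) {
  stopifnot(is(x, "CqSet"))
  if (!k %in% 1:3)
    stop("k must be 1, 2 or 3; longer combinations are not supported")
  if (is.null(pool)) pool <- rownames(x)
  unknown <- setdiff(pool, rownames(x))
  if (length(unknown))
    stop("pool gene(s) not in dataset: ", paste(unknown, collapse = ", "))
  pool <- sort(unique(pool))
  if (length(pool) < k)
    stop("candidate pool (", length(pool), ") smaller than k = ", k)
  if (is.null(datasetId)) {
    datasetId <- sourceTag(x)
    if (is.na(datasetId)) datasetId <- "dataset"
  }
  if (k == 1L) {
    fs <- finalScores(x, useGroups)
    fs <- fs[fs$entry_id %in% pool, , drop = FALSE]
    rcols <- grep("^rank_", names(fs), value = TRUE)
    out <- data.frame(members = fs$entry_id, k = 1L, dataset_id = datasetId,
                      fs[, rcols, drop = FALSE],
                      final_score = fs$final_score, place = fs$place,
                      n_entries = nrow(x), row.names = NULL,
                      check.names = FALSE)
    return(out)
  }
  combos <- combn(pool, k, simplify = FALSE)
  m <- cqValues(x)
  if (fastPath) {
    cache <- .comboCache(x, useGroups)
    rows <- lapply(combos, function(mem) {
      profile <- colMeans(m[mem, , drop = FALSE])
      .scoreAugmentedFast(cache, profile, "..combo..")
    })
  } else {
    rows <- lapply(combos, function(mem) {
      profile <- colMeans(m[mem, , drop = FALSE])
      rec <- scoreAugmentedEntry(x, profile, "..combo..",
                                 useGroups = useGroups, fastPath = FALSE)
      v <- as.numeric(rec[1L, setdiff(names(rec), c("entry_id", "n_entries"))])
      names(v) <- sub("^rank_", "",
                      setdiff(names(rec), c("entry_id", "n_entries")))
      v
    })
  }
  vals <- do.call(rbind, rows)
  out <- data.frame(members = vapply(combos, .membersId, character(1L)),
                    k = k, dataset_id = datasetId,
                    vals[, seq_len(ncol(vals) - 2L), drop = FALSE],
                    final_score = vals[, "final_score"],
                    place = as.integer(vals[, "place"]),
                    n_entries = nrow(x) + 1L,
                    row.names = NULL, check.names = FALSE)
  names(out)[seq_len(ncol(vals) - 2L) + 3L] <-
    paste0("rank_", colnames(vals)[seq_len(ncol(vals) - 2L)])
  out
}

#' Score the global-mean normalization factor
#'
#' Scores the per-sample arithmetic mean of all genes (the "mean of all"
#' normalizer usable only on full arrays) as a single augmented entry,
#' with the member sentinel `"ALL"`.
#'
#' @inheritParams enumerateCombinations
#' @return one-row data.frame in the [enumerateCombinations()] layout.
#' @export
globalMeanFactor <- function(x, datasetId = NULL,
                             useGroups = !is.null(sampleGroups(x)),
                             fastPath = TRUE) {
  stopifnot(is(x, "CqSet"), nrow(x) >= 2L)
  if (is.null(datasetId)) {
    datasetId <- sourceTag(x)
    if (is.na(datasetId)) datasetId <- "dataset"
  }
  profile <- colMeans(cqValues(x))
  rec <- scoreAugmentedEntry(x, profile, "..all..", useGroups = useGroups,
                             fastPath = fastPath)
  rcols <- grep("^rank_", names(rec), value = TRUE)
  data.frame(members = "ALL", k = nrow(x), dataset_id = datasetId,
             rec[, rcols, drop = FALSE], final_score = rec$final_score,
             place = rec$place, n_entries = rec$n_entries,
             row.names = NULL, check.names = FALSE)
}

#' Compare combinations against their component genes
#'
#' Classifies every scored combination by how many of its component genes
#' are strictly better (lower final normalization score) references than
#' the combination itself, reproducing the component-wise comparison of
#' pairs and triples against single genes.
#'
#' @param records [enumerateCombinations()] output for `k >= 2`
#' @param singles [finalScores()] output (or k=1 records) for the same
#'   dataset, providing each component's single-gene final score
#' @return list with `per_combination` (records plus
#'   `n_components_better`, the count of strictly better components, and
#'   `category`: `worse_than_all_components` when every component beats
#'   the combination, `better_than_all_components` when none does,
#'   `better_than_some` otherwise) and `summary` (per dataset and k:
#'   category counts and fractions).
#' @export
compareToComponents <- function(records, singles) {
  idcol <- if ("entry_id" %in% names(singles)) "entry_id" else "members"
  singleScore <- setNames(singles$final_score, singles[[idcol]])
  memberList <- strsplit(records$members, ";", fixed = TRUE)
  missing <- setdiff(unique(unlist(memberList)), names(singleScore))
  if (length(missing))
    stop("no single-gene score for component(s): ",
         paste(missing, collapse = ", "))
  nBetter <- mapply(function(mem, fs) sum(singleScore[mem] < fs),
                    memberList, records$final_score)
  kk <- lengths(memberList)
  category <- ifelse(nBetter == kk, "worse_than_all_components",
              ifelse(nBetter == 0L, "better_than_all_components",
                     "better_than_some"))
  per <- cbind(records,
               n_components_better = as.integer(nBetter),
               category = category)
  key <- paste(per$dataset_id, per$k, per$category, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  summary <- data.frame(
    dataset_id = vapply(parts, `[[`, character(1L), 1L),
    k = as.integer(vapply(parts, `[[`, character(1L), 2L)),
    category = vapply(parts, `[[`, character(1L), 3L),
    count = as.integer(tab), row.names = NULL)
  tot <- stats::ave(summary$count,
                    paste(summary$dataset_id, summary$k, sep = "\r"),
                    FUN = sum)
  summary$fraction <- summary$count / tot
  list(per_combination = per, summary = summary)
}
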