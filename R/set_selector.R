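# From per-dataset combination rankings to a small reference set: index the
# first-place combinations, solve the minimal cover exactly, validate with
# triples, and quantify pairwise normalizing affinity.

#' Index first-place combinations per dataset
#'
#' Collects, per dataset and combination size, every combination whose
#' place is 1 (ties at the minimal final normalization score all count as
#' first).
#'
#' @param records data.frame of [enumerateCombinations()] output rows
#'   (any mix of datasets and k), or a list of such data.frames which is
#'   row-bound first.
#' @return a `FirstPlaceIndex`: list with one element per k (`"2"`, `"3"`,
#'   ...), each a named list mapping dataset id to a list of member
#'   character vectors.
#' @export
collectFirstPlace <- function(records) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  out <- list()
  if (!nrow(records))
    return(structure(out, class = "FirstPlaceIndex"))
  first <- records[records$place == 1L, , drop = FALSE]
  for (k in sort(unique(first$k))) {
    sub <- first[first$k == k, , drop = FALSE]
    byDs <- split(sub$members, sub$dataset_id)
    out[[as.character(k)]] <- lapply(byDs, function(v)
      strsplit(v, ";", fixed = TRUE))
  }
  structure(out, class = "FirstPlaceIndex")
}

#' @export
print.FirstPlaceIndex <- function(x, ...) {
  cat("FirstPlaceIndex\n")
  for (k in names(x))
    cat(sprintf("  k=%s: %d dataset(s), %s first-place combination(s)\n",
                k, length(x[[k]]),
                paste(lengths(x[[k]]), collapse = "/")))
  invisible(x)
}

#' Smallest gene set covering first-place pairs in every dataset
#'
#' Exact search (depth-first branch-and-bound over the first-place pairs)
#' for the smallest gene set S such that every dataset has at least one
#' first-place pair entirely contained in S. All minimal solutions are
#' returned, deterministically sorted.
#'
#' @param index a `FirstPlaceIndex` from [collectFirstPlace()]
#' @param k combination size whose first places must be covered (default 2)
#' @param maxSize give up beyond this set size (default: number of genes
#'   appearing in any first-place pair)
#' @return list with `feasible` (logical), `size` (minimal size or `NA`),
#'   `sets` (list of sorted character vectors, lexicographically ordered).
#' @export
minimalCoverSet <- function(index, k = 2L, maxSize = NULL) {
  key <- as.character(k)
  if (!key %in% names(index))
    stop("index has no k=", k, " first-place combinations")
  perDataset <- index[[key]]
  if (any(lengths(perDataset) == 0L))
    stop("every dataset needs at least one first-place combination")
  universe <- sort(unique(unlist(perDataset)))
  if (is.null(maxSize)) maxSize <- length(universe)
  best <- new.env(parent = emptyenv())
  best$size <- maxSize + 1L
  best$sets <- list()
  covers <- function(S, tuples) any(vapply(tuples, function(p)
    all(p %in% S), logical(1L)))
  recurse <- function(S) {
    if (length(S) > best$size) return(invisible())
    uncovered <- Filter(function(tuples) !covers(S, tuples), perDataset)
    if (!length(uncovered)) {
      if (length(S) < best$size) {
        best$size <- length(S)
        best$sets <- list(sort(S))
      } else if (length(S) == best$size) {
        best$sets <- c(best$sets, list(sort(S)))
      }
      return(invisible())
    }
    # branch on the uncovered dataset with the fewest candidate pairs
    target <- uncovered[[which.min(lengths(uncovered))]]
    for (p in target) {
      Sp <- union(S, p)
      if (length(Sp) <= min(best$size, maxSize)) recurse(Sp)
    }
    invisible()
  }
  recurse(character())
  sets <- unique(best$sets)
  ord <- order(vapply(sets, paste, character(1L), collapse = ";"))
  feasible <- length(sets) > 0L
  list(feasible = feasible,
       size = if (feasible) best$size else NA_integer_,
       sets = sets[ord])
}

#' Validate a candidate set against first-place triples
#'
#' Checks, per dataset, whether at least one first-place triple lies
#' entirely within the candidate set S — the triple-level validation of a
#' set selected on pairs.
#'
#' @param S character vector of candidate gene ids
#' @param index a `FirstPlaceIndex` containing k=3 entries
#' @return list with `per_dataset` (named logical vector) and `passed`
#'   (all datasets covered).
#' @export
validateSetWithTriples <- function(S, index) {
  if (!"3" %in% names(index))
    stop("index has no k=3 first-place combinations")
  per <- vapply(index[["3"]], function(tuples)
    any(vapply(tuples, function(tr) all(tr %in% S), logical(1L))),
    logical(1L))
  list(per_dataset = per, passed = all(per))
}

#' Pairwise normalizing-affinity matrix
#'
#' Counts how often two genes co-occur in first-place triples, normalized
#' so each dataset contributes equally: in mode `"per_dataset"` (default)
#' every first-place triple contributes weight `1 / T_d` to each of its 3
#' unordered pairs, where `T_d` is the number of first-place triples in
#' that dataset; weights are summed over datasets. Mode `"per_pair"`
#' normalizes each pair's count by the number of that dataset's
#' first-place triples containing the pair (so a pair contributes 1 per
#' dataset in which it appears at all).
#'
#' @param index a `FirstPlaceIndex` with k=3 entries
#' @param mode normalization mode, see above
#' @param genes optional gene universe for the matrix dimensions
#'   (default: all genes seen in first-place triples)
#' @return symmetric numeric matrix with zero diagonal
#' @export
pairAffinityMatrix <- function(index, mode = c("per_dataset", "per_pair"),
                               genes = NULL) {
  mode <- match.arg(mode)
  if (!"3" %in% names(index))
    stop("index has no k=3 first-place combinations")
  triplesByDs <- index[["3"]]
  if (is.null(genes))
    genes <- sort(unique(unlist(triplesByDs)))
  A <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  for (tuples in triplesByDs) {
    Td <- length(tuples)
    if (!Td) next
    D <- matrix(0, length(genes), length(genes),
                dimnames = list(genes, genes))
    for (tr in tuples) {
      prs <- combn(sort(tr), 2L)
      for (i in seq_len(ncol(prs))) {
        a <- prs[1L, i]; b <- prs[2L, i]
        D[a, b] <- D[a, b] + 1
        D[b, a] <- D[b, a] + 1
      }
    }
    if (mode == "per_dataset") {
      A <- A + D / Td
    } else {
      contrib <- (D > 0) * 1
      A <- A + contrib
    }
  }
  A
}
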