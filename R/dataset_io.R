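#' Read a Cq expression table from delimited text
#'
#' Reads a CSV/TSV matrix of quantification cycles with one identifier
#' column (or row, depending on orientation). Cells matching
#' `missingTokens`, and Cq values above `detectionCeiling` when one is set,
#' are recorded as missing — a qPCR reaction that never reaches the
#' detection threshold carries no quantitative information.
#'
#' @param path path to a delimited text file. The first column (or row) is
#'   taken as identifiers.
#' @param orientation `"genes-in-rows"` (default) or `"samples-in-rows"`;
#'   the in-memory layout is always genes x samples.
#' @param missingTokens character vector of cell values treated as
#'   non-detects in addition to empty cells. Default covers the tokens
#'   qPCR exports commonly use.
#' @param groupsPath optional path to a two-column (sample, group) delimited
#'   file assigning each sample to a group.
#' @param detectionCeiling optional Cq cutoff in cycles; values strictly
#'   above it become missing. Default `NULL` (token-based missingness only).
#' @param sep field separator; `NULL` guesses from the file extension
#'   (".tsv"/".txt" = tab, otherwise comma).
#'
#' @return A raw [CqSet-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,S1,S2", "miR-a,21,22", "miR-b,25,Undetermined"), f)
#' readCqTable(f)
#' @export
readCqTable <- function(path,
                        orientation = c("genes-in-rows", "samples-in-rows"),
                        missingTokens = c("", "NA", "N/A", "Undetermined",
                                          "undetermined", "No Ct"),
                        groupsPath = NULL, detectionCeiling = NULL,
                        sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- tryCatch(
    read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE,
             colClasses = "character"),
    error = function(e) stop("unparseable file '", path, "': ",
                             conditionMessage(e)))
  if (ncol(df) < 2L) stop("unparseable file '", path,
                          "': need one id column plus data columns")
  ids <- trimws(df[[1L]])
  hdr <- names(df)[-1L]      # before [.data.frame uniquifies duplicates
  cells <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(cells) <- list(ids, hdr)
  # flag missing tokens before numeric coercion so real parse errors surface
  cells[trimws(cells) %in% missingTokens] <- NA_character_
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                 dimnames = dimnames(cells)))
  bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("unparseable value '%s' at row %d ('%s'), column '%s'",
                 cells[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L] + 1L,
                 rownames(cells)[bad[1L, 1L]], colnames(cells)[bad[1L, 2L]]))
  if (orientation == "samples-in-rows") num <- t(num)
  if (anyDuplicated(colnames(num)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(num)[duplicated(colnames(num))]),
               collapse = ", "))
  if (!is.null(detectionCeiling))
    num[!is.na(num) & num > detectionCeiling] <- NA_real_
  groups <- NULL
  if (!is.null(groupsPath)) {
    gsep <- if (grepl("\\.(tsv|txt)$", groupsPath, ignore.case = TRUE)) "\t" else ","
    g <- read.csv(groupsPath, sep = gsep, stringsAsFactors = FALSE,
                  check.names = FALSE)
    if (ncol(g) < 2L) stop("groups file needs two columns: sample, group")
    idx <- match(colnames(num), trimws(as.character(g[[1L]])))
    if (anyNA(idx))
      stop("groups file is missing samples: ",
           paste(colnames(num)[is.na(idx)], collapse = ", "))
    groups <- as.character(g[[2L]])[idx]
  }
  CqSet(num, groups = groups, sourceTag = path)
}

#' Curate a raw Cq table
#'
#' Applies the curation rules used before any stability scoring: drop
#' chip-specific control probes (identifier pattern match), collapse
#' duplicate gene identifiers to their first occurrence, and remove every
#' gene with at least one missing value, so the curated table is complete.
#' Each removal is recorded with its reason.
#'
#' @param x a raw [CqSet-class]
#' @param controlPatterns character vector of regular expressions; genes
#'   whose identifier matches any pattern are removed as control probes.
#' @return a curated [CqSet-class] (complete matrix, unique gene ids) whose
#'   [curationLog()] lists `(gene_id, reason)` for every removal, with
#'   reasons in `"control_probe"`, `"duplicate"`, `"missing_values"`.
#' @examples
#' m <- matrix(c(20, 21, 25, NA, 18, 19), 3, 2, byrow = TRUE,
#'             dimnames = list(c("miR-a", "miR-b", "U6"), c("S1", "S2")))
#' curateCqSet(CqSet(m), controlPatterns = "^U6")
#' @export
curateCqSet <- function(x, controlPatterns = character()) {
  stopifnot(is(x, "CqSet"))
  m <- cqValues(x)
  log <- list()
  if (length(controlPatterns)) {
    ctrl <- Reduce(`|`, lapply(controlPatterns, grepl, x = rownames(m)))
    if (any(ctrl)) {
      log[["ctrl"]] <- data.frame(gene_id = rownames(m)[ctrl],
                                  reason = "control_probe")
      m <- m[!ctrl, , drop = FALSE]
    }
  }
  dup <- duplicated(rownames(m))
  if (any(dup)) {
    log[["dup"]] <- data.frame(gene_id = rownames(m)[dup],
                               reason = "duplicate")
    m <- m[!dup, , drop = FALSE]
  }
  incomplete <- !complete.cases(m)
  if (any(incomplete)) {
    log[["na"]] <- data.frame(gene_id = rownames(m)[incomplete],
                              reason = "missing_values")
    m <- m[!incomplete, , drop = FALSE]
  }
  if (nrow(m) < 2L)
    stop("curation left fewer than 2 genes; stability scoring is undefined")
  log <- if (length(log)) do.call(rbind, unname(log))
         else data.frame(gene_id = character(), reason = character())
  CqSet(m, groups = sampleGroups(x), sourceTag = sourceTag(x),
        curated = TRUE,
        curationLog = rbind(curationLog(x), log))
}

#' Check dataset inclusion criteria
#'
#' Reports whether a raw table meets the quality gates for entering a
#' reference-gene screen: enough genes for the scorers to have context,
#' enough samples for variance estimates, and a bounded non-detect
#' fraction. The comparison on missingness is strict (`< maxMissing`).
#'
#' @param x a [CqSet-class]
#' @param minGenes minimum number of measured genes (default 170)
#' @param minSamples minimum number of samples (default 5)
#' @param maxMissing maximum tolerated missing-value proportion, exclusive
#'   (default 0.20)
#' @return a list of class `InclusionReport` with fields `n_genes`,
#'   `n_samples`, `missing_fraction`, `passed`, `failed_rules`.
#' @examples
#' sim <- simulateCqDataset(nGenes = 180, nSamples = 6, seed = 1)
#' checkInclusion(sim$dataset)
#' @export
checkInclusion <- function(x, minGenes = 170L, minSamples = 5L,
                           maxMissing = 0.20) {
  stopifnot(is(x, "CqSet"))
  m <- cqValues(x)
  mf <- mean(is.na(m))
  failed <- c(
    if (nrow(m) < minGenes) "min_genes",
    if (ncol(m) < minSamples) "min_samples",
    if (mf >= maxMissing) "max_missing"
  )
  structure(list(n_genes = nrow(m), n_samples = ncol(m),
                 missing_fraction = mf,
                 passed = length(failed) == 0L,
                 failed_rules = as.character(failed)),
            class = "InclusionReport")
}

#' @export
print.InclusionReport <- function(x, ...) {
  cat(sprintf("InclusionReport: %d genes, %d samples, %.1f%% missing -> %s\n",
              x$n_genes, x$n_samples, 100 * x$missing_fraction,
              if (x$passed) "PASSED" else
                paste("FAILED:", paste(x$failed_rules, collapse = ", "))))
  invisible(x)
}

#' Write a curated Cq table and its curation log
#'
#' @param x a [CqSet-class]
#' @param path output CSV path for the matrix (genes in rows); the log is
#'   written next to it as `<path minus .csv>_curation_log.csv`.
#' @return invisibly, the two paths written.
#' @export
writeCqTable <- function(x, path) {
  stopifnot(is(x, "CqSet"))
  m <- cqValues(x)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  logPath <- sub("\\.csv$", "", path)
  logPath <- paste0(logPath, "_curation_log.csv")
  write.csv(curationLog(x), logPath, row.names = FALSE)
  invisible(c(table = path, log = logPath))
}
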