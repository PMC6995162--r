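#' @import methods
#' @importFrom stats sd var setNames complete.cases rnorm runif aggregate ave median cor
#' @importFrom utils combn read.csv write.csv head packageVersion
#' @importFrom graphics hist
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' CqSet: a container for RT-qPCR quantification-cycle tables
#'
#' `CqSet` extends [SummarizedExperiment::SummarizedExperiment] and stores a
#' genes-by-samples matrix of quantification cycles (Cq/Ct) in the `"cq"`
#' assay. Missing values (non-detects) are allowed in a raw object;
#' [curateCqSet()] removes them. An optional per-sample grouping factor lives
#' in `colData(x)$group` and drives the grouped NormFinder variant. Curation
#' provenance is kept in the object metadata (`curationLog(x)`,
#' `sourceTag(x)`).
#'
#' @slot curated logical scalar; `TRUE` after [curateCqSet()], which
#'   guarantees a complete matrix with unique gene identifiers.
#'
#' @seealso [CqSet()] (constructor), [readCqTable()], [curateCqSet()]
#' @aliases CqSet-class
#' @export
setClass("CqSet",
  contains = "SummarizedExperiment",
  representation(curated = "logical"),
  prototype(curated = FALSE)
)

setValidity("CqSet", function(object) {
  msg <- character()
  if (!"cq" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'cq' is required")
  else {
    m <- SummarizedExperiment::assay(object, "cq")
    if (!is.numeric(m))
      msg <- c(msg, "assay 'cq' must be numeric")
    else if (any(is.infinite(m)))
      msg <- c(msg, "Cq values must be finite where present")
    if (is.null(rownames(object)) || is.null(colnames(object)))
      msg <- c(msg, "gene (row) and sample (column) identifiers are required")
    else if (anyDuplicated(colnames(object)))
      msg <- c(msg, "duplicate sample identifiers")
    if (isTRUE(object@curated)) {
      if (anyNA(m)) msg <- c(msg, "curated CqSet must not contain missing values")
      if (anyDuplicated(rownames(object)))
        msg <- c(msg, "curated CqSet must have unique gene identifiers")
    }
  }
  if ("group" %in% colnames(SummarizedExperiment::colData(object))) {
    g <- SummarizedExperiment::colData(object)$group
    if (anyNA(g)) msg <- c(msg, "group labels must not contain NA")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CqSet
#'
#' @param cq numeric matrix of Cq values, genes in rows, samples in columns;
#'   dimnames required (row = gene ids, column = sample ids). `NA` marks a
#'   non-detect.
#' @param groups optional per-sample group labels (character/factor, length
#'   `ncol(cq)`), e.g. case/control.
#' @param sourceTag free-text provenance (file path, accession, "synthetic").
#' @param curated logical; assert the matrix is already curated (complete,
#'   unique gene ids).
#' @param curationLog data.frame with columns `gene_id`, `reason` recording
#'   removals, usually filled by [curateCqSet()].
#'
#' @return A [CqSet-class] object.
#' @examples
#' m <- matrix(rnorm(12, 25), 3, 4,
#'             dimnames = list(paste0("miR-", 1:3), paste0("S", 1:4)))
#' CqSet(m, groups = c("A", "A", "B", "B"))
#' @export
CqSet <- function(cq, groups = NULL, sourceTag = NA_character_,
                  curated = FALSE,
                  curationLog = data.frame(gene_id = character(),
                                           reason = character())) {
  stopifnot(is.matrix(cq))
  storage.mode(cq) <- "double"
  cd <- S4Vectors::DataFrame(row.names = colnames(cq))
  if (!is.null(groups)) {
    if (length(groups) != ncol(cq))
      stop("'groups' must have one label per sample")
    cd$group <- as.character(groups)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(cq = cq), colData = cd,
    metadata = list(source_tag = sourceTag, curation_log = curationLog))
  new("CqSet", se, curated = curated)
}

#' Accessors for CqSet
#'
#' `cqValues()` returns the Cq matrix, `sampleGroups()` the per-sample group
#' labels (or `NULL`), `curationLog()` the removal log, `sourceTag()` the
#' provenance string and `isCurated()` the curation flag.
#'
#' @param x a [CqSet-class]
#' @return `cqValues`: numeric matrix; `sampleGroups`: character vector or
#'   `NULL`; `curationLog`: data.frame; `sourceTag`: character scalar;
#'   `isCurated`: logical scalar.
#' @name CqSet-accessors
#' @export
cqValues <- function(x) SummarizedExperiment::assay(x, "cq")

#' @rdname CqSet-accessors
#' @export
sampleGroups <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("group" %in% colnames(cd)) as.character(cd$group) else NULL
}

#' @rdname CqSet-accessors
#' @export
curationLog <- function(x) S4Vectors::metadata(x)$curation_log

#' @rdname CqSet-accessors
#' @export
sourceTag <- function(x) S4Vectors::metadata(x)$source_tag

#' @rdname CqSet-accessors
#' @export
isCurated <- function(x) isTRUE(x@curated)

setMethod("show", "CqSet", function(object) {
  m <- cqValues(object)
  cat(sprintf("CqSet: %d genes x %d samples (%s)\n",
              nrow(object), ncol(object),
              if (isCurated(object)) "curated" else "raw"))
  nmiss <- sum(is.na(m))
  cat(sprintf("  missing (non-detect): %d (%.1f%%)\n",
              nmiss, 100 * nmiss / max(1L, length(m))))
  g <- sampleGroups(object)
  if (!is.null(g))
    cat("  groups:", paste(sprintf("%s(%d)", names(table(g)), table(g)),
                           collapse = ", "), "\n")
  st <- sourceTag(object)
  if (!is.na(st)) cat("  source:", st, "\n")
  invisible(object)
})

#' StabilityScores: per-gene output of one stability algorithm
#'
#' Holds the raw stability value of every gene under a single algorithm;
#' lower values mean higher stability. For iterative GeNorm the stepwise
#' exclusion order is kept alongside.
#'
#' @slot algorithm one of `"genorm"`, `"normfinder_grouped"`,
#'   `"normfinder_ungrouped"`, `"bestkeeper"`.
#' @slot scores named numeric vector, one stability value per gene.
#' @slot exclusionOrder character vector of genes in order of removal
#'   (worst first); the final two genes share the last position. Empty
#'   unless GeNorm ran in iterative mode.
#' @aliases StabilityScores-class stabilityValues algorithmName exclusionOrder
#' @export stabilityValues algorithmName exclusionOrder
#' @exportClass StabilityScores
setClass("StabilityScores", representation(
  algorithm = "character",
  scores = "numeric",
  exclusionOrder = "character"
))

setValidity("StabilityScores", function(object) {
  msg <- character()
  if (length(object@algorithm) != 1L ||
      !object@algorithm %in% c("genorm", "normfinder_grouped",
                               "normfinder_ungrouped", "bestkeeper"))
    msg <- c(msg, "unknown algorithm")
  if (is.null(names(object@scores)) || anyDuplicated(names(object@scores)))
    msg <- c(msg, "scores must be uniquely named by gene")
  if (any(!is.finite(object@scores)))
    msg <- c(msg, "stability values must be finite")
  if (object@algorithm %in% c("genorm", "bestkeeper") &&
      any(object@scores < 0))
    msg <- c(msg, "genorm/bestkeeper stability values must be >= 0")
  if (length(msg)) msg else TRUE
})

StabilityScores <- function(algorithm, scores, exclusionOrder = character()) {
  new("StabilityScores", algorithm = algorithm, scores = scores,
      exclusionOrder = exclusionOrder)
}

#' @describeIn StabilityScores-class named numeric vector of stability values
stabilityValues <- function(x) x@scores

#' @describeIn StabilityScores-class algorithm identifier
algorithmName <- function(x) x@algorithm

#' @describeIn StabilityScores-class iterative GeNorm exclusion order
exclusionOrder <- function(x) x@exclusionOrder

setMethod("show", "StabilityScores", function(object) {
  cat(sprintf("StabilityScores [%s], %d genes\n",
              object@algorithm, length(object@scores)))
  s <- sort(object@scores)
  cat("  most stable:",
      paste(sprintf("%s=%.4g", names(head(s, 3)), head(s, 3)),
            collapse = ", "), "\n")
  if (length(object@exclusionOrder))
    cat("  exclusion order (worst first):",
        paste(head(object@exclusionOrder, 5), collapse = " > "),
        if (length(object@exclusionOrder) > 5) "..." else "", "\n")
  invisible(object)
})
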