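# Stability scorers. All operate on complete Cq matrices (genes x samples).
# Cq is already a log2-scale quantity (one cycle = one doubling), so the
# log2 expression ratio of gene j vs gene k in a sample is Cq_k - Cq_j and
# no further transformation is applied. Sample SD (n-1 denominator)
# throughout.

.rowSds <- function(m) {
  n <- ncol(m)
  if (n < 2L) stop("need >= 2 samples")
  sqrt(rowSums((m - rowMeans(m))^2) / (n - 1L))
}

.checkComplete <- function(x) {
  stopifnot(is(x, "CqSet"))
  m <- cqValues(x)
  if (anyNA(m))
    stop("Cq matrix contains missing values; curate first (curateCqSet)")
  if (nrow(m) < 2L) stop("need >= 2 genes")
  if (ncol(m) < 2L) stop("need >= 2 samples")
  m
}

# V[j,k] = sd over samples of (Cq_k - Cq_j); symmetric, zero diagonal
.pairwiseSdMatrix <- function(m) {
  N <- nrow(m)
  V <- matrix(0, N, N, dimnames = list(rownames(m), rownames(m)))
  for (j in seq_len(N)) {
    d <- m - matrix(m[j, ], N, ncol(m), byrow = TRUE)
    V[, j] <- .rowSds(d)
  }
  diag(V) <- 0
  V
}

.genormM <- function(V) {
  N <- nrow(V)
  setNames(rowSums(V) / (N - 1L), rownames(V))
}

#' GeNorm expression-stability value M
#'
#' For gene j, M is the arithmetic mean over all other genes k of the
#' standard deviation of the pairwise log2 expression ratio across samples;
#' on Cq input that ratio is `Cq_k - Cq_j`. Lower M means higher stability.
#' In `"iterative"` mode the gene with the highest M is repeatedly removed
#' and M recomputed until two genes remain (the classical stepwise ranking);
#' the final two share the last step.
#'
#' @param x a curated [CqSet-class]
#' @param mode `"single_pass"` (first-iteration M for every gene, used for
#'   ranking) or `"iterative"` (adds the exclusion order; each gene's score
#'   is its M at the iteration of its removal).
#' @return a [StabilityScores-class] with `algorithm = "genorm"`.
#' @examples
#' sim <- simulateCqDataset(nGenes = 10, nSamples = 6, seed = 1)
#' genormScores(curateCqSet(sim$dataset))
#' @export
genormScores <- function(x, mode = c("single_pass", "iterative")) {
  mode <- match.arg(mode)
  m <- .checkComplete(x)
  V <- .pairwiseSdMatrix(m)
  if (mode == "single_pass")
    return(StabilityScores("genorm", .genormM(V)))
  if (nrow(m) < 3L)
    stop("iterative mode needs >= 3 genes")
  scores <- setNames(numeric(nrow(m)), rownames(m))
  excluded <- character()
  keep <- rownames(m)
  while (length(keep) > 2L) {
    M <- .genormM(V[keep, keep])
    worst <- names(M)[M == max(M)]
    worst <- sort(worst)[1L]            # deterministic tie-break
    scores[worst] <- M[worst]
    excluded <- c(excluded, worst)
    keep <- setdiff(keep, worst)
  }
  M <- .genormM(V[keep, keep])
  scores[keep] <- M
  StabilityScores("genorm", scores,
                  exclusionOrder = c(excluded, sort(keep)))
}

# NormFinder simplified closed-form estimator, following the original
# model-based formulation: log-scale data y_igj = gene-group effect +
# sample effect + noise. Per group, sample means (over genes) are removed;
# a_ig is the gene's group average, s2_ig its residual variance. Because
# subtracting the sample mean mixes all genes' noise, E[s2_ig] =
# (1-2/k) sig2_ig + T_g/k^2 with T_g the summed true variances; the
# corrected sig2_ig inverts that (floored at 0; skipped when k < 3 where
# the inversion is undefined).
.nfGroupStats <- function(m, groups) {
  k <- nrow(m)
  gl <- split(seq_along(groups), groups)
  a <- s2 <- matrix(NA_real_, k, length(gl),
                    dimnames = list(rownames(m), names(gl)))
  ng <- lengths(gl)
  for (g in seq_along(gl)) {
    mg <- m[, gl[[g]], drop = FALSE]
    r <- sweep(mg, 2L, colMeans(mg))
    a[, g] <- rowMeans(r)
    s2[, g] <- rowSums((r - a[, g])^2) / (ng[g] - 1L)
  }
  sig2 <- if (k >= 3L) {
    Tg <- (k / (k - 1)) * colSums(s2)
    pmax(sweep(s2, 2L, Tg / k^2) * k / (k - 2), 0)
  } else s2
  list(a = a, sig2 = sig2, ng = ng)
}

.nfUngroupedVals <- function(m) {
  st <- .nfGroupStats(m, rep("all", ncol(m)))
  setNames(sqrt(st$sig2[, 1L]), rownames(m))
}

.nfGroupedVals <- function(m, groups) {
  st <- .nfGroupStats(m, groups)
  k <- nrow(m); G <- length(st$ng)
  d <- st$a - rowMeans(st$a)                     # intergroup differences
  v <- sweep(st$sig2, 2L, st$ng, `/`)            # sampling variance of d
  gamma2 <- max(0, sum(d^2) / ((G - 1) * (k - 1)) - mean(v))
  shrink <- ifelse(gamma2 + v > 0, gamma2 / (gamma2 + v), 0)
  stab <- abs(d * shrink) + sqrt(v * shrink)
  setNames(rowMeans(stab), rownames(m))
}

#' NormFinder model-based stability value
#'
#' Implements the model-based candidate-gene estimator in its simplified
#' closed form. The grouped variant decomposes each gene's (log-scale, here
#' Cq) expression into a systematic intergroup difference and intragroup
#' noise: intragroup variances are estimated per gene and group with a
#' common-variance correction, intergroup differences are shrunk towards
#' zero by the empirical-Bayes factor `gamma2 / (gamma2 + sig2_ig/n_g)`
#' (where `gamma2` is a moment estimate of the variance of true group
#' differences across genes), and the stability value is the absolute
#' shrunk difference plus the posterior SD, averaged over groups. The
#' ungrouped variant treats all samples as one group and scores each gene
#' by its residual SD after removing gene and sample effects (with the same
#' common-variance correction). Lower values mean higher stability.
#'
#' @param x a curated [CqSet-class]
#' @param useGroups logical; defaults to `TRUE` when `x` carries group
#'   labels. The grouped variant requires >= 2 groups with >= 2 samples
#'   each.
#' @return a [StabilityScores-class] with algorithm
#'   `"normfinder_grouped"` or `"normfinder_ungrouped"`.
#' @examples
#' sim <- simulateCqDataset(nGenes = 12, nSamples = 8, nGroups = 2, seed = 1)
#' normfinderScores(curateCqSet(sim$dataset))
#' @export
normfinderScores <- function(x, useGroups = !is.null(sampleGroups(x))) {
  m <- .checkComplete(x)
  if (!useGroups)
    return(StabilityScores("normfinder_ungrouped", .nfUngroupedVals(m)))
  groups <- sampleGroups(x)
  if (is.null(groups)) stop("useGroups = TRUE but no group labels present")
  tab <- table(groups)
  if (length(tab) < 2L) stop("grouped variant needs >= 2 groups")
  if (any(tab < 2L))
    stop("every group needs >= 2 samples (offending: ",
         paste(names(tab)[tab < 2L], collapse = ", "), ")")
  StabilityScores("normfinder_grouped", .nfGroupedVals(m, groups))
}

#' BestKeeper stability: per-gene Cq standard deviation
#'
#' Scores each gene by the sample standard deviation of its Cq values
#' across samples; genes with lower SD are considered more stable.
#'
#' @param x a curated [CqSet-class]
#' @return a [StabilityScores-class] with `algorithm = "bestkeeper"`.
#' @examples
#' sim <- simulateCqDataset(nGenes = 10, nSamples = 6, seed = 1)
#' bestkeeperScores(curateCqSet(sim$dataset))
#' @export
bestkeeperScores <- function(x) {
  m <- .checkComplete(x)
  StabilityScores("bestkeeper", setNames(.rowSds(m), rownames(m)))
}

#' BestKeeper index diagnostics
#'
#' Optional diagnostic companion to [bestkeeperScores()]: the BestKeeper
#' index is the per-sample arithmetic mean Cq over all genes (the geometric
#' mean on the linear scale); each gene is additionally characterised by
#' its Pearson correlation with that index. The correlations are
#' descriptive only and do not enter the normalization score.
#'
#' @param x a curated [CqSet-class]
#' @return data.frame with columns `gene_id`, `sd`, `cor_with_index`.
#' @export
bestkeeperDiagnostics <- function(x) {
  m <- .checkComplete(x)
  idx <- colMeans(m)
  data.frame(gene_id = rownames(m),
             sd = .rowSds(m),
             cor_with_index = apply(m, 1L, stats::cor, y = idx),
             row.names = NULL)
}

#' Export stability scores as a tidy table
#'
#' @param ... one or more [StabilityScores-class] objects
#' @return data.frame with columns `gene_id`, `algorithm`,
#'   `stability_value`.
#' @export
stabilityTable <- function(...) {
  objs <- list(...)
  do.call(rbind, lapply(objs, function(s) {
    data.frame(gene_id = names(stabilityValues(s)),
               algorithm = algorithmName(s),
               stability_value = unname(stabilityValues(s)),
               row.names = NULL)
  }))
}
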