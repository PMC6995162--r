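# Shared fixtures and independent reference implementations. The oracles
# below are deliberately loop-based, direct transcriptions of the published
# formulas, kept free of any code shared with the package internals.

randCqSet <- function(nGenes, nSamples, seed, groups = NULL,
                      cqRange = c(15, 35), noiseSd = 1.5) {
  set.seed(seed)
  m <- matrix(runif(nGenes, cqRange[1], cqRange[2]) +
                rnorm(nGenes * nSamples, sd = noiseSd),
              nGenes, nSamples,
              dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                              sprintf("s%02d", seq_len(nSamples))))
  CqSet(m, groups = groups, curated = TRUE)
}

writeTempCsv <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# --- GeNorm oracle: brute-force pairwise SDs, explicit loops ------------

oracleSd <- function(v) {
  mu <- sum(v) / length(v)
  sqrt(sum((v - mu)^2) / (length(v) - 1))
}

oracleGenormM <- function(m) {
  N <- nrow(m)
  M <- numeric(N)
  for (j in seq_len(N)) {
    vs <- numeric(0)
    for (k in seq_len(N)) {
      if (k == j) next
      vs <- c(vs, oracleSd(m[k, ] - m[j, ]))   # log2 ratio on Cq scale
    }
    M[j] <- mean(vs)
  }
  names(M) <- rownames(m)
  M
}

oracleGenormExclusion <- function(m) {
  order <- character(0)
  cur <- m
  while (nrow(cur) > 2) {
    M <- oracleGenormM(cur)
    worst <- sort(names(M)[M == max(M)])[1]
    order <- c(order, worst)
    cur <- cur[rownames(cur) != worst, , drop = FALSE]
  }
  c(order, sort(rownames(cur)))
}

# --- NormFinder oracle: direct transcription of the model-based
# estimator (sample-mean removal, common-variance correction, moment
# estimate of the intergroup variance, shrinkage, |d| + posterior SD) ----

oracleNormfinderGrouped <- function(m, groups) {
  k <- nrow(m)
  gs <- sort(unique(groups))
  G <- length(gs)
  a <- matrix(0, k, G)
  s2 <- matrix(0, k, G)
  ng <- integer(G)
  for (gi in seq_len(G)) {
    cols <- which(groups == gs[gi])
    ng[gi] <- length(cols)
    for (i in seq_len(k)) {
      r <- numeric(length(cols))
      for (ci in seq_along(cols)) {
        s <- cols[ci]
        r[ci] <- m[i, s] - mean(m[, s])
      }
      a[i, gi] <- mean(r)
      s2[i, gi] <- sum((r - mean(r))^2) / (ng[gi] - 1)
    }
  }
  sig2 <- matrix(0, k, G)
  for (gi in seq_len(G)) {
    Tg <- (k / (k - 1)) * sum(s2[, gi])
    for (i in seq_len(k))
      sig2[i, gi] <- max(0, (s2[i, gi] - Tg / k^2) * k / (k - 2))
  }
  d <- a - rowMeans(a)
  v <- matrix(0, k, G)
  for (gi in seq_len(G)) v[, gi] <- sig2[, gi] / ng[gi]
  gamma2 <- max(0, sum(d^2) / ((G - 1) * (k - 1)) - mean(v))
  stab <- matrix(0, k, G)
  for (i in seq_len(k)) for (gi in seq_len(G)) {
    shr <- if (gamma2 + v[i, gi] > 0) gamma2 / (gamma2 + v[i, gi]) else 0
    stab[i, gi] <- abs(d[i, gi] * shr) + sqrt(v[i, gi] * shr)
  }
  setNames(rowMeans(stab), rownames(m))
}

# --- exhaustive minimal-cover oracle for small pools --------------------

oracleMinimalCover <- function(pairsByDataset, maxSize) {
  universe <- sort(unique(unlist(pairsByDataset)))
  for (size in seq_len(min(maxSize, length(universe)))) {
    sols <- list()
    for (S in combn(universe, size, simplify = FALSE)) {
      ok <- all(vapply(pairsByDataset, function(tuples)
        any(vapply(tuples, function(p) all(p %in% S), logical(1))),
        logical(1)))
      if (ok) sols <- c(sols, list(S))
    }
    if (length(sols)) return(list(size = size, sets = sols))
  }
  list(size = NA_integer_, sets = list())
}
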