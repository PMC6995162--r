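test_that("GeNorm M is zero for constant-ratio genes and matches the hand example", {
  # gene B = gene A + constant shift: the pairwise ratio never varies
  m <- matrix(c(20, 22, 24, 23, 25, 27), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  M <- stabilityValues(genormScores(CqSet(m, curated = TRUE)))
  expect_equal(unname(M), c(0, 0))

  # frozen 3-gene example: sd(C - A) = sd(c(0, 2, -2)) = 2, so
  # M_A = M_B = mean(0, 2) = 1 and M_C = mean(2, 2) = 2
  m3 <- matrix(c(20, 21, 22, 20, 21, 22, 20, 23, 20), 3, 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
  M3 <- stabilityValues(genormScores(CqSet(m3, curated = TRUE)))
  expect_equal(M3, c(A = 1, B = 1, C = 2))
  expect_equal(M3, oracleGenormM(m3))
})

test_that("for a 2-gene table the two single-pass M values are exactly equal", {
  x <- randCqSet(2, 7, seed = 31)
  M <- stabilityValues(genormScores(x))
  expect_identical(M[[1]], M[[2]])
})

test_that("iterative GeNorm reproduces the naive full-recompute exclusion order", {
  for (seed in 1:20) {
    x <- randCqSet(6, 6, seed = 100 + seed)
    it <- genormScores(x, mode = "iterative")
    expect_identical(exclusionOrder(it), oracleGenormExclusion(cqValues(x)))
  }
  expect_error(genormScores(randCqSet(2, 4, seed = 1), mode = "iterative"),
               ">= 3 genes")
})

test_that("BestKeeper SD matches hand calculations and is shift-invariant", {
  m <- matrix(c(25, 25, 25, 25, 20, 22, 24, 26), 2, 4, byrow = TRUE,
              dimnames = list(c("const", "ramp"), paste0("s", 1:4)))
  s <- stabilityValues(bestkeeperScores(CqSet(m, curated = TRUE)))
  expect_equal(s[["const"]], 0)
  expect_equal(s[["ramp"]], sd(c(20, 22, 24, 26)))

  x <- randCqSet(6, 5, seed = 41)
  shifted <- CqSet(cqValues(x) + runif(6, -3, 3), curated = TRUE)
  expect_equal(stabilityValues(bestkeeperScores(x)),
               stabilityValues(bestkeeperScores(shifted)))
})

test_that("a gene tracking the per-sample mean gets the best ungrouped NormFinder score", {
  set.seed(7)
  m <- matrix(rnorm(5 * 8, 25, 2), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  m[1, ] <- colMeans(m[-1, ]) + 3   # zero residual after sample centering
  s <- stabilityValues(normfinderScores(CqSet(m, curated = TRUE),
                                        useGroups = FALSE))
  expect_equal(unname(which.min(s)), 1L)
})

test_that("grouped NormFinder matches the independent formula oracle", {
  for (seed in 1:15) {
    G <- sample(2:3, 1)
    n <- G * sample(3:5, 1)
    groups <- rep(paste0("G", seq_len(G)), length.out = n)
    x <- randCqSet(sample(5:9, 1), n, seed = 300 + seed, groups = groups)
    # add group effects so the intergroup component is active
    m <- cqValues(x)
    eff <- matrix(rnorm(nrow(m) * G, sd = 1), nrow(m), G)
    m <- m + eff[, match(groups, paste0("G", seq_len(G)))]
    x <- CqSet(m, groups = groups, curated = TRUE)
    expect_equal(stabilityValues(normfinderScores(x, useGroups = TRUE)),
                 oracleNormfinderGrouped(m, groups), tolerance = 1e-12)
  }
})

test_that("a planted zero-group-effect, low-noise gene wins grouped NormFinder", {
  sim <- simulateCqDataset(nGenes = 40, nSamples = 12, nGroups = 2,
                           nStable = 1, stableSd = 0.05,
                           unstableSdRange = c(1, 3), seed = 9)
  x <- curateCqSet(sim$dataset)
  s <- stabilityValues(normfinderScores(x, useGroups = TRUE))
  expect_equal(names(which.min(s)), sim$truth$stable_gene_ids)
})

test_that("grouped NormFinder validates its preconditions", {
  x <- randCqSet(5, 4, seed = 3)
  expect_error(normfinderScores(x, useGroups = TRUE), "no group labels")
  x1 <- randCqSet(5, 3, seed = 3, groups = c("A", "A", "B"))
  expect_error(normfinderScores(x1, useGroups = TRUE), ">= 2 samples")
})

test_that("scores are invariant to sample permutations and sample-wise shifts", {
  x <- randCqSet(7, 6, seed = 55, groups = rep(c("A", "B"), each = 3))
  m <- cqValues(x)
  perm <- c(4, 1, 6, 2, 5, 3)
  xp <- CqSet(m[, perm], groups = sampleGroups(x)[perm], curated = TRUE)
  for (fn in list(function(z) genormScores(z),
                  function(z) bestkeeperScores(z),
                  function(z) normfinderScores(z, useGroups = TRUE),
                  function(z) normfinderScores(z, useGroups = FALSE)))
    expect_equal(stabilityValues(fn(x)), stabilityValues(fn(xp)))

  # per-sample constant shifts cancel in pairwise ratios
  shifts <- runif(ncol(m), -2, 2)
  xs <- CqSet(sweep(m, 2, shifts, `+`), curated = TRUE)
  expect_equal(stabilityValues(genormScores(x)),
               stabilityValues(genormScores(xs)))
})

test_that("missing values are rejected before scoring", {
  m <- matrix(c(20, NA, 21, 22), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(genormScores(CqSet(m)), "missing")
})

test_that("BestKeeper diagnostics report the index correlation", {
  x <- randCqSet(5, 8, seed = 77)
  d <- bestkeeperDiagnostics(x)
  expect_named(d, c("gene_id", "sd", "cor_with_index"))
  idx <- colMeans(cqValues(x))
  expect_equal(d$cor_with_index[1], cor(cqValues(x)[1, ], idx))
})
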