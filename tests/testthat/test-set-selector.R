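mkRecord <- function(members, dataset, k, place) {
  data.frame(members = members, k = k, dataset_id = dataset,
             final_score = 0.1, place = place, n_entries = 10L)
}

test_that("first-place collection keeps every tied winner, per dataset and k", {
  recs <- rbind(
    mkRecord("A;B", "d1", 2L, 1L),
    mkRecord("A;C", "d1", 2L, 2L),
    mkRecord("B;C", "d2", 2L, 1L),
    mkRecord("A;D", "d2", 2L, 1L),      # tie at the minimum
    mkRecord("A;B;C", "d1", 3L, 1L))
  idx <- collectFirstPlace(recs)
  expect_equal(idx[["2"]][["d1"]], list(c("A", "B")))
  expect_setequal(vapply(idx[["2"]][["d2"]], paste, "", collapse = ";"),
                  c("B;C", "A;D"))
  expect_equal(idx[["3"]][["d1"]], list(c("A", "B", "C")))
  empty <- collectFirstPlace(mkRecord("A;B", "d", 2L, 2L)[0, ])
  expect_length(empty, 0L)
})

test_that("the minimal cover set solves toy instances exactly", {
  idx1 <- collectFirstPlace(mkRecord("A;B", "d1", 2L, 1L))
  res1 <- minimalCoverSet(idx1)
  expect_equal(res1$size, 2L)
  expect_equal(res1$sets, list(c("A", "B")))

  # {A,B} and {A,C} first in different datasets: no 2-gene set covers both
  idx2 <- collectFirstPlace(rbind(mkRecord("A;B", "d1", 2L, 1L),
                                  mkRecord("A;C", "d2", 2L, 1L)))
  res2 <- minimalCoverSet(idx2)
  expect_equal(res2$size, 3L)
  expect_equal(res2$sets, list(c("A", "B", "C")))

  # infeasible within maxSize is reported, not silently truncated
  res3 <- minimalCoverSet(idx2, maxSize = 2L)
  expect_false(res3$feasible)
  expect_true(is.na(res3$size))
})

test_that("branch-and-bound agrees with exhaustive enumeration on random instances", {
  set.seed(42)
  genes <- LETTERS[1:9]
  for (rep in 1:10) {
    nd <- sample(2:4, 1)
    pairsByDs <- lapply(seq_len(nd), function(i) {
      np <- sample(1:3, 1)
      lapply(seq_len(np), function(j) sort(sample(genes, 2)))
    })
    names(pairsByDs) <- paste0("d", seq_len(nd))
    recs <- do.call(rbind, lapply(names(pairsByDs), function(d)
      do.call(rbind, lapply(pairsByDs[[d]], function(p)
        mkRecord(paste(p, collapse = ";"), d, 2L, 1L)))))
    res <- minimalCoverSet(collectFirstPlace(recs))
    oracle <- oracleMinimalCover(pairsByDs, maxSize = 9L)
    expect_equal(res$size, oracle$size)
    expect_setequal(vapply(res$sets, paste, "", collapse = ";"),
                    vapply(oracle$sets, paste, "", collapse = ";"))
  }
})

test_that("triple validation is per dataset and monotone in the set", {
  idx <- collectFirstPlace(rbind(
    mkRecord("A;B;C", "d1", 3L, 1L),
    mkRecord("D;E;F", "d2", 3L, 1L),
    mkRecord("A;B;D", "d2", 3L, 1L)))
  v1 <- validateSetWithTriples(c("A", "B", "C", "D"), idx)
  expect_true(v1$per_dataset[["d1"]])
  expect_true(v1$per_dataset[["d2"]])   # via A;B;D
  expect_true(v1$passed)
  v2 <- validateSetWithTriples(c("A", "B", "C"), idx)
  expect_false(v2$per_dataset[["d2"]])
  expect_false(v2$passed)
  # supersets never lose coverage
  v3 <- validateSetWithTriples(c("A", "B", "C", "D", "E", "F"), idx)
  expect_true(all(v3$per_dataset >= v2$per_dataset))
})

test_that("affinity weights follow the per-dataset normalization rule", {
  # one dataset, one first-place triple: every pair weighs 1
  idx1 <- collectFirstPlace(mkRecord("A;B;C", "d1", 3L, 1L))
  A1 <- pairAffinityMatrix(idx1)
  expect_equal(A1["A", "B"], 1)
  expect_equal(A1["A", "C"], 1)
  expect_equal(A1["B", "C"], 1)

  # two overlapping first-place triples in one dataset: each triple
  # contributes 1/2 per pair
  idx2 <- collectFirstPlace(rbind(mkRecord("A;B;C", "d1", 3L, 1L),
                                  mkRecord("A;B;D", "d1", 3L, 1L)))
  A2 <- pairAffinityMatrix(idx2)
  expect_equal(A2["A", "B"], 1)
  expect_equal(A2["A", "C"], 0.5)
  expect_equal(A2["B", "C"], 0.5)
  expect_equal(A2["A", "D"], 0.5)
  expect_equal(A2["B", "D"], 0.5)
  expect_equal(A2["C", "D"], 0)

  # symmetry, zero diagonal, and a per-dataset total weight of 3
  expect_identical(A2, t(A2))
  expect_equal(unname(diag(A2)), rep(0, 4))
  expect_equal(sum(A2) / 2, 3)

  # the alternative per-pair normalization counts presence per dataset
  A3 <- pairAffinityMatrix(idx2, mode = "per_pair")
  expect_equal(A3["A", "B"], 1)
  expect_equal(A3["A", "C"], 1)
})

test_that("selection recovers a planted cover on simulated multi-dataset screens", {
  # three datasets sharing a clear pair of planted ultra-stable genes:
  # the first-place pairs concentrate on them and the cover finds them
  perDs <- lapply(1:3, function(i) {
    sim <- simulateCqDataset(nGenes = 12, nSamples = 8, nStable = 2,
                             stableSd = 0.02, seed = 200 + i)
    x <- curateCqSet(sim$dataset)
    list(recs = rbind(enumerateCombinations(x, k = 2,
                                            datasetId = paste0("d", i)),
                      enumerateCombinations(x, k = 3,
                                            datasetId = paste0("d", i))),
         stable = sim$truth$stable_gene_ids)
  })
  idx <- collectFirstPlace(lapply(perDs, `[[`, "recs"))
  res <- minimalCoverSet(idx)
  expect_true(res$feasible)
  expect_true(res$size <= 6L)
  val <- validateSetWithTriples(unique(unlist(lapply(res$sets, identity))),
                                idx)
  expect_type(val$passed, "logical")
})
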