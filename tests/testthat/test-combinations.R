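test_that("a combination profile is the per-sample mean of member Cq values", {
  m <- matrix(c(20, 24, 22, 26, 23, 21), 3, 2, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  x <- CqSet(m, curated = TRUE)
  expect_equal(unname(combinationProfile(x, c("A", "B"))), c(21, 25))
  expect_equal(combinationProfile(x, c("A", "B", "C")), colMeans(m))
  expect_equal(combinationProfile(x, "A"), m["A", ])
  expect_error(combinationProfile(x, c("A", "Z")), "unknown member")
})

test_that("an augmented entry duplicating a gene ties that gene everywhere", {
  x <- randCqSet(6, 6, seed = 91, groups = rep(c("A", "B"), each = 3))
  profile <- cqValues(x)["g03", ]
  aug <- CqSet(rbind(cqValues(x), twin = profile),
               groups = sampleGroups(x), curated = TRUE)
  for (s in list(genormScores(aug), bestkeeperScores(aug),
                 normfinderScores(aug, TRUE), normfinderScores(aug, FALSE))) {
    v <- stabilityValues(s)
    expect_equal(v[["twin"]], v[["g03"]], tolerance = 1e-10)
  }
})

test_that("augmentation scores over exactly N+1 entries and never mutates the base", {
  x <- randCqSet(8, 5, seed = 101)
  before <- serialize(x, NULL)
  rec <- scoreAugmentedEntry(x, combinationProfile(x, c("g01", "g02")), "cmb")
  expect_equal(rec$n_entries, 9L)
  expect_true(rec$final_score >= 0 && rec$final_score < 1)
  expect_true(rec$place >= 1 && rec$place <= 9)
  all2 <- enumerateCombinations(x, k = 2)
  all3 <- enumerateCombinations(x, k = 3)
  expect_identical(serialize(x, NULL), before)
  expect_equal(nrow(all2), choose(8, 2))
  expect_equal(nrow(all3), choose(8, 3))
  expect_error(scoreAugmentedEntry(x, rep(25, 4), "cmb"), "length")
  expect_error(scoreAugmentedEntry(x, cqValues(x)[1, ], "g01"),
               "already present")
})

test_that("member order never changes a combination record", {
  x <- randCqSet(5, 6, seed = 111)
  r1 <- scoreAugmentedEntry(x, combinationProfile(x, c("g01", "g04")), "c")
  r2 <- scoreAugmentedEntry(x, combinationProfile(x, c("g04", "g01")), "c")
  expect_identical(r1, r2)
})

test_that("k = 1 reduces exactly to the plain single-gene ranking", {
  x <- randCqSet(7, 5, seed = 121, groups = c("A", "A", "A", "B", "B"))
  k1 <- enumerateCombinations(x, k = 1)
  fs <- finalScores(x)
  expect_equal(k1$members, fs$entry_id)
  expect_equal(k1$final_score, fs$final_score)
  expect_equal(k1$place, fs$place)
})

test_that("the cached fast path equals naive recomputation", {
  for (seed in 1:5) {
    groups <- if (seed %% 2) rep(c("A", "B"), each = 4) else NULL
    x <- randCqSet(8, 8, seed = 130 + seed, groups = groups)
    fast <- enumerateCombinations(x, k = 3, fastPath = TRUE)
    naive <- enumerateCombinations(x, k = 3, fastPath = FALSE)
    expect_equal(fast, naive, tolerance = 1e-12)
  }
})

test_that("combination sizes beyond 3 are rejected and pools validated", {
  x <- randCqSet(6, 4, seed = 141)
  expect_error(enumerateCombinations(x, k = 4), "1, 2 or 3")
  expect_error(enumerateCombinations(x, k = 3, pool = c("g01", "g02")),
               "smaller than k")
  expect_error(enumerateCombinations(x, k = 2, pool = c("g01", "nope")),
               "not in dataset")
  expect_equal(nrow(enumerateCombinations(x, k = 2,
                                          pool = c("g01", "g02", "g03"))),
               3L)
})

test_that("the global-mean factor behaves as the ALL-gene combination", {
  # identical genes: the global mean ties every gene, sharing place 1
  m <- matrix(rep(c(20, 21, 22, 23), each = 3), 3, 4,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  x <- CqSet(m, curated = TRUE)
  gm <- globalMeanFactor(x)
  expect_equal(gm$members, "ALL")
  expect_equal(gm$place, 1L)

  # on a 2-gene table ALL is exactly the single pair
  x2 <- randCqSet(2, 6, seed = 151)
  gm2 <- globalMeanFactor(x2)
  pair <- enumerateCombinations(x2, k = 2)
  expect_equal(gm2$final_score, pair$final_score)
  expect_equal(gm2$place, pair$place)

  # heterogeneous tables give it no guarantee of first place: under strong
  # group effects the all-gene mean inherits systematic variation that a
  # planted zero-effect reference does not carry
  sim <- simulateCqDataset(nGenes = 10, nSamples = 10, nGroups = 2,
                           nStable = 2, stableSd = 0.05,
                           unstableSdRange = c(0.3, 0.8),
                           groupEffectSd = 3, seed = 13)
  gm3 <- globalMeanFactor(curateCqSet(sim$dataset))
  expect_gt(gm3$place, 1L)
})

test_that("combinations are classified against their component genes", {
  singles <- data.frame(entry_id = c("A", "B", "C"),
                        final_score = c(0.2, 0.3, 0.6))
  recs <- data.frame(
    members = c("A;B", "A;B", "A;C"),
    k = 2L, dataset_id = c("d1", "d2", "d2"),
    final_score = c(0.1, 0.25, 0.7),
    place = c(1L, 2L, 3L), n_entries = 4L)
  cmp <- compareToComponents(recs, singles)
  expect_equal(cmp$per_combination$category,
               c("better_than_all_components", "better_than_some",
                 "worse_than_all_components"))
  expect_equal(cmp$per_combination$n_components_better, c(0L, 1L, 2L))
  s <- cmp$summary
  expect_equal(sum(s$count), 3L)
  expect_equal(s$fraction[s$dataset_id == "d2"], c(0.5, 0.5))
  expect_error(compareToComponents(
    data.frame(members = "A;Z", k = 2L, dataset_id = "d", final_score = 0.1,
               place = 1L, n_entries = 3L), singles), "no single-gene score")
})

test_that("triples carry the four-way component split used for reporting", {
  singles <- data.frame(entry_id = c("A", "B", "C"),
                        final_score = c(0.1, 0.5, 0.9))
  rec <- data.frame(members = "A;B;C", k = 3L, dataset_id = "d1",
                    final_score = 0.3, place = 2L, n_entries = 5L)
  cmp <- compareToComponents(rec, singles)
  # exactly one component (A) is more stable than the triple
  expect_equal(cmp$per_combination$n_components_better, 1L)
  expect_equal(cmp$per_combination$category, "better_than_some")
})
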