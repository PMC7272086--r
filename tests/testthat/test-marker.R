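test_that("per-pathway scores follow the evidence rules", {
  # the query's own evidence pins the score
  expect_equal(pathwayScore("E1", 4, 1, 0), 10)
  expect_equal(pathwayScore("E2", 4, 1, 0), 8)
  # one E1 OGSP among four: 5 * (1/4) + 3
  expect_equal(pathwayScore("NONE", 4, 1, 0), 4.25)
  # all OGSPs E2: the suggestive floor, exactly 3
  expect_equal(pathwayScore("NONE", 10, 0, 10), 3)
  # all OGSPs E1: the unconfirmed maximum, exactly 8
  expect_equal(pathwayScore("NONE", 4, 4, 0), 8)
  # no evidence at all
  expect_equal(pathwayScore("NONE", 5, 0, 0), 0)
  # mixed evidence goes through the E1 branch
  expect_equal(pathwayScore("NONE", 5, 2, 1), 5 * (2 + 0.8) / 5 + 3)
  # degenerate pathway for an unconfirmed query
  expect_error(pathwayScore("NONE", 0, 0, 0), "no other members")
  expect_error(pathwayScore("NONE", 3, 2, 2))
})

test_that("pathway weights are the published step function", {
  expect_equal(pathwayWeight(10), 10)
  expect_equal(pathwayWeight(8), 8)
  expect_equal(pathwayWeight(6.5), 5)
  expect_equal(pathwayWeight(5), 5)
  expect_equal(pathwayWeight(4.25), 3)
  expect_equal(pathwayWeight(0), 3)
  # the unreachable open interval (8, 10) maps to 5
  expect_equal(pathwayWeight(9), 5)
  expect_equal(pathwayWeight(c(10, 8, 7, 2)), c(10, 8, 5, 3))
})

test_that("pathways with E1 evidence always outscore all-E2 pathways", {
  set.seed(21)
  for (i in 1:200) {
    Np <- sample(1:30, 1)
    Ne <- sample(1:Np, 1)
    Nm <- sample(0:(Np - Ne), 1)
    withE1 <- pathwayScore("NONE", Np, Ne, Nm)
    expect_gt(withE1, 3)
    expect_lte(withE1, 8)
    Np2 <- sample(1:30, 1)
    Nm2 <- sample(1:Np2, 1)
    onlyE2 <- pathwayScore("NONE", Np2, 0, Nm2)
    expect_gt(onlyE2, 0)
    expect_lte(onlyE2, 3)
    expect_gt(withE1, onlyE2)
  }
})

test_that("Sc is monotone in Ne and Nm at fixed Np", {
  for (Np in c(4, 10, 25)) {
    for (Ne in 0:(Np - 1)) {
      Nm <- 0
      expect_gte(pathwayScore("NONE", Np, Ne + 1, Nm),
                 pathwayScore("NONE", Np, Ne, Nm))
    }
    for (Nm in 0:(Np - 1))
      expect_gte(pathwayScore("NONE", Np, 0, Nm + 1),
                 pathwayScore("NONE", Np, 0, Nm))
    for (Nm in 0:(Np - 2))
      expect_gte(pathwayScore("NONE", Np, 1, Nm + 1),
                 pathwayScore("NONE", Np, 1, Nm))
  }
})

test_that("marker evaluation aggregates pathways by the step weights", {
  # known E1 marker: Scm pinned at 10 regardless of pathway composition
  corp <- markerCorpus(list(list(Np = 5, Ne = 0, Nm = 0)),
                       queryEvidence = "E1")
  r <- scoreMarker(corp, "Q1")
  expect_equal(r@Scm, 10)
  expect_identical(r@classification, "STRONGLY_SUGGESTIVE")
  expect_true(r@knownMarker)

  # single pathway at the strong threshold
  r <- scoreMarker(markerCorpus(list(list(Np = 4, Ne = 1, Nm = 0))), "Q1")
  expect_equal(r@Scm, 4.25)
  expect_identical(r@classification, "STRONGLY_SUGGESTIVE")
  expect_false(r@knownMarker)

  # two pathways, Sc = 4.25 and 3.0, both weight 3: (4.25*3 + 3*3)/6
  r <- scoreMarker(markerCorpus(list(list(Np = 4, Ne = 1, Nm = 0),
                                     list(Np = 10, Ne = 0, Nm = 10))),
                   "Q1")
  expect_equal(r@Scm, 3.625)
  expect_identical(r@classification, "SUGGESTIVE")
  expect_equal(r@perPathway$Sc, c(4.25, 3))
  expect_equal(r@perPathway$weight, c(3, 3))

  # gene in no pathway
  r <- scoreMarker(markerCorpus(list(list(Np = 3, Ne = 1, Nm = 0))),
                   "ABSENT_GENE")
  expect_identical(r@classification, "NOT_SUPPORTED")
  expect_identical(nrow(r@perPathway), 0L)
})

test_that("Scm lies between the smallest and largest per-pathway Sc", {
  set.seed(31)
  for (i in 1:50) {
    specs <- lapply(seq_len(sample(1:4, 1)), function(.) {
      Np <- sample(2:12, 1)
      Ne <- sample(0:Np, 1)
      list(Np = Np, Ne = Ne, Nm = sample(0:(Np - Ne), 1))
    })
    r <- scoreMarker(markerCorpus(specs), "Q1")
    expect_gte(r@Scm, min(r@perPathway$Sc) - 1e-9)
    expect_lte(r@Scm, max(r@perPathway$Sc) + 1e-9)
    # identity Scm = sum(Sc W) / sum(W)
    expect_equal(r@Scm, sum(r@perPathway$Sc * r@perPathway$weight) /
                          sum(r@perPathway$weight), tolerance = 1e-9)
  }
})

test_that("known markers always classify strongly suggestive", {
  for (ev in c("E1", "E2")) {
    r <- scoreMarker(markerCorpus(list(list(Np = 6, Ne = 0, Nm = 0)),
                                  queryEvidence = ev), "Q1")
    expect_identical(r@classification, "STRONGLY_SUGGESTIVE")
  }
})

test_that("the three marker classes partition the candidate set", {
  fx <- makeCorpus(fixtureConfig(nProteins = 80, nKinases = 8, seed = 17))
  res <- scoreAllMarkers(fx$corpus)
  expect_identical(nrow(res$markers), 80L)
  expect_identical(sum(classCounts(res$markers$classification)), 80L)
  # per-pathway long table is consistent with the per-gene table
  expect_setequal(unique(res$perPathway$accession), res$markers$accession)
})
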