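test_that("tissue pairs score by the weaker evidence level", {
  cases <- list(
    list("T1", "T1", 10), list("T1", "T2", 6), list("T2", "T1", 6),
    list("T2", "T2", 6), list("T1", "T3", 2), list("T3", "T2", 2),
    list("T2", "ABSENT", 0), list("ABSENT", "ABSENT", 0),
    list("T1", "ABSENT", 0))
  for (cs in cases)
    expect_identical(tissueScore(cs[[1]], cs[[2]]), cs[[3]],
                     info = paste(cs[[1]], cs[[2]]))
  # symmetric over the full level set
  for (a in c("T1", "T2", "T3", "ABSENT"))
    for (b in c("T1", "T2", "T3", "ABSENT"))
      expect_identical(tissueScore(a, b), tissueScore(b, a))
})

test_that("localization layer 1 scores shared GO terms by evidence pair", {
  go <- function(acc, term, code)
    data.frame(accession = acc, go_term_id = term, evidence_code = code,
               stringsAsFactors = FALSE)
  # both L1 -> 10
  expect_equal(localizationScore(go("q", "GO:1", "IDA"),
                                 go("k", "GO:1", "IMP")), 10)
  # L1 + L2 -> 8
  expect_equal(localizationScore(go("q", "GO:1", "IDA"),
                                 go("k", "GO:1", "ISS")), 8)
  # L3 + L1 (no shared category) -> 4
  expect_equal(localizationScore(go("q", "GO:1", "TAS"),
                                 go("k", "GO:1", "IDA")), 4)
  # any L4 -> 2
  expect_equal(localizationScore(go("q", "GO:1", "IEA"),
                                 go("k", "GO:1", "IDA")), 2)
  # L1 + L4 but shared category -> layer 2 lifts to 6
  expect_equal(localizationScore(go("q", "GO:1", "IDA"),
                                 go("k", "GO:1", "IEA"),
                                 "Nucleus", "Nucleus"), 6)
  # no shared term, no shared category -> 0
  expect_equal(localizationScore(go("q", "GO:1", "IDA"),
                                 go("k", "GO:2", "IDA")), 0)
  # no shared term but shared category -> 6
  expect_equal(localizationScore(go("q", "GO:1", "IDA"),
                                 go("k", "GO:2", "IDA"),
                                 "Secreted;Nucleus", "Nucleus"), 6)
  # layer 1 >= 8 is final even with shared categories
  expect_equal(localizationScore(go("q", "GO:1", "IDA"),
                                 go("k", "GO:1", "ISS"),
                                 "Nucleus", "Nucleus"), 8)
  # the best shared term wins
  expect_equal(localizationScore(
    rbind(go("q", "GO:1", "IEA"), go("q", "GO:2", "IDA")),
    rbind(go("k", "GO:1", "IDA"), go("k", "GO:2", "IDA"))), 10)
  # empty annotation on either side scores 0 without categories
  expect_equal(localizationScore(go("q", "GO:1", "IDA"), emptyGoTable()), 0)
})

test_that("phase score needs two profiles and overlapping support", {
  early <- normalizeProfile(c(0, 49, 50, 99), c(1, 1, -1, -1))
  late <- normalizeProfile(c(0, 49, 50, 99), c(-1, -1, 1, 1))
  expect_equal(phaseScore(early, early), 10)
  expect_equal(phaseScore(early, late), 0)
  expect_equal(phaseScore(NULL, early), 0)
  expect_equal(phaseScore(early, NULL), 0)
})

test_that("the kinase-correlation score is the stated weighted mean", {
  expect_equal(kinaseCorrelation(6, 6, 10), 6.8)
  expect_equal(kinaseCorrelation(6, 6, 0), 4.8)
  expect_equal(kinaseCorrelation(0, 0, 0), 0)
  expect_equal(kinaseCorrelation(10, 10, 10), 10)
  # custom weights
  expect_equal(kinaseCorrelation(10, 0, 0, phosphoWeights(1, 1, 2)), 2.5)
  expect_error(kinaseCorrelation(5, 5, 5, phosphoWeights(0, 1, 1)),
               "positive")
})

test_that("the component lattice pins the published Sk thresholds", {
  lattice <- expand.grid(St = c(0, 2, 6, 10), Sl = c(0, 2, 4, 6, 8, 10),
                         Sp = c(0, 10))
  lattice$Sk <- kinaseCorrelation(lattice$St, lattice$Sl, lattice$Sp)
  # minimal Sk over the strongly-suggestive component region is exactly 6.8
  strong <- lattice$St >= 6 & lattice$Sl >= 6 & lattice$Sp == 10
  expect_equal(min(lattice$Sk[strong]), 6.8)
  # minimal Sk with the phase criterion dropped is exactly 4.8
  sugg <- lattice$St >= 6 & lattice$Sl >= 6 & lattice$Sp == 0
  expect_equal(min(lattice$Sk[sugg]), 4.8)
  # Sk stays on the 0.1 grid and inside [0, 10]
  expect_true(all(abs(lattice$Sk * 10 - round(lattice$Sk * 10)) < 1e-9))
  expect_true(all(lattice$Sk >= 0 & lattice$Sk <= 10))
})

test_that("Sk is monotone in every component", {
  lattice <- expand.grid(St = c(0, 2, 6, 10), Sl = c(0, 2, 4, 6, 8, 10),
                         Sp = c(0, 10))
  for (comp in c("St", "Sl", "Sp")) {
    for (i in seq_len(nrow(lattice))) {
      bumped <- lattice[i, ]
      bumped[[comp]] <- bumped[[comp]] + 2
      expect_gte(kinaseCorrelation(bumped$St, bumped$Sl, bumped$Sp),
                 kinaseCorrelation(lattice$St[i], lattice$Sl[i],
                                   lattice$Sp[i]))
    }
  }
})

test_that("criteria classification applies the component conditions", {
  expect_identical(classifyPhospho(6, 6, 10), "STRONGLY_SUGGESTIVE")
  expect_identical(classifyPhospho(10, 6, 0), "SUGGESTIVE")
  expect_identical(classifyPhospho(2, 10, 10), "NOT_SUPPORTED")
  # threshold mode applies the Sk cutoffs
  expect_identical(classifyPhospho(6, 6, 10, mode = "threshold"),
                   "STRONGLY_SUGGESTIVE")
  expect_identical(classifyPhospho(6, 6, 0, mode = "threshold"),
                   "SUGGESTIVE")
  expect_identical(classifyPhospho(2, 2, 0, mode = "threshold"),
                   "NOT_SUPPORTED")
})

test_that("criteria and threshold modes diverge at St=Sl=10, Sp=0", {
  # Sk = 8 >= 6.8 yet the phase condition fails: the two published rules
  # are not equivalent, and both readings are preserved
  expect_equal(kinaseCorrelation(10, 10, 0), 8)
  expect_identical(classifyPhospho(10, 10, 0), "SUGGESTIVE")
  expect_identical(classifyPhospho(10, 10, 0, mode = "threshold"),
                   "STRONGLY_SUGGESTIVE")
})

test_that("scorePhospho composes the components for the planted kinase", {
  corp <- cleanCorpus()   # T1/T1, shared L1 GO term, co-expressed
  r <- scorePhospho(corp, "P1")
  expect_identical(r@bestKinase, "K1")
  expect_equal(c(r@St, r@Sl, r@Sp, r@Sk), c(10, 10, 10, 10))
  expect_identical(r@classification, "STRONGLY_SUGGESTIVE")
})

test_that("a query without motif matches is not supported", {
  corp <- cleanCorpus()
  corp@sequences <- Biostrings::AAStringSet(c(P1 = "AAAAAAAA",
                                              K1 = "MKGATLLE"))
  r <- scorePhospho(corp, "P1")
  expect_identical(r@bestKinase, NA_character_)
  expect_equal(r@Sk, 0)
  expect_identical(r@classification, "NOT_SUPPORTED")
  expect_identical(nrow(r@perKinase), 0L)
})

test_that("the best kinase attains the maximal Sk", {
  corp <- twoKinaseCorpus()
  r <- scorePhospho(corp, "P1")
  # KA: T1/T2 -> 6, shared L1 term -> 10, co-expressed -> 10 => Sk = 8
  # KB: T2/T2 -> 6, shared L1 term -> 10, disjoint phase -> 0 => Sk = 6
  expect_identical(r@bestKinase, "KA")
  expect_equal(r@Sk, 8)
  expect_equal(r@perKinase$Sk, c(8, 6))
  expect_identical(r@perKinase$kinase, c("KA", "KB"))
})

test_that("equal-Sk kinases break ties lexicographically", {
  corp <- twoKinaseCorpus()
  # make KB identical in evidence to KA
  corp@proteins$tissue_evidence[corp@proteins$accession == "KB"] <- "T1"
  corp@profiles$log2_ratio[corp@profiles$accession == "KB"] <-
    c(1, 1, -1, -1)
  corp <- HCCCorpus(proteins = corp@proteins, sequences = corp@sequences,
                    goAnnotations = corp@goAnnotations,
                    motifs = corp@motifs, profiles = corp@profiles)
  r <- scorePhospho(corp, "P1")
  expect_equal(r@perKinase$Sk[1], r@perKinase$Sk[2])
  expect_identical(r@bestKinase, "KA")
})

test_that("unresolvable candidate kinases are skipped with a warning", {
  corp <- cleanCorpus()
  corp@motifs$kinase_accessions <- "K1;KGHOST"
  expect_warning(r <- scorePhospho(corp, "P1"), "KGHOST")
  expect_identical(r@bestKinase, "K1")
})

test_that("classification partitions any scored corpus", {
  fx <- makeCorpus(fixtureConfig(nProteins = 60, nKinases = 6, seed = 3))
  tab <- scoreAllPhospho(fx$corpus)
  expect_identical(nrow(tab), 60L)
  expect_identical(sum(classCounts(tab$classification)), 60L)
})
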