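test_that("patterns parse into the expected element lists", {
  ast <- parsePrositePattern("[RK](2)-x-[ST].")
  expect_length(ast$elements, 3L)
  expect_identical(ast$elements[[1]]$type, "class")
  expect_setequal(ast$elements[[1]]$residues, c("R", "K"))
  expect_identical(ast$elements[[1]]$min, 2L)
  expect_identical(ast$elements[[1]]$max, 2L)
  expect_identical(ast$elements[[2]]$type, "wildcard")
  expect_setequal(ast$elements[[3]]$residues, c("S", "T"))

  ast <- parsePrositePattern("x.")
  expect_length(ast$elements, 1L)
  expect_identical(ast$elements[[1]]$type, "wildcard")

  ast <- parsePrositePattern("[ST]-x(2,3)-{P}")
  expect_identical(ast$elements[[2]]$min, 2L)
  expect_identical(ast$elements[[2]]$max, 3L)
  expect_identical(ast$elements[[3]]$type, "negclass")
  expect_identical(ast$elements[[3]]$residues, "P")

  anchored <- parsePrositePattern("<A-x-T>")
  expect_true(anchored$nterm)
  expect_true(anchored$cterm)
})

test_that("malformed patterns raise errors naming the element", {
  expect_error(parsePrositePattern("[ST"), "element 1")
  expect_error(parsePrositePattern("x-[]"), "element 2")
  expect_error(parsePrositePattern("x(3,2)"), "m < n")
  expect_error(parsePrositePattern("x(0)"), ">= 1")
  expect_error(parsePrositePattern("st"), "malformed")
  expect_error(parsePrositePattern(""))
})

test_that("scanning reports matches with 1-based inclusive coordinates", {
  m <- scanSequence("[ST]-x(2)-[DE]", "AASGGDAA", siteOffset = 0)
  expect_identical(nrow(m), 1L)
  expect_identical(m$start, 3L)
  expect_identical(m$end, 6L)
  expect_identical(m$matched_span, "SGGD")
  expect_identical(m$site_position, 3L)
  expect_identical(m$site_residue, "S")

  # N-terminal anchor tests only position 1
  m <- scanSequence("<A-x", "AGA", siteOffset = 0)
  expect_identical(m$start, 1L)
  expect_identical(nrow(m), 1L)

  # C-terminal anchor: only windows ending at the last residue
  m <- scanSequence("A-x>", "AGAG", siteOffset = 0)
  expect_identical(m$start, 3L)

  # sequence shorter than the minimal window
  expect_identical(nrow(scanSequence("[ST]-x(2)-[DE]", "AS", 0)), 0L)

  # variable-length elements enumerate all window lengths
  m <- scanSequence("S-x(1,2)-D", "SADDD", siteOffset = 0)
  expect_identical(m$end, c(3L, 4L))

  # site position within a repeated element is its first residue
  m <- scanSequence("[RK](2)-x-[ST]", "ARKAS", siteOffset = 0)
  expect_identical(m$site_position, 2L)
})

test_that("siteOffset is validated against the element count", {
  expect_error(scanSequence("x-x", "AAAA", siteOffset = 2), "out of range")
  expect_error(scanSequence("x-x", "AAAA", siteOffset = -1), "out of range")
})

test_that("candidate kinases come from motifs with surviving matches", {
  corp <- cleanCorpus()
  got <- findCandidateKinases(corp, "P1")
  expect_identical(got$kinases, "K1")
  expect_identical(got$matches$motif_id, "M1")
  expect_identical(got$matches$site_residue, "S")

  # skip-flagged motifs are excluded by default, included on request
  corp@motifs$skip_flag <- TRUE
  expect_identical(findCandidateKinases(corp, "P1")$kinases, character(0))
  expect_identical(findCandidateKinases(corp, "P1",
                                        includeSkipped = TRUE)$kinases,
                   "K1")

  # matches whose acceptor is not S/T/Y/H contribute nothing
  corp2 <- cleanCorpus()
  corp2@motifs$pattern <- "[RK](2)-x-[AG]"
  expect_identical(findCandidateKinases(corp2, "P1")$kinases, character(0))

  # proteins without a sequence cannot be scanned
  expect_error(findCandidateKinases(cleanCorpus(), "NOSUCH"),
               "no sequence")
})

test_that("max_repeat caps per-protein matches only when enforced", {
  corp <- cleanCorpus()
  corp@sequences <- Biostrings::AAStringSet(c(P1 = "RRASRRASRRAS"))
  corp@motifs$max_repeat <- 2L
  expect_identical(nrow(findCandidateKinases(corp, "P1")$matches), 3L)
  expect_identical(
    nrow(findCandidateKinases(corp, "P1",
                              enforceMaxRepeat = TRUE)$matches), 2L)
})

test_that("scanner agrees with the regex oracle on random patterns", {
  set.seed(42)
  nAgree <- 0L
  for (i in 1:1000) {
    pat <- randomPattern()
    seq <- randomSequence()
    mine <- unique(scanSequence(pat, seq, siteOffset = 0)$start)
    oracle <- oracleStarts(pat, seq)
    expect_identical(sort(mine), sort(oracle),
                     info = sprintf("pattern %s on %s", pat, seq))
    nAgree <- nAgree + 1L
  }
  expect_identical(nAgree, 1000L)
})

test_that("anchored patterns report at most one start per anchor side", {
  set.seed(7)
  for (i in 1:100) {
    pat <- paste0("<", randomPattern())
    starts <- unique(scanSequence(sub("^<+", "<", pat),
                                  randomSequence(), 0)$start)
    expect_lte(length(starts), 1L)
  }
})

test_that("specializing a wildcard never adds matches", {
  set.seed(11)
  for (i in 1:200) {
    seq <- randomSequence()
    general <- "[ST]-x-x-[AD]"
    special <- "[ST]-A-x-[AD]"
    nG <- length(unique(scanSequence(general, seq, 0)$start))
    nS <- length(unique(scanSequence(special, seq, 0)$start))
    expect_lte(nS, nG)
  }
})

test_that("reported spans re-validate against the pattern in isolation", {
  set.seed(13)
  for (i in 1:200) {
    pat <- randomPattern()
    # strip anchors: a span re-test has its own termini
    bare <- sub("^<", "", sub(">$", "", pat))
    m <- scanSequence(bare, randomSequence(), 0)
    for (j in seq_len(nrow(m))) {
      re <- scanSequence(bare, m$matched_span[j], 0)
      expect_true(any(re$start == 1L & re$end == nchar(m$matched_span[j])))
    }
  }
})

test_that("the regex translation utility round-trips simple patterns", {
  expect_identical(prositeToRegex("[RK](2)-x-[ST]."), "[RK]{2}.[ST]")
  expect_identical(prositeToRegex("<A-x(2,3)-{P}>"), "^A.{2,3}[^P]$")
})
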