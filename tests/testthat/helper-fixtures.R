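# Small hand-built corpora used by several test files.

# a minimal fully consistent corpus: one query with a motif hit on one kinase
cleanCorpus <- function() {
  HCCCorpus(
    proteins = data.frame(
      accession = c("P1", "K1"),
      gene_id = c("1", "2"), gene_symbol = c("G1", "KIN1"),
      tissue_evidence = c("T1", "T1"),
      hcc_evidence = c("NONE", "NONE"),
      localization_categories = c("Nucleus", "Nucleus"),
      is_kinase = c(FALSE, TRUE), stringsAsFactors = FALSE),
    sequences = c(P1 = "AARRASAA", K1 = "MKGATLLE"),
    goAnnotations = data.frame(
      accession = c("P1", "K1"),
      go_term_id = c("GO:0005634", "GO:0005634"),
      evidence_code = c("IDA", "IDA"), stringsAsFactors = FALSE),
    motifs = data.frame(
      motif_id = "M1", pattern = "[RK](2)-x-[ST]", site_offset = 2L,
      max_repeat = 0L, skip_flag = FALSE, kinase_accessions = "K1",
      description = "fixture", stringsAsFactors = FALSE),
    pathways = list(PWA = c("P1", "K1")),
    drugs = data.frame(
      drug_id = "D1", drug_name = "drug one", category = "CANCER",
      target_accession = "P1", stringsAsFactors = FALSE),
    profiles = data.frame(
      accession = rep(c("P1", "K1"), each = 4),
      time_percent = rep(c(0, 49, 50, 99), 2),
      log2_ratio = c(1, 1, -1, -1, 1, 1, -1, -1),
      stringsAsFactors = FALSE))
}

# corpus with two candidate kinases whose planted evidence yields the given
# tissue/GO-class/phase combinations for the query
twoKinaseCorpus <- function() {
  prof <- function(acc, kind) {
    pts <- switch(kind,
      early = data.frame(time_percent = c(0, 49, 50, 99),
                         log2_ratio = c(1, 1, -1, -1)),
      late = data.frame(time_percent = c(0, 49, 50, 99),
                        log2_ratio = c(-1, -1, 1, 1)))
    cbind(accession = acc, pts, stringsAsFactors = FALSE)
  }
  HCCCorpus(
    proteins = data.frame(
      accession = c("P1", "KA", "KB"),
      tissue_evidence = c("T2", "T1", "T2"),
      hcc_evidence = "NONE",
      localization_categories = c("Nucleus", "Cytoplasm", "Nucleus"),
      is_kinase = c(FALSE, TRUE, TRUE), stringsAsFactors = FALSE),
    sequences = c(P1 = "AARRASAA"),
    goAnnotations = data.frame(
      accession = c("P1", "KA", "KB"),
      go_term_id = "GO:0005634",
      evidence_code = c("IDA", "IDA", "IDA"), stringsAsFactors = FALSE),
    motifs = data.frame(
      motif_id = "M1", pattern = "[RK](2)-x-[ST]", site_offset = 2L,
      max_repeat = 0L, skip_flag = FALSE, kinase_accessions = "KA;KB",
      description = "fixture", stringsAsFactors = FALSE),
    profiles = rbind(prof("P1", "early"), prof("KA", "early"),
                     prof("KB", "late")))
}

# build a corpus where `query` sits in the given pathways; each pathway is
# a list(Np=, Ne=, Nm=) of OGSP evidence counts
markerCorpus <- function(pathwaySpecs, queryEvidence = "NONE",
                         query = "Q1") {
  rows <- list(data.frame(accession = query, tissue_evidence = "T1",
                          hcc_evidence = queryEvidence, is_kinase = FALSE,
                          stringsAsFactors = FALSE))
  pws <- list()
  for (i in seq_along(pathwaySpecs)) {
    sp <- pathwaySpecs[[i]]
    id <- sprintf("PW%02d", i)
    pw <- makePathway(sp$Np, sp$Ne, sp$Nm, queryAccession = query,
                      pathwayId = id)
    rows[[length(rows) + 1L]] <-
      pw$proteins[pw$proteins$accession != query, , drop = FALSE]
    pws[[id]] <- pw$members
  }
  HCCCorpus(proteins = do.call(rbind, rows), pathways = pws)
}

classLevels <- c("STRONGLY_SUGGESTIVE", "SUGGESTIVE", "NOT_SUPPORTED")
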