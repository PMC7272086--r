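# Synthetic corpus generation. Ground truth is computed constructively from
# the planted evidence (literal rule tables below), never by calling the
# scoring engine, so pipeline tests are genuine oracle comparisons.

.withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic corpus generator
#'
#' Defaults emulate the composition of a genome-scale candidate set: about
#' 7% of candidates carry small-scale wet-lab HCC evidence (E1) and 3%
#' large-scale evidence (E2); pathways hold 25 genes; most proteins have
#' liver/blood/lymph expression evidence at the protein or mRNA level; half
#' of the (query, kinase) pairs share a GO cellular-component term.
#'
#' @param nProteins number of candidate (non-kinase) genes.
#' @param nKinases number of kinases; each carries its own fixture motif.
#' @param tissueMix named proportions over `T1`/`T2`/`T3`/`ABSENT`.
#' @param e1Fraction,e2Fraction proportions of candidates with E1 / E2
#'   HCC evidence.
#' @param goSharing probability a query shares a GO CC term with its
#'   planted kinase.
#' @param goClassMix named proportions over evidence classes `L1`..`L4`
#'   for each side of a shared term.
#' @param categorySharing probability a query shares a localization
#'   category with its kinase.
#' @param pathwaySize genes per generated pathway.
#' @param profileProb probability a query gene has a cycle profile (all
#'   kinases are profiled).
#' @param coexpressProb probability a profiled query overlaps its kinase's
#'   expressed phase.
#' @param noKinaseFraction proportion of queries generated without any
#'   motif match (no candidate kinases).
#' @param drugProb probability a gene has drug-target rows.
#' @param sequenceLength length of generated protein sequences.
#' @param seed mandatory integer seed.
#' @return named list of class `FixtureConfig`.
#' @export
fixtureConfig <- function(nProteins = 1000, nKinases = 50,
                          tissueMix = c(T1 = 0.35, T2 = 0.30, T3 = 0.20,
                                        ABSENT = 0.15),
                          e1Fraction = 0.07, e2Fraction = 0.03,
                          goSharing = 0.5,
                          goClassMix = c(L1 = 0.4, L2 = 0.3, L3 = 0.2,
                                         L4 = 0.1),
                          categorySharing = 0.5,
                          pathwaySize = 25,
                          profileProb = 0.7, coexpressProb = 0.5,
                          noKinaseFraction = 0.1,
                          drugProb = 0.1,
                          sequenceLength = 60,
                          seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  stopifnot(nProteins >= 1, nKinases >= 1,
            abs(sum(tissueMix) - 1) < 1e-8,
            abs(sum(goClassMix) - 1) < 1e-8,
            e1Fraction >= 0, e2Fraction >= 0,
            e1Fraction + e2Fraction <= 1,
            goSharing >= 0, goSharing <= 1,
            categorySharing >= 0, categorySharing <= 1,
            profileProb >= 0, profileProb <= 1,
            coexpressProb >= 0, coexpressProb <= 1,
            noKinaseFraction >= 0, noKinaseFraction <= 1,
            pathwaySize >= 2, sequenceLength >= 10)
  structure(as.list(environment()), class = "FixtureConfig")
}

#' Build a pathway with controlled evidence counts
#'
#' Returns one unconfirmed query gene plus exactly `NpOthers` other genes
#' in the same pathway (OGSPs), of which `Ne` carry E1 and `Nm` carry E2
#' evidence. Useful for exercising the per-pathway marker score.
#'
#' @param NpOthers number of OGSPs.
#' @param Ne,Nm numbers of E1 / E2 OGSPs; `Ne + Nm <= NpOthers`.
#' @param queryAccession accession of the unconfirmed query gene.
#' @param pathwayId pathway identifier.
#' @return list with `pathwayId`, `query`, `members` (accession vector
#'   including the query) and `proteins` (annotation data.frame for all
#'   members).
#' @examples
#' pw <- makePathway(4, Ne = 1, Nm = 0)
#' @export
makePathway <- function(NpOthers, Ne, Nm, queryAccession = "QUERY",
                        pathwayId = "PW_FIX") {
  stopifnot(NpOthers >= 0, Ne >= 0, Nm >= 0)
  if (Ne + Nm > NpOthers)
    stop("infeasible counts: Ne + Nm exceeds NpOthers")
  others <- if (NpOthers > 0)
    sprintf("%s_OG%03d", pathwayId, seq_len(NpOthers)) else character(0)
  evid <- rep("NONE", NpOthers)
  if (Ne > 0) evid[seq_len(Ne)] <- "E1"
  if (Nm > 0) evid[Ne + seq_len(Nm)] <- "E2"
  proteins <- data.frame(
    accession = c(queryAccession, others),
    tissue_evidence = "T1",
    hcc_evidence = c("NONE", evid),
    is_kinase = FALSE, stringsAsFactors = FALSE)
  list(pathwayId = pathwayId, query = queryAccession,
       members = c(queryAccession, others), proteins = proteins)
}

# One concrete realization of a pattern whose site element carries a valid
# phosphoacceptor; elements realized at their minimum repeat count.
.realizePattern <- function(ast, siteOffset, alphabet = .AA_ALPHABET) {
  pick <- function(el, wantAcceptor) {
    pool <- switch(el$type,
      wildcard = alphabet,
      literal = el$residues,
      class = el$residues,
      negclass = setdiff(alphabet, el$residues))
    if (wantAcceptor) pool <- intersect(pool, .ACCEPTORS)
    if (!length(pool))
      stop("pattern cannot realize a valid phosphoacceptor at the site")
    pool[sample.int(length(pool), 1L)]
  }
  parts <- character(0)
  for (i in seq_along(ast$elements)) {
    el <- ast$elements[[i]]
    first <- pick(el, wantAcceptor = i == siteOffset + 1L)
    rest <- if (el$min > 1L)
      vapply(seq_len(el$min - 1L), function(.) pick(el, FALSE),
             character(1)) else character(0)
    parts <- c(parts, first, rest)
  }
  paste(parts, collapse = "")
}

#' Plant a motif occurrence in a random sequence
#'
#' Generates a random amino-acid sequence of the requested length and
#' overwrites the window starting at `position` with a concrete
#' realization of the pattern whose phosphoacceptor site is a valid
#' S/T/Y/H. Background residues are drawn from `background` (restricting
#' it, e.g. excluding a residue the pattern starts with, makes accidental
#' extra matches impossible rather than merely improbable).
#'
#' @param sequenceLength total sequence length.
#' @param pattern Prosite-syntax pattern (or parsed `PrositePattern`).
#' @param position 1-based start of the planted match.
#' @param siteOffset 0-based element index of the phosphoacceptor.
#' @param background alphabet for non-planted residues.
#' @return single sequence string; [scanSequence()] finds a match at
#'   `position`.
#' @examples
#' set.seed(1)
#' s <- plantMotif(8, "[ST]-x(2)-[DE]", position = 3)
#' scanSequence("[ST]-x(2)-[DE]", s)$start
#' @export
plantMotif <- function(sequenceLength, pattern, position, siteOffset = 0L,
                       background = .AA_ALPHABET) {
  ast <- if (is.character(pattern)) parsePrositePattern(pattern) else pattern
  core <- .realizePattern(ast, as.integer(siteOffset))
  if (position < 1L || position + nchar(core) - 1L > sequenceLength)
    stop("impossible placement: pattern of length ", nchar(core),
         " at position ", position, " in length ", sequenceLength)
  chars <- sample(background, sequenceLength, replace = TRUE)
  chars[position + seq_len(nchar(core)) - 1L] <- strsplit(core, "")[[1]]
  paste(chars, collapse = "")
}

# literal rule tables used for constructive ground truth ---------------------

.gtTissue <- function(a, b) {
  lv <- c(T1 = 1, T2 = 2, T3 = 3, ABSENT = 4)
  c(10, 6, 2, 0)[max(lv[[a]], lv[[b]])]
}

.gtLocalization <- function(shared, clsQ, clsK, sharedCategory) {
  layer1 <- 0
  if (shared) {
    worst <- max(match(clsQ, .GO_CLASSES), match(clsK, .GO_CLASSES))
    layer1 <- c(10, 8, 4, 2)[worst]
  }
  if (layer1 >= 8) return(layer1)
  if (sharedCategory) return(max(layer1, 6))
  layer1
}

.gtSc <- function(evidence, Np, Ne, Nm, W1 = 5, W2 = 3) {
  if (evidence == "E1") return(10)
  if (evidence == "E2") return(8)
  if (Ne >= 1) return(W1 * (Ne + 0.8 * Nm) / Np + W2)
  if (Nm >= 1) return(W2 * Nm / Np)
  0
}

.gtPhosphoClass <- function(St, Sl, Sp) {
  if (St >= 6 && Sl >= 6 && Sp == 10) "STRONGLY_SUGGESTIVE"
  else if (St >= 6 && Sl >= 6) "SUGGESTIVE"
  else "NOT_SUPPORTED"
}

.gtMarkerClass <- function(Scm) {
  if (Scm >= 4.25) "STRONGLY_SUGGESTIVE"
  else if (Scm >= 3) "SUGGESTIVE"
  else "NOT_SUPPORTED"
}

.gtHccpmClass <- function(p, m) {
  if (p == "STRONGLY_SUGGESTIVE" && m == "STRONGLY_SUGGESTIVE") p
  else if (p == "NOT_SUPPORTED" && m == "NOT_SUPPORTED") p
  else "SUGGESTIVE"
}

# representative GO evidence code per class
.gtCodeFor <- c(L1 = "IDA", L2 = "ISS", L3 = "TAS", L4 = "IEA")

# square-wave cycle profiles: expressed (+1) on one half of the cycle
.profilePoints <- function(kind) {
  switch(kind,
    early = data.frame(time_percent = c(0, 49, 50, 99),
                       log2_ratio = c(1, 1, -1, -1)),
    mid = data.frame(time_percent = c(24, 25, 74, 75),
                     log2_ratio = c(-1, 1, 1, -1)),
    late = data.frame(time_percent = c(0, 49, 50, 99),
                      log2_ratio = c(-1, -1, 1, 1)))
}

#' Generate a synthetic corpus with a constructive ground-truth ledger
#'
#' Builds a fully cross-consistent [HCCCorpus-class]: each kinase carries a
#' unique literal tag motif (`W-<a>-<b>-S`, site at the serine); each
#' candidate gene (unless drawn as a no-candidate control) has its kinase's
#' tag planted in an otherwise tryptophan-free sequence, so the planted
#' kinase is its only candidate and the engine's behaviour is decidable in
#' advance. Tissue levels, HCC evidence, shared GO terms with evidence
#' classes, localization categories, cycle-phase overlap, pathway
#' membership and drug rows are all drawn from the configured mixes, and
#' the expected component scores and classifications are computed
#' constructively from the planted evidence while generating.
#'
#' @param config a [fixtureConfig()].
#' @return list with `corpus` (an `HCCCorpus`) and `ledger` (data.frame
#'   with one row per candidate gene: planted kinase, expected `St`, `Sl`,
#'   `Sp`, `Sk`, `Sc`, `Scm`, expected classifications and drug counts).
#' @examples
#' fx <- makeCorpus(fixtureConfig(nProteins = 20, nKinases = 4, seed = 1))
#' fx$corpus
#' @export
makeCorpus <- function(config) {
  stopifnot(inherits(config, "FixtureConfig"))
  .withSeed(config$seed, .makeCorpusImpl(config))
}

.makeCorpusImpl <- function(cfg) {
  nP <- cfg$nProteins
  nK <- cfg$nKinases
  tagAlphabet <- setdiff(.AA_ALPHABET, "W")
  tagPairs <- expand.grid(a = tagAlphabet, b = tagAlphabet,
                          stringsAsFactors = FALSE)
  if (nK > nrow(tagPairs)) stop("too many kinases for distinct tag motifs")

  kinAcc <- sprintf("KIN%03d", seq_len(nK))
  qAcc <- sprintf("GENE%04d", seq_len(nP))

  # motifs: one unique literal tag per kinase
  motifTab <- data.frame(
    motif_id = sprintf("MOT%03d", seq_len(nK)),
    pattern = sprintf("W-%s-%s-S", tagPairs$a[seq_len(nK)],
                      tagPairs$b[seq_len(nK)]),
    site_offset = 3L, max_repeat = 0L, skip_flag = FALSE,
    kinase_accessions = kinAcc,
    description = "synthetic tag motif", stringsAsFactors = FALSE)

  kinTissue <- sample(names(cfg$tissueMix), nK, replace = TRUE,
                      prob = cfg$tissueMix)
  kinCategory <- sample(.LOCALIZATION_CATEGORIES, nK, replace = TRUE)

  qTissue <- sample(names(cfg$tissueMix), nP, replace = TRUE,
                    prob = cfg$tissueMix)
  ev <- runif(nP)
  qEvidence <- ifelse(ev < cfg$e1Fraction, "E1",
                      ifelse(ev < cfg$e1Fraction + cfg$e2Fraction,
                             "E2", "NONE"))
  qKinaseIdx <- rep_len(seq_len(nK), nP)
  noCand <- runif(nP) < cfg$noKinaseFraction
  goShared <- runif(nP) < cfg$goSharing
  clsQ <- sample(names(cfg$goClassMix), nP, replace = TRUE,
                 prob = cfg$goClassMix)
  clsK <- sample(names(cfg$goClassMix), nP, replace = TRUE,
                 prob = cfg$goClassMix)
  catShared <- runif(nP) < cfg$categorySharing
  profiled <- runif(nP) < cfg$profileProb
  overlap <- runif(nP) < cfg$coexpressProb

  seqs <- character(nP)
  goRows <- list()
  profRows <- list()
  qCategory <- character(nP)

  # kinases: all profiled as expressed early in the cycle
  for (j in seq_len(nK)) {
    pts <- .profilePoints("early")
    profRows[[length(profRows) + 1L]] <-
      cbind(accession = kinAcc[j], pts, stringsAsFactors = FALSE)
    goRows[[length(goRows) + 1L]] <- data.frame(
      accession = kinAcc[j], go_term_id = sprintf("GO:K%03d", j),
      evidence_code = "IDA", stringsAsFactors = FALSE)
  }

  for (i in seq_len(nP)) {
    j <- qKinaseIdx[i]
    if (noCand[i]) {
      seqs[i] <- paste(sample(tagAlphabet, cfg$sequenceLength,
                              replace = TRUE), collapse = "")
    } else {
      pos <- sample.int(cfg$sequenceLength - 4L, 1L)
      seqs[i] <- plantMotif(cfg$sequenceLength, motifTab$pattern[j], pos,
                            siteOffset = 3L, background = tagAlphabet)
    }
    if (goShared[i]) {
      term <- sprintf("GO:P%04d", i)
      goRows[[length(goRows) + 1L]] <- data.frame(
        accession = c(qAcc[i], kinAcc[j]), go_term_id = term,
        evidence_code = unname(.gtCodeFor[c(clsQ[i], clsK[i])]),
        stringsAsFactors = FALSE)
    }
    # a private, automatically assigned term for realism
    goRows[[length(goRows) + 1L]] <- data.frame(
      accession = qAcc[i], go_term_id = sprintf("GO:V%04d", i),
      evidence_code = "IEA", stringsAsFactors = FALSE)
    qCategory[i] <- if (catShared[i]) kinCategory[j]
      else sample(setdiff(.LOCALIZATION_CATEGORIES, kinCategory[j]), 1L)
    if (profiled[i]) {
      pts <- .profilePoints(if (overlap[i]) "mid" else "late")
      profRows[[length(profRows) + 1L]] <-
        cbind(accession = qAcc[i], pts, stringsAsFactors = FALSE)
    }
  }

  # pathways: contiguous chunks of candidate genes
  pwIdx <- ceiling(seq_len(nP) / cfg$pathwaySize)
  pwIds <- sprintf("PW%03d", unique(pwIdx))
  pathwayList <- split(qAcc, pwIdx)
  names(pathwayList) <- pwIds

  # drugs
  drugRows <- list()
  withDrugs <- runif(nP) < cfg$drugProb
  drugNo <- 0L
  drugCounts <- matrix(0L, nrow = nP, ncol = 3,
                       dimnames = list(NULL, .DRUG_CATEGORIES))
  for (i in which(withDrugs)) {
    nDrugs <- sample.int(3L, 1L)
    cats <- sample(.DRUG_CATEGORIES, nDrugs, replace = TRUE)
    for (cat in cats) {
      drugNo <- drugNo + 1L
      drugRows[[length(drugRows) + 1L]] <- data.frame(
        drug_id = sprintf("DRG%04d", drugNo),
        drug_name = sprintf("compound-%04d", drugNo),
        category = cat, target_accession = qAcc[i],
        stringsAsFactors = FALSE)
      drugCounts[i, cat] <- drugCounts[i, cat] + 1L
    }
  }

  proteinsTab <- data.frame(
    accession = c(qAcc, kinAcc),
    gene_id = as.character(seq_len(nP + nK)),
    gene_symbol = c(sprintf("G%04d", seq_len(nP)),
                    sprintf("K%03d", seq_len(nK))),
    tissue_evidence = c(qTissue, kinTissue),
    hcc_evidence = c(qEvidence, rep("NONE", nK)),
    localization_categories = c(qCategory, kinCategory),
    is_kinase = c(rep(FALSE, nP), rep(TRUE, nK)),
    stringsAsFactors = FALSE)

  corpus <- HCCCorpus(
    proteins = proteinsTab,
    sequences = Biostrings::AAStringSet(setNames(seqs, qAcc)),
    goAnnotations = do.call(rbind, goRows),
    motifs = motifTab,
    pathways = pathwayList,
    drugs = if (length(drugRows)) do.call(rbind, drugRows)
            else emptyDrugTable(),
    profiles = do.call(rbind, profRows))

  # ---- constructive ledger -------------------------------------------------
  ledger <- data.frame(accession = qAcc, kinase = NA_character_,
                       St = 0, Sl = 0, Sp = 0, Sk = 0,
                       phospho_class = "NOT_SUPPORTED",
                       pathway_id = pwIds[pwIdx],
                       Np = 0L, Ne = 0L, Nm = 0L, Sc = 0, Scm = 0,
                       marker_class = "NOT_SUPPORTED",
                       hccpm_class = "NOT_SUPPORTED",
                       stringsAsFactors = FALSE)
  for (i in seq_len(nP)) {
    j <- qKinaseIdx[i]
    if (!noCand[i]) {
      St <- .gtTissue(qTissue[i], kinTissue[j])
      Sl <- .gtLocalization(goShared[i], clsQ[i], clsK[i], catShared[i])
      Sp <- if (profiled[i] && overlap[i]) 10 else 0
      ledger$kinase[i] <- kinAcc[j]
      ledger$St[i] <- St; ledger$Sl[i] <- Sl; ledger$Sp[i] <- Sp
      ledger$Sk[i] <- (5 * St + 3 * Sl + 2 * Sp) / 10
      ledger$phospho_class[i] <- .gtPhosphoClass(St, Sl, Sp)
    }
    members <- which(pwIdx == pwIdx[i])
    ogsp <- setdiff(members, i)
    Np <- length(ogsp)
    Ne <- sum(qEvidence[ogsp] == "E1")
    Nm <- sum(qEvidence[ogsp] == "E2")
    Sc <- .gtSc(qEvidence[i], Np, Ne, Nm)
    ledger$Np[i] <- Np; ledger$Ne[i] <- Ne; ledger$Nm[i] <- Nm
    ledger$Sc[i] <- Sc
    ledger$Scm[i] <- Sc  # one pathway per gene
    ledger$marker_class[i] <- .gtMarkerClass(Sc)
    ledger$hccpm_class[i] <- .gtHccpmClass(ledger$phospho_class[i],
                                           ledger$marker_class[i])
  }
  ledger$n_liver_cancer_drugs <- drugCounts[, "LIVER_CANCER"]
  ledger$n_cancer_drugs <- drugCounts[, "CANCER"]
  ledger$n_non_cancer_drugs <- drugCounts[, "NON_CANCER"]

  list(corpus = corpus, ledger = ledger)
}
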