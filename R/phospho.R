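#' Scoring weights for the kinase-correlation score
#'
#' Tissue compatibility carries half of the total weight (tissue-restricted
#' expression is the defining property of a liver-cancer biomarker); the
#' remaining half is split between subcellular localization and cell-cycle
#' phase, with phase down-weighted because profile coverage is sparser.
#'
#' @param Wt,Wl,Wp positive weights for tissue, localization and phase.
#' @return named list of the three weights.
#' @export
phosphoWeights <- function(Wt = 5, Wl = 3, Wp = 2) {
  if (any(c(Wt, Wl, Wp) <= 0)) stop("weights must be positive")
  list(Wt = Wt, Wl = Wl, Wp = Wp)
}

#' Tissue-evidence component score St
#'
#' Scores a (query, kinase) pair by the credibility of their
#' tissue-restricted expression evidence, using the weaker of the two
#' levels: both protein-level (`T1`) scores 10; if the weaker is mRNA-level
#' (`T2`) the score drops to 6; if the weaker is sequence-origin only
#' (`T3`) only 2 is left; and a partner not expressed in liver, blood or
#' the lymphatic system (`ABSENT`) has no chance to meet its partner, so
#' the pair scores 0.
#'
#' @param query,kinase tissue-evidence levels (`"T1"`, `"T2"`, `"T3"`,
#'   `"ABSENT"`); vectors recycle.
#' @return numeric vector of St values in \{0, 2, 6, 10\}.
#' @examples
#' tissueScore("T1", "T2")  # 6
#' @export
tissueScore <- function(query, kinase) {
  stopifnot(all(query %in% .TISSUE_LEVELS), all(kinase %in% .TISSUE_LEVELS))
  rankOf <- function(x) match(x, .TISSUE_LEVELS)  # 1 best .. 4 absent
  weaker <- pmax(rankOf(query), rankOf(kinase))
  c(10, 6, 2, 0)[weaker]
}

# pair score for one shared GO term given the two evidence classes
.goPairScore <- function(clsA, clsB) {
  worst <- pmax(match(clsA, .GO_CLASSES), match(clsB, .GO_CLASSES))
  c(10, 8, 4, 2)[worst]
}

#' Subcellular-localization component score Sl
#'
#' Two-layer scoring. Layer 1 compares GO cellular-component annotations:
#' for every term shared by query and kinase, the pair of evidence classes
#' is scored (both experimental `L1` -> 10; weaker `L2` -> 8; weaker `L3`
#' -> 4; any `L4` -> 2) and the best shared term wins; with no shared term
#' the layer scores 0. A layer-1 score of at least 8 is final. Otherwise
#' layer 2 falls back on the curated localization categories: sharing at
#' least one category lifts the score to 6 (never below the layer-1
#' result).
#'
#' @param queryGo,kinaseGo data.frames with columns `go_term_id` and
#'   `evidence_code` (zero rows allowed).
#' @param queryCategories,kinaseCategories character vectors of
#'   localization categories (or a single semicolon-separated string).
#' @param map evidence-code map, see [mapEvidenceCode()].
#' @return single numeric Sl in \{0, 2, 4, 6, 8, 10\}.
#' @export
localizationScore <- function(queryGo, kinaseGo,
                              queryCategories = character(0),
                              kinaseCategories = character(0),
                              map = defaultEvidenceClassMap()) {
  queryCategories <- .asCategories(queryCategories)
  kinaseCategories <- .asCategories(kinaseCategories)
  layer1 <- 0
  if (NROW(queryGo) && NROW(kinaseGo)) {
    shared <- intersect(queryGo$go_term_id, kinaseGo$go_term_id)
    for (term in shared) {
      clsA <- mapEvidenceCode(
        queryGo$evidence_code[queryGo$go_term_id == term], map)
      clsB <- mapEvidenceCode(
        kinaseGo$evidence_code[kinaseGo$go_term_id == term], map)
      # best evidence on each side of the shared term
      best <- .goPairScore(clsA[which.min(match(clsA, .GO_CLASSES))],
                           clsB[which.min(match(clsB, .GO_CLASSES))])
      layer1 <- max(layer1, best)
    }
  }
  if (layer1 >= 8) return(layer1)
  if (length(intersect(queryCategories, kinaseCategories)))
    return(max(layer1, 6))
  layer1
}

.asCategories <- function(x) {
  if (length(x) == 1L && grepl(";", x)) x <- .splitSemicolon(x)
  x <- x[!is.na(x) & nzchar(x)]
  unique(x)
}

#' Cell-cycle phase component score Sp
#'
#' 10 when both partners have a cycle profile and are co-expressed (see
#' [coexpressed()]); 0 otherwise. A missing profile on either side
#' contributes nothing.
#'
#' @param queryGrid,kinaseGrid numeric grids of length 100, or `NULL`.
#' @param threshold co-expression threshold passed to [coexpressed()].
#' @return 0 or 10.
#' @export
phaseScore <- function(queryGrid, kinaseGrid, threshold = 0) {
  if (is.null(queryGrid) || is.null(kinaseGrid)) return(0)
  if (coexpressed(queryGrid, kinaseGrid, threshold)) 10 else 0
}

#' Kinase-correlation score Sk
#'
#' Weighted mean of the three component scores:
#' `Sk = (Wt*St + Wl*Sl + Wp*Sp) / (Wt + Wl + Wp)`.
#'
#' @param St,Sl,Sp component scores (vectors recycle).
#' @param weights list from [phosphoWeights()].
#' @return numeric Sk in \[0, 10\].
#' @examples
#' kinaseCorrelation(6, 6, 10)  # 6.8
#' @export
kinaseCorrelation <- function(St, Sl, Sp, weights = phosphoWeights()) {
  w <- weights
  if (any(c(w$Wt, w$Wl, w$Wp) <= 0)) stop("weights must be positive")
  (w$Wt * St + w$Wl * Sl + w$Wp * Sp) / (w$Wt + w$Wl + w$Wp)
}

#' Classify phosphorylation support
#'
#' Two classification readings are provided. `"criteria"` (the default)
#' applies the component conditions: strongly suggestive requires St >= 6,
#' Sl >= 6 and Sp = 10; suggestive relaxes only the phase condition
#' (St >= 6 and Sl >= 6, any Sp); everything else is not supported.
#' `"threshold"` applies the published Sk cutoffs instead: Sk >= 6.8 /
#' 6.8 > Sk >= 4.8 / Sk < 4.8. The two rules are not logically equivalent
#' (e.g. St = Sl = 10, Sp = 0 gives Sk = 8): see the methods vignette.
#'
#' @param St,Sl,Sp,Sk score vectors (recycled to common length).
#' @param mode `"criteria"` or `"threshold"`.
#' @param skStrong,skSuggestive Sk cutoffs for threshold mode.
#' @return character vector of class labels.
#' @export
classifyPhospho <- function(St, Sl, Sp, Sk = kinaseCorrelation(St, Sl, Sp),
                            mode = c("criteria", "threshold"),
                            skStrong = 6.8, skSuggestive = 4.8) {
  mode <- match.arg(mode)
  n <- max(length(St), length(Sl), length(Sp), length(Sk))
  St <- rep_len(St, n); Sl <- rep_len(Sl, n)
  Sp <- rep_len(Sp, n); Sk <- rep_len(Sk, n)
  if (mode == "criteria") {
    ifelse(St >= 6 & Sl >= 6 & Sp == 10, "STRONGLY_SUGGESTIVE",
           ifelse(St >= 6 & Sl >= 6, "SUGGESTIVE", "NOT_SUPPORTED"))
  } else {
    ifelse(Sk >= skStrong, "STRONGLY_SUGGESTIVE",
           ifelse(Sk >= skSuggestive, "SUGGESTIVE", "NOT_SUPPORTED"))
  }
}

#' Score the phosphorylation correlation of one query protein
#'
#' Finds candidate kinases by motif scanning ([findCandidateKinases()]),
#' scores every (query, kinase) pair for tissue, localization and phase
#' compatibility, combines them into Sk, and selects the kinase with the
#' highest Sk (ties broken by lexicographic kinase accession). A query
#' without any candidate kinase is returned with all components 0 and
#' classification `NOT_SUPPORTED`.
#'
#' @param corpus an [HCCCorpus-class].
#' @param accession query protein accession (must have a sequence).
#' @param weights list from [phosphoWeights()].
#' @param mode classification mode, see [classifyPhospho()].
#' @param threshold co-expression threshold for the phase component.
#' @param map GO evidence-code map.
#' @param includeSkipped,enforceMaxRepeat passed to
#'   [findCandidateKinases()].
#' @return a [PhosphoResult-class].
#' @export
scorePhospho <- function(corpus, accession, weights = phosphoWeights(),
                         mode = c("criteria", "threshold"), threshold = 0,
                         map = defaultEvidenceClassMap(),
                         includeSkipped = FALSE,
                         enforceMaxRepeat = FALSE) {
  mode <- match.arg(mode)
  pr <- proteins(corpus)
  go <- goAnnotations(corpus)
  cand <- findCandidateKinases(corpus, accession,
                               includeSkipped = includeSkipped,
                               enforceMaxRepeat = enforceMaxRepeat)
  kinases <- cand$kinases
  unknown <- setdiff(kinases, pr$accession)
  if (length(unknown)) {
    warning("candidate kinase(s) not in corpus, skipped: ",
            paste(unknown, collapse = ", "))
    kinases <- setdiff(kinases, unknown)
  }
  qRow <- pr[pr$accession == accession, , drop = FALSE]
  if (!nrow(qRow)) stop("unknown protein: ", accession)
  qGo <- go[go$accession == accession, , drop = FALSE]
  qGrid <- cycleGrid(corpus, accession)
  per <- data.frame(kinase = character(0), St = numeric(0),
                    Sl = numeric(0), Sp = numeric(0), Sk = numeric(0),
                    self = logical(0), stringsAsFactors = FALSE)
  for (k in kinases) {
    kRow <- pr[pr$accession == k, , drop = FALSE]
    St <- tissueScore(qRow$tissue_evidence, kRow$tissue_evidence)
    Sl <- localizationScore(
      qGo, go[go$accession == k, , drop = FALSE],
      qRow$localization_categories, kRow$localization_categories, map)
    Sp <- phaseScore(qGrid, cycleGrid(corpus, k), threshold)
    per <- rbind(per, data.frame(
      kinase = k, St = St, Sl = Sl, Sp = Sp,
      Sk = kinaseCorrelation(St, Sl, Sp, weights),
      self = identical(k, accession), stringsAsFactors = FALSE))
  }
  if (!nrow(per)) {
    return(new("PhosphoResult", accession = accession,
               bestKinase = NA_character_, St = 0, Sl = 0, Sp = 0, Sk = 0,
               perKinase = per, classification = "NOT_SUPPORTED"))
  }
  per <- per[order(-per$Sk, per$kinase), , drop = FALSE]
  rownames(per) <- NULL
  best <- per[1L, ]
  new("PhosphoResult", accession = accession, bestKinase = best$kinase,
      St = best$St, Sl = best$Sl, Sp = best$Sp, Sk = best$Sk,
      perKinase = per,
      classification = classifyPhospho(best$St, best$Sl, best$Sp, best$Sk,
                                       mode = mode))
}

#' Score phosphorylation correlation for many proteins
#'
#' Applies [scorePhospho()] to each accession and returns the flat result
#' table the reports are written from.
#'
#' @inheritParams scorePhospho
#' @param accessions character vector; defaults to every non-kinase
#'   protein with a sequence.
#' @return data.frame with one row per query: `accession`, `best_kinase`,
#'   `St`, `Sl`, `Sp`, `Sk`, `classification`, `n_candidate_kinases`.
#' @export
scoreAllPhospho <- function(corpus, accessions = NULL,
                            weights = phosphoWeights(),
                            mode = c("criteria", "threshold"),
                            threshold = 0,
                            map = defaultEvidenceClassMap(),
                            includeSkipped = FALSE,
                            enforceMaxRepeat = FALSE) {
  mode <- match.arg(mode)
  pr <- proteins(corpus)
  if (is.null(accessions))
    accessions <- pr$accession[!pr$is_kinase &
                               pr$accession %in%
                               names(proteinSequences(corpus))]
  rows <- lapply(accessions, function(a) {
    r <- scorePhospho(corpus, a, weights = weights, mode = mode,
                      threshold = threshold, map = map,
                      includeSkipped = includeSkipped,
                      enforceMaxRepeat = enforceMaxRepeat)
    data.frame(accession = r@accession, best_kinase = r@bestKinase,
               St = r@St, Sl = r@Sl, Sp = r@Sp, Sk = r@Sk,
               classification = r@classification,
               n_candidate_kinases = nrow(r@perKinase),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame(
    accession = character(0), best_kinase = character(0), St = numeric(0),
    Sl = numeric(0), Sp = numeric(0), Sk = numeric(0),
    classification = character(0), n_candidate_kinases = integer(0),
    stringsAsFactors = FALSE)
  out
}
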