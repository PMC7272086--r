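#' Per-pathway HCC-marker score Sc
#'
#' Scores a query gene inside one pathway from HCC evidence. A query that
#' is itself a known marker is pinned: wet-lab (`E1`) evidence scores 10,
#' large-scale (`E2`) evidence scores 8. Otherwise the other genes in the
#' same pathway (OGSPs) decide: with at least one E1 OGSP,
#' `Sc = W1*(Ne + 0.8*Nm)/Np + W2`; with only E2 OGSPs,
#' `Sc = W2*(Nm/Np)`; with no evidence at all, 0. `Np` counts the OGSPs
#' (pathway members excluding the query), `Ne`/`Nm` the E1/E2 OGSPs, so an
#' unconfirmed gene tops out at exactly `W1 + W2 = 8` and an all-E2
#' pathway at exactly `W2 = 3`.
#'
#' @param queryEvidence the query's own HCC evidence (`"E1"`, `"E2"`,
#'   `"NONE"`).
#' @param Np number of OGSPs (>= 1 for an unconfirmed query).
#' @param Ne,Nm numbers of E1 / E2 OGSPs; `Ne + Nm <= Np`.
#' @param W1,W2 weights of E1 and E2 OGSP evidence.
#' @return single numeric Sc in \[0, 10\].
#' @examples
#' pathwayScore("NONE", Np = 4, Ne = 1, Nm = 0)  # 4.25
#' @export
pathwayScore <- function(queryEvidence, Np, Ne, Nm, W1 = 5, W2 = 3) {
  stopifnot(queryEvidence %in% .HCC_LEVELS)
  if (queryEvidence == "E1") return(10)
  if (queryEvidence == "E2") return(8)
  stopifnot(Np >= 0, Ne >= 0, Nm >= 0, Ne + Nm <= Np)
  if (Np == 0)
    stop("pathway has no other members; cannot score an unconfirmed query")
  if (Ne >= 1) W1 * (Ne + 0.8 * Nm) / Np + W2
  else if (Nm >= 1) W2 * (Nm / Np)
  else 0
}

#' Pathway weight W(Sc) for aggregation
#'
#' Step weights for the Scm weighted mean: `Sc = 10 -> 10`, `Sc = 8 -> 8`,
#' `5 <= Sc < 8 -> 5`, `Sc < 5 -> 3`. The open interval (8, 10) is
#' unreachable for an unconfirmed gene (the Sc maximum is exactly 8) and
#' maps to 5.
#'
#' @param Sc numeric vector of per-pathway scores in \[0, 10\].
#' @return numeric vector of weights in \{3, 5, 8, 10\}.
#' @export
pathwayWeight <- function(Sc) {
  stopifnot(all(Sc >= 0 & Sc <= 10))
  ifelse(Sc == 10, 10,
         ifelse(Sc == 8, 8,
                ifelse(Sc >= 5, 5, 3)))
}

#' Classify a marker score Scm
#'
#' `Scm >= 4.25` strongly suggestive (reached when a quarter of the
#' pathway carries E1 evidence), `3 <= Scm < 4.25` suggestive (all-E2
#' support at least), below 3 not supported.
#'
#' @param Scm numeric vector.
#' @param strong,suggestive class thresholds.
#' @return character vector of class labels.
#' @export
classifyMarker <- function(Scm, strong = 4.25, suggestive = 3) {
  ifelse(Scm >= strong, "STRONGLY_SUGGESTIVE",
         ifelse(Scm >= suggestive, "SUGGESTIVE", "NOT_SUPPORTED"))
}

#' Evaluate one gene as an HCC marker across its pathways
#'
#' Computes Sc in every pathway containing the query, aggregates with the
#' step weights into `Scm = sum(Sc * W(Sc)) / sum(W(Sc))`, and classifies.
#' A gene contained in no pathway is `NOT_SUPPORTED` with `Scm = 0`.
#' Pathway members absent from the protein table count as unconfirmed
#' (`NONE`) OGSPs.
#'
#' @param corpus an [HCCCorpus-class].
#' @param accession query accession.
#' @param W1,W2 OGSP evidence weights, see [pathwayScore()].
#' @param strong,suggestive Scm class thresholds.
#' @return a [MarkerResult-class].
#' @export
scoreMarker <- function(corpus, accession, W1 = 5, W2 = 3,
                        strong = 4.25, suggestive = 3) {
  pr <- proteins(corpus)
  evid <- setNames(pr$hcc_evidence, pr$accession)
  queryEvidence <- if (accession %in% names(evid)) evid[[accession]]
                   else "NONE"
  pws <- pathways(corpus)
  containing <- names(pws)[vapply(pws, function(m) accession %in% m,
                                  logical(1))]
  rows <- list()
  for (pw in containing) {
    ogsp <- setdiff(pws[[pw]], accession)
    e <- evid[ogsp]
    e[is.na(e)] <- "NONE"
    Np <- length(ogsp)
    Ne <- sum(e == "E1")
    Nm <- sum(e == "E2")
    if (Np == 0 && queryEvidence == "NONE") {
      warning("pathway ", pw, " has no other members; skipped for ",
              accession)
      next
    }
    Sc <- pathwayScore(queryEvidence, Np, Ne, Nm, W1, W2)
    rows[[length(rows) + 1L]] <- data.frame(
      pathway_id = pw, Np = Np, Ne = Ne, Nm = Nm, Sc = Sc,
      weight = pathwayWeight(Sc), stringsAsFactors = FALSE)
  }
  perPathway <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pathway_id = character(0), Np = integer(0),
               Ne = integer(0), Nm = integer(0), Sc = numeric(0),
               weight = numeric(0), stringsAsFactors = FALSE)
  rownames(perPathway) <- NULL
  if (nrow(perPathway)) {
    Scm <- sum(perPathway$Sc * perPathway$weight) / sum(perPathway$weight)
    cls <- classifyMarker(Scm, strong, suggestive)
  } else {
    Scm <- 0
    cls <- "NOT_SUPPORTED"
  }
  new("MarkerResult", accession = accession, perPathway = perPathway,
      Scm = Scm, classification = cls,
      knownMarker = queryEvidence %in% c("E1", "E2"))
}

#' Evaluate many genes as HCC markers
#'
#' Applies [scoreMarker()] to each accession and returns the flat summary
#' table plus the long per-pathway table.
#'
#' @inheritParams scoreMarker
#' @param accessions character vector; defaults to the union of all
#'   pathway members.
#' @return list with `markers` (one row per gene: `accession`,
#'   `n_pathways`, `Scm`, `classification`, `known_marker`) and
#'   `perPathway` (long format: `accession`, `pathway_id`, `Np`, `Ne`,
#'   `Nm`, `Sc`, `weight`).
#' @export
scoreAllMarkers <- function(corpus, accessions = NULL, W1 = 5, W2 = 3,
                            strong = 4.25, suggestive = 3) {
  if (is.null(accessions))
    accessions <- sort(unique(unlist(pathways(corpus), use.names = FALSE)))
  rows <- list()
  long <- list()
  for (a in accessions) {
    r <- scoreMarker(corpus, a, W1, W2, strong, suggestive)
    rows[[length(rows) + 1L]] <- data.frame(
      accession = a, n_pathways = nrow(r@perPathway), Scm = r@Scm,
      classification = r@classification, known_marker = r@knownMarker,
      stringsAsFactors = FALSE)
    if (nrow(r@perPathway))
      long[[length(long) + 1L]] <-
        cbind(accession = a, r@perPathway, stringsAsFactors = FALSE)
  }
  markers <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(0), n_pathways = integer(0),
               Scm = numeric(0), classification = character(0),
               known_marker = logical(0), stringsAsFactors = FALSE)
  perPathway <- if (length(long)) do.call(rbind, long) else
    data.frame(accession = character(0), pathway_id = character(0),
               Np = integer(0), Ne = integer(0), Nm = integer(0),
               Sc = numeric(0), weight = numeric(0),
               stringsAsFactors = FALSE)
  rownames(markers) <- rownames(perPathway) <- NULL
  list(markers = markers, perPathway = perPathway)
}
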