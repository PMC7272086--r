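#' Combine phosphorylation and marker classes into the HCCPM call
#'
#' A candidate is a strongly suggestive HCC phosphorylated marker only
#' when both the phosphorylation-correlation and the marker evaluation are
#' strongly suggestive; it is not supported only when both are not
#' supported; every mixed case is suggestive.
#'
#' @param phosphoClass,markerClass character vectors of class labels
#'   (recycled to common length).
#' @return character vector of HCCPM class labels.
#' @examples
#' classifyHccpm("STRONGLY_SUGGESTIVE", "NOT_SUPPORTED")  # SUGGESTIVE
#' @export
classifyHccpm <- function(phosphoClass, markerClass) {
  stopifnot(all(phosphoClass %in% .CLASS_LEVELS),
            all(markerClass %in% .CLASS_LEVELS))
  n <- max(length(phosphoClass), length(markerClass))
  p <- rep_len(phosphoClass, n)
  m <- rep_len(markerClass, n)
  ifelse(p == "STRONGLY_SUGGESTIVE" & m == "STRONGLY_SUGGESTIVE",
         "STRONGLY_SUGGESTIVE",
         ifelse(p == "NOT_SUPPORTED" & m == "NOT_SUPPORTED",
                "NOT_SUPPORTED", "SUGGESTIVE"))
}

#' Join drug-target rows for one gene
#'
#' Returns all drug rows targeting the accession, grouped counts per
#' category. A gene absent from the table gets zero counts.
#'
#' @param accession target accession.
#' @param drugs drug-target data.frame (`drug_id`, `drug_name`,
#'   `category`, `target_accession`), e.g. from [drugTargets()].
#' @return list with `drugs` (the matching rows) and `counts` (named
#'   integer vector over `LIVER_CANCER`, `CANCER`, `NON_CANCER`).
#' @export
joinDrugs <- function(accession, drugs) {
  hit <- drugs[drugs$target_accession == accession, , drop = FALSE]
  rownames(hit) <- NULL
  counts <- vapply(.DRUG_CATEGORIES,
                   function(cat) sum(hit$category == cat), integer(1))
  list(drugs = hit, counts = counts)
}

#' Full HCCPM table for a corpus
#'
#' Merges the phosphorylation and marker result tables over the union of
#' their accessions (a gene missing from one side counts as
#' `NOT_SUPPORTED` there with score 0), derives the HCCPM class and joins
#' the per-category drug counts.
#'
#' @param phospho data.frame from [scoreAllPhospho()].
#' @param markers data.frame from [scoreAllMarkers()]`$markers`.
#' @param drugs drug-target data.frame.
#' @return data.frame with one row per gene: `accession`, `Sk`, `Scm`,
#'   `phospho_class`, `marker_class`, `hccpm_class`,
#'   `n_liver_cancer_drugs`, `n_cancer_drugs`, `n_non_cancer_drugs`.
#' @export
hccpmTable <- function(phospho, markers, drugs = emptyDrugTable()) {
  accs <- sort(unique(c(phospho$accession, markers$accession)))
  pi <- match(accs, phospho$accession)
  mi <- match(accs, markers$accession)
  out <- data.frame(
    accession = accs,
    Sk = ifelse(is.na(pi), 0, phospho$Sk[pi]),
    Scm = ifelse(is.na(mi), 0, markers$Scm[mi]),
    phospho_class = ifelse(is.na(pi), "NOT_SUPPORTED",
                           phospho$classification[pi]),
    marker_class = ifelse(is.na(mi), "NOT_SUPPORTED",
                          markers$classification[mi]),
    stringsAsFactors = FALSE)
  out$hccpm_class <- classifyHccpm(out$phospho_class, out$marker_class)
  counts <- t(vapply(accs, function(a) joinDrugs(a, drugs)$counts,
                     integer(3)))
  out$n_liver_cancer_drugs <- counts[, "LIVER_CANCER"]
  out$n_cancer_drugs <- counts[, "CANCER"]
  out$n_non_cancer_drugs <- counts[, "NON_CANCER"]
  rownames(out) <- NULL
  out
}

#' Count classifications per scoring system
#'
#' Tabulates a class-label vector over the three levels (in fixed order),
#' so each triple sums to the number of classified genes.
#'
#' @param classes character vector of class labels.
#' @return named integer vector over the three class levels.
#' @export
classCounts <- function(classes) {
  stopifnot(all(classes %in% .CLASS_LEVELS))
  vapply(.CLASS_LEVELS, function(l) sum(classes == l), integer(1))
}

#' Fraction of genes with phosphorylation support
#'
#' The share of genes classified strongly suggestive or suggestive, in
#' percent of the classified total.
#'
#' @param counts named vector as from [classCounts()] (order strongly
#'   suggestive, suggestive, not supported).
#' @return single numeric percentage.
#' @examples
#' supportedFraction(c(71, 1373, 4511))  # 24.2
#' @export
supportedFraction <- function(counts) {
  stopifnot(length(counts) == 3L, all(counts >= 0), sum(counts) > 0)
  100 * (counts[[1]] + counts[[2]]) / sum(counts)
}

#' Summarize an HCCPM result table
#'
#' Per-system class counts (each summing to the candidate count) and drug
#' coverage (number of genes with at least one drug, per category).
#'
#' @param hccpm data.frame from [hccpmTable()].
#' @return list with `n` (candidate count), `phospho`, `marker`, `hccpm`
#'   (named count triples) and `drug_coverage` (named counts per drug
#'   category).
#' @export
summarizeResults <- function(hccpm) {
  list(
    n = nrow(hccpm),
    phospho = classCounts(hccpm$phospho_class),
    marker = classCounts(hccpm$marker_class),
    hccpm = classCounts(hccpm$hccpm_class),
    drug_coverage = c(
      LIVER_CANCER = sum(hccpm$n_liver_cancer_drugs > 0),
      CANCER = sum(hccpm$n_cancer_drugs > 0),
      NON_CANCER = sum(hccpm$n_non_cancer_drugs > 0))
  )
}
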