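#' HCCCorpus: container for a biomarker-prediction corpus
#'
#' An `HCCCorpus` bundles everything a prediction run needs: per-protein
#' annotation, amino-acid sequences, GO cellular-component annotations,
#' phosphorylation motif definitions, pathway gene sets, drug-target rows and
#' cell-cycle expression profiles (raw points plus their 100-point grids).
#'
#' @slot proteins `data.frame` with columns `accession`, `gene_id`,
#'   `gene_symbol`, `tissue_evidence` (`T1`/`T2`/`T3`/`ABSENT`),
#'   `hcc_evidence` (`E1`/`E2`/`NONE`), `localization_categories`
#'   (semicolon-separated subset of the six categories) and `is_kinase`
#'   (logical).
#' @slot sequences [Biostrings::AAStringSet] named by accession; proteins
#'   without a sequence simply have no entry.
#' @slot goAnnotations `data.frame` with columns `accession`, `go_term_id`,
#'   `evidence_code`.
#' @slot motifs `data.frame` with columns `motif_id`, `pattern` (Prosite
#'   syntax), `site_offset` (0-based element index of the phosphoacceptor),
#'   `max_repeat`, `skip_flag` (logical), `kinase_accessions`
#'   (semicolon-separated), `description`.
#' @slot pathways named list of character vectors (member accessions), names
#'   are pathway ids.
#' @slot pathwayNames named character vector of free-text pathway names.
#' @slot drugs `data.frame` with columns `drug_id`, `drug_name`, `category`
#'   (`LIVER_CANCER`/`CANCER`/`NON_CANCER`), `target_accession`.
#' @slot profiles `data.frame` of raw cycle points: `accession`,
#'   `time_percent` in \[0,100), `log2_ratio`.
#' @slot profileGrid numeric matrix (one row per profiled accession, 100
#'   columns for integer cycle percents 0-99) of interpolated log2 ratios.
#'
#' @seealso [HCCCorpus()] for construction, [validateCorpus()] for
#'   cross-reference checking, [makeCorpus()] for synthetic corpora.
#' @importClassesFrom Biostrings AAStringSet
#' @export
setClass("HCCCorpus",
  representation(
    proteins = "data.frame",
    sequences = "AAStringSet",
    goAnnotations = "data.frame",
    motifs = "data.frame",
    pathways = "list",
    pathwayNames = "character",
    drugs = "data.frame",
    profiles = "data.frame",
    profileGrid = "matrix"
  )
)

#' PhosphoResult: phosphorylation-correlation result for one query protein
#'
#' Holds the per-kinase component scores and the best-kinase summary produced
#' by [scorePhospho()].
#'
#' @slot accession query protein accession.
#' @slot bestKinase accession of the kinase attaining the maximal Sk
#'   (ties broken lexicographically), or `NA` when no candidate kinase exists.
#' @slot St,Sl,Sp,Sk component and combined scores of the best kinase
#'   (all 0 when no candidates).
#' @slot perKinase `data.frame` with one row per candidate kinase:
#'   `kinase`, `St`, `Sl`, `Sp`, `Sk`, `self` (autophosphorylation flag).
#' @slot classification one of `STRONGLY_SUGGESTIVE`, `SUGGESTIVE`,
#'   `NOT_SUPPORTED`.
#' @export
setClass("PhosphoResult",
  representation(
    accession = "character",
    bestKinase = "character",
    St = "numeric",
    Sl = "numeric",
    Sp = "numeric",
    Sk = "numeric",
    perKinase = "data.frame",
    classification = "character"
  )
)

#' MarkerResult: HCC-marker evaluation result for one query gene
#'
#' Produced by [scoreMarker()]: per-pathway scores Sc with their weights, the
#' aggregated Scm and the classification.
#'
#' @slot accession query accession.
#' @slot perPathway `data.frame` with one row per containing pathway:
#'   `pathway_id`, `Np`, `Ne`, `Nm`, `Sc`, `weight`.
#' @slot Scm weighted mean of the per-pathway Sc (0 when the gene sits in no
#'   pathway).
#' @slot classification one of the three class labels.
#' @slot knownMarker `TRUE` when the query itself carries E1 or E2 evidence.
#' @export
setClass("MarkerResult",
  representation(
    accession = "character",
    perPathway = "data.frame",
    Scm = "numeric",
    classification = "character",
    knownMarker = "logical"
  )
)

setValidity("HCCCorpus", function(object) {
  msgs <- character(0)
  pr <- object@proteins
  need <- c("accession", "gene_id", "gene_symbol", "tissue_evidence",
            "hcc_evidence", "localization_categories", "is_kinase")
  miss <- setdiff(need, names(pr))
  if (length(miss))
    msgs <- c(msgs, paste0("proteins lacks column(s): ",
                           paste(miss, collapse = ", ")))
  if (!length(msgs)) {
    if (anyDuplicated(pr$accession))
      msgs <- c(msgs, "duplicate protein accessions")
    if (!all(pr$tissue_evidence %in% .TISSUE_LEVELS))
      msgs <- c(msgs, "invalid tissue_evidence level")
    if (!all(pr$hcc_evidence %in% .HCC_LEVELS))
      msgs <- c(msgs, "invalid hcc_evidence level")
  }
  if (nrow(object@profiles) &&
      !all(c("accession", "time_percent", "log2_ratio") %in%
           names(object@profiles)))
    msgs <- c(msgs, "profiles lacks accession/time_percent/log2_ratio")
  if (nrow(object@profileGrid) && ncol(object@profileGrid) != 100L)
    msgs <- c(msgs, "profileGrid must have 100 columns")
  if (length(object@pathways) && is.null(names(object@pathways)))
    msgs <- c(msgs, "pathways must be a named list")
  if (length(msgs)) msgs else TRUE
})
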