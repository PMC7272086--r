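#' Construct an HCCCorpus
#'
#' Assembles the corpus container from its parts, normalising column types
#' and computing the 100-point cell-cycle grids from the raw profile points.
#' Cross-reference consistency is *not* enforced here; run
#' [validateCorpus()] to obtain a report.
#'
#' @param proteins data.frame of per-protein annotation (see [HCCCorpus-class]
#'   for columns; missing optional columns are filled with `NA`/defaults).
#' @param sequences named [Biostrings::AAStringSet] (or named character
#'   vector) of amino-acid sequences.
#' @param goAnnotations data.frame `accession`, `go_term_id`,
#'   `evidence_code`.
#' @param motifs data.frame of motif definitions (see [HCCCorpus-class]).
#' @param pathways named list of member-accession character vectors.
#' @param pathwayNames optional named character vector of pathway names.
#' @param drugs data.frame of drug-target rows.
#' @param profiles data.frame of raw cycle points (`accession`,
#'   `time_percent`, `log2_ratio`).
#' @param cyclic logical; interpolate profiles cyclically (wrap 100 -> 0,
#'   the default) or with flat extrapolation beyond the first/last point.
#' @return an [HCCCorpus-class] object.
#' @examples
#' pr <- data.frame(accession = c("P1", "K1"),
#'                  tissue_evidence = c("T1", "T1"),
#'                  hcc_evidence = c("NONE", "NONE"),
#'                  is_kinase = c(FALSE, TRUE))
#' corpus <- HCCCorpus(proteins = pr,
#'                     sequences = c(P1 = "AARRASAA", K1 = "MKKK"))
#' proteins(corpus)
#' @export
HCCCorpus <- function(proteins = emptyProteinTable(),
                      sequences = Biostrings::AAStringSet(),
                      goAnnotations = emptyGoTable(),
                      motifs = emptyMotifTable(),
                      pathways = list(),
                      pathwayNames = character(0),
                      drugs = emptyDrugTable(),
                      profiles = emptyProfileTable(),
                      cyclic = TRUE) {
  proteins <- .normalizeProteinTable(proteins)
  if (is.character(sequences))
    sequences <- Biostrings::AAStringSet(sequences)
  goAnnotations <- .coerceTable(goAnnotations, emptyGoTable())
  motifs <- .coerceTable(motifs, emptyMotifTable())
  if (nrow(motifs)) {
    motifs$site_offset <- as.integer(motifs$site_offset)
    motifs$max_repeat <- as.integer(motifs$max_repeat)
    motifs$skip_flag <- as.logical(motifs$skip_flag)
  }
  drugs <- .coerceTable(drugs, emptyDrugTable())
  profiles <- .coerceTable(profiles, emptyProfileTable())
  pathways <- lapply(pathways, function(m) unique(as.character(m)))
  if (length(pathways) && is.null(names(pathways)))
    names(pathways) <- paste0("PW", seq_along(pathways))
  if (!length(pathwayNames))
    pathwayNames <- setNames(names(pathways), names(pathways))
  grid <- .profileGridMatrix(profiles, cyclic = cyclic)
  new("HCCCorpus",
      proteins = proteins, sequences = sequences,
      goAnnotations = goAnnotations, motifs = motifs,
      pathways = pathways,
      pathwayNames = as.character(pathwayNames) |>
        setNames(names(pathwayNames)),
      drugs = drugs, profiles = profiles, profileGrid = grid)
}

# -- empty prototypes ---------------------------------------------------------

#' Empty annotation-table prototypes
#'
#' Zero-row data.frames with the canonical columns, used as constructor
#' defaults and as read/write schemas.
#' @return a zero-row data.frame.
#' @export
emptyProteinTable <- function() {
  data.frame(accession = character(0), gene_id = character(0),
             gene_symbol = character(0), tissue_evidence = character(0),
             hcc_evidence = character(0),
             localization_categories = character(0),
             is_kinase = logical(0), stringsAsFactors = FALSE)
}

#' @rdname emptyProteinTable
#' @export
emptyGoTable <- function() {
  data.frame(accession = character(0), go_term_id = character(0),
             evidence_code = character(0), stringsAsFactors = FALSE)
}

#' @rdname emptyProteinTable
#' @export
emptyMotifTable <- function() {
  data.frame(motif_id = character(0), pattern = character(0),
             site_offset = integer(0), max_repeat = integer(0),
             skip_flag = logical(0), kinase_accessions = character(0),
             description = character(0), stringsAsFactors = FALSE)
}

#' @rdname emptyProteinTable
#' @export
emptyDrugTable <- function() {
  data.frame(drug_id = character(0), drug_name = character(0),
             category = character(0), target_accession = character(0),
             stringsAsFactors = FALSE)
}

#' @rdname emptyProteinTable
#' @export
emptyProfileTable <- function() {
  data.frame(accession = character(0), time_percent = numeric(0),
             log2_ratio = numeric(0), stringsAsFactors = FALSE)
}

.normalizeProteinTable <- function(pr) {
  pr <- as.data.frame(pr, stringsAsFactors = FALSE)
  defaults <- list(gene_id = NA_character_, gene_symbol = NA_character_,
                   tissue_evidence = "ABSENT", hcc_evidence = "NONE",
                   localization_categories = "", is_kinase = FALSE)
  for (nm in names(defaults))
    if (is.null(pr[[nm]])) pr[[nm]] <- rep(defaults[[nm]],
                                           length.out = nrow(pr))
  pr$accession <- as.character(pr$accession)
  pr$is_kinase <- as.logical(pr$is_kinase)
  pr$localization_categories[is.na(pr$localization_categories)] <- ""
  rownames(pr) <- NULL
  pr[c("accession", "gene_id", "gene_symbol", "tissue_evidence",
       "hcc_evidence", "localization_categories", "is_kinase")]
}

.coerceTable <- function(x, proto) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  miss <- setdiff(names(proto), names(x))
  if (length(miss) && nrow(x))
    stop("table lacks column(s): ", paste(miss, collapse = ", "))
  if (!nrow(x)) return(proto)
  x[names(proto)]
}

.profileGridMatrix <- function(profiles, cyclic = TRUE) {
  if (!nrow(profiles))
    return(matrix(numeric(0), nrow = 0, ncol = 100))
  accs <- unique(profiles$accession)
  grid <- t(vapply(accs, function(a) {
    sub <- profiles[profiles$accession == a, , drop = FALSE]
    sub <- sub[order(sub$time_percent), , drop = FALSE]
    normalizeProfile(sub$time_percent, sub$log2_ratio, cyclic = cyclic)
  }, numeric(100)))
  rownames(grid) <- accs
  grid
}

# -- accessors ---------------------------------------------------------------

#' Corpus accessors
#'
#' Accessor generics for the components of an [HCCCorpus-class].
#' `cycleGrid()` returns the interpolated 100-point profile matrix;
#' `cycleGrid(x, accession)` returns one row, or `NULL` when the accession
#' has no profile.
#'
#' @param x an `HCCCorpus`.
#' @param accession optional accession for `cycleGrid`.
#' @return the requested component.
#' @name corpus-accessors
NULL

#' @rdname corpus-accessors
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))
#' @rdname corpus-accessors
#' @export
setGeneric("proteinSequences",
           function(x) standardGeneric("proteinSequences"))
#' @rdname corpus-accessors
#' @export
setGeneric("goAnnotations", function(x) standardGeneric("goAnnotations"))
#' @rdname corpus-accessors
#' @export
setGeneric("motifs", function(x) standardGeneric("motifs"))
#' @rdname corpus-accessors
#' @export
setGeneric("pathways", function(x) standardGeneric("pathways"))
#' @rdname corpus-accessors
#' @export
setGeneric("drugTargets", function(x) standardGeneric("drugTargets"))
#' @rdname corpus-accessors
#' @export
setGeneric("cycleProfiles", function(x) standardGeneric("cycleProfiles"))
#' @rdname corpus-accessors
#' @export
setGeneric("cycleGrid",
           function(x, accession = NULL) standardGeneric("cycleGrid"))

#' @rdname corpus-accessors
setMethod("proteins", "HCCCorpus", function(x) x@proteins)
#' @rdname corpus-accessors
setMethod("proteinSequences", "HCCCorpus", function(x) x@sequences)
#' @rdname corpus-accessors
setMethod("goAnnotations", "HCCCorpus", function(x) x@goAnnotations)
#' @rdname corpus-accessors
setMethod("motifs", "HCCCorpus", function(x) x@motifs)
#' @rdname corpus-accessors
setMethod("pathways", "HCCCorpus", function(x) x@pathways)
#' @rdname corpus-accessors
setMethod("drugTargets", "HCCCorpus", function(x) x@drugs)
#' @rdname corpus-accessors
setMethod("cycleProfiles", "HCCCorpus", function(x) x@profiles)
#' @rdname corpus-accessors
setMethod("cycleGrid", "HCCCorpus", function(x, accession = NULL) {
  if (is.null(accession)) return(x@profileGrid)
  if (!accession %in% rownames(x@profileGrid)) return(NULL)
  x@profileGrid[accession, ]
})

#' @describeIn HCCCorpus compact display of component sizes.
#' @param object an `HCCCorpus`.
#' @exportMethod show
setMethod("show", "HCCCorpus", function(object) {
  pr <- object@proteins
  cat("HCCCorpus with", nrow(pr), "proteins (",
      sum(pr$is_kinase), "kinases )\n")
  cat("  sequences:    ", length(object@sequences), "\n")
  cat("  GO rows:      ", nrow(object@goAnnotations), "\n")
  cat("  motifs:       ", nrow(object@motifs), "\n")
  cat("  pathways:     ", length(object@pathways), "\n")
  cat("  drug rows:    ", nrow(object@drugs), "\n")
  cat("  cycle grids:  ", nrow(object@profileGrid), "\n")
  invisible(object)
})

setMethod("show", "PhosphoResult", function(object) {
  cat("PhosphoResult for", object@accession, "\n")
  if (is.na(object@bestKinase)) {
    cat("  no candidate kinases;", object@classification, "\n")
  } else {
    cat(sprintf("  best kinase %s: St=%g Sl=%g Sp=%g Sk=%.3f (%s)\n",
                object@bestKinase, object@St, object@Sl, object@Sp,
                object@Sk, object@classification))
    cat("  candidate kinases:", nrow(object@perKinase), "\n")
  }
  invisible(object)
})

setMethod("show", "MarkerResult", function(object) {
  cat("MarkerResult for", object@accession,
      if (object@knownMarker) "(known marker)" else "", "\n")
  cat(sprintf("  %d pathway(s); Scm = %.3f (%s)\n",
              nrow(object@perPathway), object@Scm, object@classification))
  invisible(object)
})
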