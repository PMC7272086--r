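#' Validate an HCCCorpus
#'
#' Checks corpus invariants and cross-references and returns a report
#' instead of failing: duplicate accessions, invalid enumeration values,
#' sequences with non-standard residues, unparsable motif patterns or
#' out-of-range site offsets, and dangling references (motif kinases,
#' pathway members, drug targets, GO or profile accessions that do not
#' resolve against the protein table) are `ERROR`; missing optional data
#' (e.g. proteins without a sequence) are `INFO`.
#'
#' @param corpus an [HCCCorpus-class].
#' @return data.frame with columns `severity` (`ERROR`/`WARNING`/`INFO`),
#'   `location`, `message`; zero rows when the corpus is fully consistent.
#' @export
validateCorpus <- function(corpus) {
  issues <- list()
  add <- function(severity, location, message)
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, location = location, message = message,
      stringsAsFactors = FALSE)

  pr <- proteins(corpus)
  dup <- unique(pr$accession[duplicated(pr$accession)])
  for (d in dup) add("ERROR", "proteins", paste0("duplicate accession ", d))
  bad <- pr$accession[!pr$tissue_evidence %in% .TISSUE_LEVELS]
  for (b in bad) add("ERROR", "proteins",
                     paste0(b, ": invalid tissue_evidence"))
  bad <- pr$accession[!pr$hcc_evidence %in% .HCC_LEVELS]
  for (b in bad) add("ERROR", "proteins",
                     paste0(b, ": invalid hcc_evidence"))
  for (i in seq_len(nrow(pr))) {
    cats <- .asCategories(pr$localization_categories[i])
    unknown <- setdiff(cats, .LOCALIZATION_CATEGORIES)
    if (length(unknown))
      add("ERROR", "proteins",
          paste0(pr$accession[i], ": unknown localization category ",
                 paste(unknown, collapse = ";")))
  }

  seqs <- proteinSequences(corpus)
  seqless <- setdiff(pr$accession, names(seqs))
  if (length(seqless))
    add("INFO", "sequences",
        paste0(length(seqless),
               " protein(s) without a sequence (not motif-scannable)"))
  orphan <- setdiff(names(seqs), pr$accession)
  for (o in orphan) add("ERROR", "sequences",
                        paste0("sequence for unknown accession ", o))
  for (nm in names(seqs)) {
    ch <- unique(strsplit(as.character(seqs[[nm]]), "")[[1]])
    if (!all(ch %in% .AA_ALPHABET))
      add("ERROR", "sequences",
          paste0(nm, ": non-standard residue(s) ",
                 paste(setdiff(ch, .AA_ALPHABET), collapse = "")))
  }

  mots <- motifs(corpus)
  for (i in seq_len(nrow(mots))) {
    ast <- tryCatch(parsePrositePattern(mots$pattern[i]),
                    error = function(e) e)
    if (inherits(ast, "error")) {
      add("ERROR", "motifs",
          paste0(mots$motif_id[i], ": unparsable pattern (",
                 conditionMessage(ast), ")"))
      next
    }
    if (mots$site_offset[i] < 0L ||
        mots$site_offset[i] >= length(ast$elements))
      add("ERROR", "motifs",
          paste0(mots$motif_id[i], ": site_offset out of range"))
    dangling <- setdiff(.splitSemicolon(mots$kinase_accessions[i]),
                        pr$accession)
    for (d in dangling)
      add("ERROR", "motifs",
          paste0(mots$motif_id[i], ": unresolved kinase accession ", d))
  }

  for (pw in names(pathways(corpus))) {
    dangling <- setdiff(pathways(corpus)[[pw]], pr$accession)
    for (d in dangling)
      add("ERROR", "pathways",
          paste0(pw, ": unresolved member ", d))
  }

  dr <- drugTargets(corpus)
  if (nrow(dr)) {
    bad <- !dr$category %in% .DRUG_CATEGORIES
    for (i in which(bad))
      add("ERROR", "drugs",
          paste0(dr$drug_id[i], ": invalid category ", dr$category[i]))
    key <- paste(dr$drug_id, dr$target_accession)
    for (k in unique(key[duplicated(key)]))
      add("ERROR", "drugs", paste0("duplicate drug-target row ", k))
    dangling <- setdiff(unique(dr$target_accession), pr$accession)
    for (d in dangling)
      add("ERROR", "drugs", paste0("unresolved target accession ", d))
  }

  prof <- cycleProfiles(corpus)
  if (nrow(prof)) {
    dangling <- setdiff(unique(prof$accession), pr$accession)
    for (d in dangling)
      add("ERROR", "profiles",
          paste0("profile for unknown accession ", d))
  }
  go <- goAnnotations(corpus)
  if (nrow(go)) {
    dangling <- setdiff(unique(go$accession), pr$accession)
    for (d in dangling)
      add("ERROR", "go_annotations",
          paste0("annotation for unknown accession ", d))
  }

  if (!length(issues))
    return(data.frame(severity = character(0), location = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}
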