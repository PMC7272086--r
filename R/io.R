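# Readers and writers for the plain-text interchange formats. Everything is
# tab-delimited (free-text drug and pathway names make CSV quoting fragile),
# UTF-8, with a header row.

#' Read protein sequences from FASTA
#'
#' The accession is the first whitespace-delimited token of the header.
#' Sequences are upper-cased and a terminal `*` is stripped; records
#' containing residues outside the standard 20-letter alphabet are skipped
#' with a warning.
#'
#' @param path FASTA file.
#' @return named [Biostrings::AAStringSet].
#' @export
readFastaProteins <- function(path) {
  raw <- Biostrings::readAAStringSet(path)
  names(raw) <- vapply(strsplit(names(raw), "[[:space:]]+"), `[`,
                       character(1), 1L)
  seqs <- toupper(as.character(raw))
  seqs <- sub("\\*$", "", seqs)
  ok <- vapply(seqs, function(s)
    all(strsplit(s, "")[[1]] %in% .AA_ALPHABET), logical(1))
  if (any(!ok))
    warning("skipping record(s) with non-standard residues: ",
            paste(names(seqs)[!ok], collapse = ", "))
  Biostrings::AAStringSet(seqs[ok])
}

#' Write protein sequences to FASTA
#'
#' @param seqs named [Biostrings::AAStringSet] or character vector.
#' @param path output file.
#' @export
writeFastaProteins <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read pathway gene sets from GMT
#'
#' Standard GMT: one pathway per line, tab-delimited `id`, `description`,
#' then member identifiers. Duplicate members are deduplicated with a
#' warning; lines with fewer than three fields are an error naming the
#' line.
#'
#' @param path GMT file.
#' @return list with `pathways` (named list of member vectors) and
#'   `names` (named character vector of descriptions).
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  pws <- list()
  descs <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT line ", i, ": fewer than 3 fields")
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning("GMT line ", i, " (", f[1],
              "): duplicate members deduplicated")
      members <- unique(members)
    }
    pws[[f[1]]] <- members
    descs[f[1]] <- f[2]
  }
  list(pathways = pws, names = descs)
}

#' Write pathway gene sets to GMT
#'
#' @param pathways named list of member vectors.
#' @param path output file.
#' @param names optional named character vector of descriptions.
#' @export
writeGmt <- function(pathways, path, names = NULL) {
  lines <- vapply(base::names(pathways), function(id) {
    desc <- if (!is.null(names) && !is.na(names[id])) names[id] else id
    paste(c(id, desc, pathways[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write the tab-delimited annotation tables
#'
#' `readAnnotationTable()` reads the per-protein table (semicolon-separated
#' `localization_categories`, logical `is_kinase`);
#' `readGoAnnotationTable()`, `readMotifTable()`, `readProfileTable()` and
#' `readDrugTable()` read the GO, motif, cycle-profile and drug-target
#' tables. `writeTsv()` writes any data.frame back (tab-delimited, no
#' quoting, no row names).
#'
#' @param path file path.
#' @return data.frame with the canonical columns of the table.
#' @export
readAnnotationTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  tab$is_kinase <- as.logical(tab$is_kinase)
  .normalizeProteinTable(tab)
}

#' @rdname readAnnotationTable
#' @export
readGoAnnotationTable <- function(path) {
  .coerceTable(utils::read.delim(path, stringsAsFactors = FALSE),
               emptyGoTable())
}

#' @rdname readAnnotationTable
#' @export
readMotifTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab <- .coerceTable(tab, emptyMotifTable())
  if (nrow(tab)) {
    tab$site_offset <- as.integer(tab$site_offset)
    tab$max_repeat <- as.integer(tab$max_repeat)
    tab$skip_flag <- as.logical(tab$skip_flag)
  }
  tab
}

#' @rdname readAnnotationTable
#' @export
readProfileTable <- function(path) {
  .coerceTable(utils::read.delim(path, stringsAsFactors = FALSE),
               emptyProfileTable())
}

#' @rdname readAnnotationTable
#' @export
readDrugTable <- function(path) {
  .coerceTable(utils::read.delim(path, stringsAsFactors = FALSE),
               emptyDrugTable())
}

#' @rdname readAnnotationTable
#' @param x data.frame to write.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# canonical file names of a corpus bundle
.BUNDLE_FILES <- c(proteins = "proteins.tsv", sequences = "sequences.fasta",
                   go = "go_annotations.tsv", motifs = "motifs.tsv",
                   pathways = "pathways.gmt", drugs = "drugs.tsv",
                   profiles = "profiles.tsv")

#' Write / read a corpus as a directory bundle
#'
#' `writeCorpus()` serializes an [HCCCorpus-class] into a directory of
#' plain-text files (`proteins.tsv`, `sequences.fasta`,
#' `go_annotations.tsv`, `motifs.tsv`, `pathways.gmt`, `drugs.tsv`,
#' `profiles.tsv`); `readCorpus()` reassembles it. Files for empty
#' components are still written so a bundle is always complete.
#'
#' @param corpus an `HCCCorpus`.
#' @param dir bundle directory (created if needed).
#' @return `writeCorpus()` the directory, `readCorpus()` an `HCCCorpus`.
#' @export
writeCorpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(nm) file.path(dir, .BUNDLE_FILES[[nm]])
  writeTsv(proteins(corpus), f("proteins"))
  writeFastaProteins(proteinSequences(corpus), f("sequences"))
  writeTsv(goAnnotations(corpus), f("go"))
  writeTsv(motifs(corpus), f("motifs"))
  writeGmt(pathways(corpus), f("pathways"), corpus@pathwayNames)
  writeTsv(drugTargets(corpus), f("drugs"))
  writeTsv(cycleProfiles(corpus), f("profiles"))
  invisible(dir)
}

#' @rdname writeCorpus
#' @param cyclic passed to [HCCCorpus()] for profile interpolation.
#' @export
readCorpus <- function(dir, cyclic = TRUE) {
  f <- function(nm) file.path(dir, .BUNDLE_FILES[[nm]])
  gmt <- if (file.exists(f("pathways")) &&
             length(readLines(f("pathways"), warn = FALSE)))
    readGmt(f("pathways")) else list(pathways = list(),
                                     names = character(0))
  HCCCorpus(
    proteins = readAnnotationTable(f("proteins")),
    sequences = readFastaProteins(f("sequences")),
    goAnnotations = readGoAnnotationTable(f("go")),
    motifs = readMotifTable(f("motifs")),
    pathways = gmt$pathways, pathwayNames = gmt$names,
    drugs = readDrugTable(f("drugs")),
    profiles = readProfileTable(f("profiles")),
    cyclic = cyclic)
}

#' Run the full prediction pipeline on a corpus
#'
#' Stage order: corpus validation (aborts on `ERROR` findings unless
#' `force`), motif scan + phosphorylation correlation, marker evaluation,
#' HCCPM combination with drug join, and the corpus summary.
#'
#' @param corpus an [HCCCorpus-class].
#' @param weights phosphorylation weights ([phosphoWeights()]).
#' @param mode phosphorylation classification mode
#'   ([classifyPhospho()]).
#' @param threshold co-expression threshold.
#' @param map GO evidence-code map.
#' @param W1,W2 marker evidence weights.
#' @param markerStrong,markerSuggestive Scm class thresholds.
#' @param includeSkipped,enforceMaxRepeat motif-scan options.
#' @param force run even when validation reports errors.
#' @return list with `validation`, `phospho`, `markers`, `perPathway`,
#'   `hccpm`, `summary`.
#' @export
runPipeline <- function(corpus, weights = phosphoWeights(),
                        mode = c("criteria", "threshold"), threshold = 0,
                        map = defaultEvidenceClassMap(), W1 = 5, W2 = 3,
                        markerStrong = 4.25, markerSuggestive = 3,
                        includeSkipped = FALSE, enforceMaxRepeat = FALSE,
                        force = FALSE) {
  mode <- match.arg(mode)
  report <- validateCorpus(corpus)
  if (!force && any(report$severity == "ERROR"))
    stop("corpus validation failed with ",
         sum(report$severity == "ERROR"), " error(s); see validateCorpus()")
  phospho <- scoreAllPhospho(corpus, weights = weights, mode = mode,
                             threshold = threshold, map = map,
                             includeSkipped = includeSkipped,
                             enforceMaxRepeat = enforceMaxRepeat)
  mk <- scoreAllMarkers(corpus, W1 = W1, W2 = W2,
                        strong = markerStrong,
                        suggestive = markerSuggestive)
  hccpm <- hccpmTable(phospho, mk$markers, drugTargets(corpus))
  list(validation = report, phospho = phospho, markers = mk$markers,
       perPathway = mk$perPathway, hccpm = hccpm,
       summary = summarizeResults(hccpm))
}

#' Write pipeline results as TSV files
#'
#' Writes `phospho.tsv`, `markers.tsv`, `marker_pathways.tsv` and
#' `hccpm.tsv` into a directory. Scores are printed with three decimals;
#' classifications were computed on full precision.
#'
#' @param results list from [runPipeline()].
#' @param dir output directory.
#' @export
writeResults <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  round3 <- function(d, cols) {
    for (cl in intersect(cols, names(d))) d[[cl]] <- sprintf("%.3f", d[[cl]])
    d
  }
  writeTsv(round3(results$phospho, "Sk"), file.path(dir, "phospho.tsv"))
  writeTsv(round3(results$markers, "Scm"), file.path(dir, "markers.tsv"))
  writeTsv(round3(results$perPathway, "Sc"),
           file.path(dir, "marker_pathways.tsv"))
  writeTsv(round3(results$hccpm, c("Sk", "Scm")),
           file.path(dir, "hccpm.tsv"))
  invisible(dir)
}
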