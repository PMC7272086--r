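#' Parse a Prosite-syntax motif pattern
#'
#' Prosite patterns are dash-separated element lists: a single residue
#' letter, `x` (any residue), `[ABC]` (allowed residues), `{ABC}` (forbidden
#' residues), any element optionally followed by a repeat `(n)` or range
#' `(n,m)`; a leading `<` anchors the match to the N terminus, a trailing
#' `>` to the C terminus, and a terminal `.` is ignored.
#'
#' @param pattern Prosite-syntax string, e.g. `"[RK](2)-x-[ST]."`.
#' @return an object of class `PrositePattern`: a list with `elements`
#'   (each a list with `type` in literal/class/negclass/wildcard,
#'   `residues`, `min`, `max`), logical anchors `nterm`/`cterm`, the
#'   original `pattern`, and `minLength`/`maxLength` of a matching window.
#' @examples
#' ast <- parsePrositePattern("[ST]-x(2,3)-{P}")
#' length(ast$elements)
#' @export
parsePrositePattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  p <- gsub("[[:space:]]", "", pattern)
  p <- sub("\\.$", "", p)
  nterm <- grepl("^<", p)
  if (nterm) p <- sub("^<", "", p)
  cterm <- grepl(">$", p)
  if (cterm) p <- sub(">$", "", p)
  if (!nzchar(p)) stop("empty pattern")
  tokens <- strsplit(p, "-", fixed = TRUE)[[1]]
  elements <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (!nzchar(tok)) stop("element ", i, ": empty element")
    m <- regmatches(tok, regexec("^(.*?)\\((\\d+)(,(\\d+))?\\)$", tok))[[1]]
    if (length(m)) {
      base <- m[2]
      lo <- as.integer(m[3])
      hi <- if (nzchar(m[5])) as.integer(m[5]) else lo
    } else {
      base <- tok
      lo <- hi <- 1L
    }
    if (lo < 1L) stop("element ", i, ": repeat count must be >= 1")
    if (hi < lo) stop("element ", i, ": repeat range has m < n")
    el <- if (identical(base, "x")) {
      list(type = "wildcard", residues = character(0))
    } else if (grepl("^\\[[A-Z]+\\]$", base)) {
      list(type = "class",
           residues = strsplit(substr(base, 2, nchar(base) - 1), "")[[1]])
    } else if (grepl("^\\{[A-Z]+\\}$", base)) {
      list(type = "negclass",
           residues = strsplit(substr(base, 2, nchar(base) - 1), "")[[1]])
    } else if (grepl("^[A-Z]$", base)) {
      list(type = "literal", residues = base)
    } else {
      stop("element ", i, ": malformed element '", tok, "'")
    }
    el$min <- lo
    el$max <- hi
    elements[[i]] <- el
  }
  structure(
    list(elements = elements, nterm = nterm, cterm = cterm,
         pattern = pattern,
         minLength = sum(vapply(elements, `[[`, 1L, "min")),
         maxLength = sum(vapply(elements, `[[`, 1L, "max"))),
    class = "PrositePattern")
}

#' @export
print.PrositePattern <- function(x, ...) {
  cat("PrositePattern:", x$pattern, "\n")
  cat(" ", length(x$elements), "elements; window length",
      x$minLength, "-", x$maxLength,
      if (x$nterm) "; N-anchored" else "",
      if (x$cterm) "; C-anchored" else "", "\n")
  invisible(x)
}

#' Translate a parsed Prosite pattern to a PCRE regular expression
#'
#' Convenience translation (classes to `[...]`, negations to `[^...]`,
#' `x` to `.`, repeats to `{n}`/`{n,m}`, anchors to `^`/`$`). The package's
#' scanner does not use regular expressions; this is provided for export
#' and interoperability.
#'
#' @param ast a `PrositePattern` (or a pattern string, parsed on the fly).
#' @return single regex string.
#' @export
prositeToRegex <- function(ast) {
  if (is.character(ast)) ast <- parsePrositePattern(ast)
  piece <- vapply(ast$elements, function(el) {
    base <- switch(el$type,
      wildcard = ".",
      literal = el$residues,
      class = paste0("[", paste(el$residues, collapse = ""), "]"),
      negclass = paste0("[^", paste(el$residues, collapse = ""), "]"))
    rep <- if (el$min == 1L && el$max == 1L) ""
           else if (el$min == el$max) sprintf("{%d}", el$min)
           else sprintf("{%d,%d}", el$min, el$max)
    paste0(base, rep)
  }, character(1))
  paste0(if (ast$nterm) "^", paste(piece, collapse = ""),
         if (ast$cterm) "$")
}

# TRUE where residue ch satisfies element el.
.elementAllows <- function(el, ch) {
  switch(el$type,
    wildcard = rep(TRUE, length(ch)),
    literal = ch == el$residues,
    class = ch %in% el$residues,
    negclass = !(ch %in% el$residues))
}

#' Scan a sequence with a parsed motif pattern
#'
#' Slides the pattern over every window start (anchors restrict the tested
#' windows), enumerating all lengths of variable-length elements, and
#' reports every distinct match as 1-based inclusive coordinates. The
#' phosphoacceptor position is the sequence position of the element at
#' `siteOffset` (the first matched residue when that element repeats). No
#' acceptor-residue filtering happens here; see [findCandidateKinases()].
#'
#' @param ast `PrositePattern` (or pattern string).
#' @param sequence single amino-acid string.
#' @param siteOffset 0-based element index of the phosphoacceptor.
#' @return data.frame with columns `start`, `end`, `matched_span`,
#'   `site_position`, `site_residue`; zero rows when nothing matches.
#' @examples
#' scanSequence("[ST]-x(2)-[DE]", "AASGGDAA", siteOffset = 0)
#' @export
scanSequence <- function(ast, sequence, siteOffset = 0L) {
  if (is.character(ast)) ast <- parsePrositePattern(ast)
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) >= 1L)
  nElem <- length(ast$elements)
  siteOffset <- as.integer(siteOffset)
  if (siteOffset < 0L || siteOffset >= nElem)
    stop("siteOffset out of range: ", siteOffset,
         " for ", nElem, " pattern elements")
  chars <- strsplit(toupper(sequence), "")[[1]]
  len <- length(chars)
  siteIdx <- siteOffset + 1L

  hits <- list()
  rec <- function(pos, i, sitePos) {
    if (i > nElem) {
      if (!ast$cterm || pos == len + 1L)
        hits[[length(hits) + 1L]] <<- c(pos - 1L, sitePos)
      return(invisible())
    }
    el <- ast$elements[[i]]
    if (i == siteIdx) sitePos <- pos
    # consume k residues, k in [min, max]; stop extending at first failure
    k <- 0L
    while (k < el$max) {
      nxt <- pos + k
      if (nxt > len) break
      if (!.elementAllows(el, chars[nxt])) break
      k <- k + 1L
      if (k >= el$min) rec(pos + k, i + 1L, sitePos)
    }
    invisible()
  }

  starts <- if (ast$nterm) 1L else seq_len(max(len - ast$minLength + 1L, 0L))
  # cheap prefilter: the first element must match at the window start
  if (length(starts))
    starts <- starts[.elementAllows(ast$elements[[1L]], chars[starts])]
  out <- list()
  for (s in starts) {
    hits <- list()
    rec(s, 1L, NA_integer_)
    if (length(hits)) {
      m <- do.call(rbind, hits)
      out[[length(out) + 1L]] <-
        data.frame(start = s, end = m[, 1L], site_position = m[, 2L])
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      matched_span = character(0),
                      site_position = integer(0),
                      site_residue = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- unique(res)
  res <- res[order(res$start, res$end, res$site_position), , drop = FALSE]
  res$matched_span <- substring(sequence, res$start, res$end)
  res$site_residue <- chars[res$site_position]
  rownames(res) <- NULL
  res[c("start", "end", "matched_span", "site_position", "site_residue")]
}

#' Find candidate kinases for a protein by motif scanning
#'
#' Scans the protein's sequence with every motif definition (motifs with
#' `skip_flag` are excluded by default), discards matches whose acceptor
#' residue is not one of S/T/Y/H, and maps each motif with at least one
#' surviving match to its kinase list. The candidate kinase set of the
#' protein is the union over contributing motifs.
#'
#' @param corpus an [HCCCorpus-class] (used to resolve the sequence).
#' @param accession query protein accession; must have a sequence.
#' @param includeSkipped logical; also scan motifs flagged `skip_flag`.
#' @param enforceMaxRepeat logical; when `TRUE`, a motif with
#'   `max_repeat > 0` keeps at most that many matches per protein.
#' @return list with `matches` (data.frame `accession`, `motif_id`,
#'   `start`, `end`, `matched_span`, `site_position`, `site_residue`),
#'   `perMotif` (named list of kinase vectors for motifs that matched) and
#'   `kinases` (sorted union of candidate kinase accessions).
#' @examples
#' corp <- HCCCorpus(
#'   proteins = data.frame(accession = c("P1", "K1"),
#'                         is_kinase = c(FALSE, TRUE)),
#'   sequences = c(P1 = "AARRASAA"),
#'   motifs = data.frame(motif_id = "M1", pattern = "[RK](2)-x-[ST]",
#'                       site_offset = 2L, max_repeat = 0L,
#'                       skip_flag = FALSE, kinase_accessions = "K1",
#'                       description = "fixture"))
#' findCandidateKinases(corp, "P1")$kinases
#' @export
findCandidateKinases <- function(corpus, accession,
                                 includeSkipped = FALSE,
                                 enforceMaxRepeat = FALSE) {
  seqs <- proteinSequences(corpus)
  if (!accession %in% names(seqs))
    stop("protein ", accession,
         " has no sequence; motif scanning requires one")
  sequence <- as.character(seqs[[accession]])
  mots <- motifs(corpus)
  if (!includeSkipped && nrow(mots))
    mots <- mots[!mots$skip_flag, , drop = FALSE]
  matchRows <- list()
  perMotif <- list()
  for (i in seq_len(nrow(mots))) {
    mm <- scanSequence(mots$pattern[i], sequence, mots$site_offset[i])
    mm <- mm[mm$site_residue %in% .ACCEPTORS, , drop = FALSE]
    if (enforceMaxRepeat && mots$max_repeat[i] > 0L &&
        nrow(mm) > mots$max_repeat[i])
      mm <- mm[seq_len(mots$max_repeat[i]), , drop = FALSE]
    if (nrow(mm)) {
      mm <- cbind(accession = accession, motif_id = mots$motif_id[i], mm,
                  stringsAsFactors = FALSE)
      matchRows[[length(matchRows) + 1L]] <- mm
      perMotif[[mots$motif_id[i]]] <-
        .splitSemicolon(mots$kinase_accessions[i])
    }
  }
  matches <- if (length(matchRows)) do.call(rbind, matchRows) else
    data.frame(accession = character(0), motif_id = character(0),
               start = integer(0), end = integer(0),
               matched_span = character(0), site_position = integer(0),
               site_residue = character(0), stringsAsFactors = FALSE)
  rownames(matches) <- NULL
  list(matches = matches, perMotif = perMotif,
       kinases = sort(unique(as.character(
         unlist(perMotif, use.names = FALSE)))))
}

.splitSemicolon <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)[[1]]
  out <- trimws(out)
  out[nzchar(out)]
}
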