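#' Default GO evidence-code classification
#'
#' Maps GO evidence codes onto four credibility classes: `L1` experimental,
#' `L2` computational analysis, `L3` curatorial statement, `L4` automatically
#' assigned. The default follows the standard GO evidence-code taxonomy and
#' can be overridden wholesale or per code (e.g. from a two-column TSV read
#' with [readEvidenceMap()]).
#'
#' @return named character vector: names are evidence codes, values are
#'   `"L1"`..`"L4"`.
#' @examples
#' defaultEvidenceClassMap()[["IDA"]]
#' @export
defaultEvidenceClassMap <- function() {
  c(
    # experimental (incl. high-throughput variants)
    EXP = "L1", IDA = "L1", IPI = "L1", IMP = "L1", IGI = "L1", IEP = "L1",
    HTP = "L1", HDA = "L1", HMP = "L1", HGI = "L1", HEP = "L1",
    # computational analysis
    ISS = "L2", ISO = "L2", ISA = "L2", ISM = "L2", IGC = "L2", IBA = "L2",
    IBD = "L2", IKR = "L2", IRD = "L2", RCA = "L2",
    # curatorial statement
    TAS = "L3", NAS = "L3", IC = "L3",
    # automatically assigned / no data
    IEA = "L4", ND = "L4"
  )
}

#' Map a GO evidence code to its credibility class
#'
#' Total and deterministic: codes not present in the map fall back to the
#' most conservative class `L4` with a warning.
#'
#' @param code character vector of GO evidence codes (e.g. `"IDA"`).
#' @param map named character vector as from [defaultEvidenceClassMap()].
#' @return character vector of classes `"L1"`..`"L4"`.
#' @examples
#' mapEvidenceCode(c("IDA", "IEA"))
#' @export
mapEvidenceCode <- function(code, map = defaultEvidenceClassMap()) {
  stopifnot(is.character(code), all(nzchar(code)))
  cls <- unname(map[code])
  unknown <- is.na(cls)
  if (any(unknown)) {
    warning("unknown GO evidence code(s) mapped to L4: ",
            paste(unique(code[unknown]), collapse = ", "))
    cls[unknown] <- "L4"
  }
  cls
}

#' Read an evidence-code map from a two-column TSV
#'
#' Expects a header row with columns `evidence_code` and `class`
#' (`L1`..`L4`).
#'
#' @param path file path.
#' @return named character vector usable as `map` in [mapEvidenceCode()].
#' @export
readEvidenceMap <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("evidence_code", "class") %in% names(tab)),
            all(tab$class %in% .GO_CLASSES))
  setNames(tab$class, tab$evidence_code)
}
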