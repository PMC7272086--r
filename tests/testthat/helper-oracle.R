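# Independent oracles used across the suite. The regex translation below is
# written directly from the Prosite syntax (string processing only) and the
# matching is done by R's PCRE engine in overlapped mode, so it shares no
# code with the package's AST scanner.

# Prosite pattern string -> PCRE regex, independent of parsePrositePattern()
oracleRegex <- function(pattern) {
  p <- gsub("[[:space:]]", "", pattern)
  p <- sub("\\.$", "", p)
  nterm <- startsWith(p, "<")
  if (nterm) p <- substring(p, 2)
  cterm <- endsWith(p, ">")
  if (cterm) p <- substring(p, 1, nchar(p) - 1)
  out <- character(0)
  for (tok in strsplit(p, "-", fixed = TRUE)[[1]]) {
    rep <- ""
    m <- regmatches(tok, regexec("^(.*?)\\((\\d+)(,(\\d+))?\\)$", tok))[[1]]
    if (length(m)) {
      rep <- if (nzchar(m[5])) sprintf("{%s,%s}", m[3], m[5])
             else sprintf("{%s}", m[3])
      tok <- m[2]
    }
    base <- if (tok == "x") "."
      else if (startsWith(tok, "[")) tok
      else if (startsWith(tok, "{"))
        paste0("[^", substring(tok, 2, nchar(tok) - 1), "]")
      else tok
    out <- c(out, paste0(base, rep))
  }
  paste0(if (nterm) "^", paste(out, collapse = ""), if (cterm) "$")
}

# all 1-based start positions where the regex matches, overlapped
oracleStarts <- function(pattern, sequence) {
  rx <- paste0("(?=(", oracleRegex(pattern), "))")
  hit <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (hit[1] == -1) integer(0) else as.integer(hit)
}

# random Prosite pattern from a constrained grammar over a small alphabet
randomPattern <- function(alphabet = c("A", "C", "D", "S", "T")) {
  nElem <- sample(1:4, 1)
  toks <- vapply(seq_len(nElem), function(i) {
    kind <- sample(c("literal", "class", "negclass", "wildcard"), 1,
                   prob = c(0.3, 0.3, 0.2, 0.2))
    base <- switch(kind,
      literal = sample(alphabet, 1),
      class = paste0("[", paste(sample(alphabet, sample(2:3, 1)),
                                collapse = ""), "]"),
      negclass = paste0("{", paste(sample(alphabet, sample(1:2, 1)),
                                   collapse = ""), "}"),
      wildcard = "x")
    rep <- sample(c("", "(2)", "(1,2)", "(2,3)"), 1,
                  prob = c(0.6, 0.15, 0.15, 0.1))
    paste0(base, rep)
  }, character(1))
  pat <- paste(toks, collapse = "-")
  if (runif(1) < 0.15) pat <- paste0("<", pat)
  if (runif(1) < 0.15) pat <- paste0(pat, ">")
  pat
}

randomSequence <- function(alphabet = c("A", "C", "D", "S", "T"),
                           len = sample(8:20, 1)) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# brute-force piecewise-linear evaluator for cyclic profiles: walks the
# segment list explicitly instead of using approx()
bruteProfileValue <- function(time, value, at) {
  o <- order(time)
  time <- time[o]; value <- value[o]
  n <- length(time)
  segs <- cbind(t0 = time, t1 = c(time[-1], time[1] + 100),
                v0 = value, v1 = c(value[-1], value[1]))
  vapply(at, function(tt) {
    for (s in seq_len(n)) {
      a <- segs[s, ]
      for (shift in c(0, -100, 100)) {
        t0 <- a[["t0"]] + shift; t1 <- a[["t1"]] + shift
        if (tt >= t0 && tt <= t1) {
          if (t1 == t0) return(a[["v0"]])
          return(a[["v0"]] + (a[["v1"]] - a[["v0"]]) * (tt - t0) / (t1 - t0))
        }
      }
    }
    stop("no segment covers ", tt)
  }, numeric(1))
}
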