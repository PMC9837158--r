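#' Parse an ordered pattern dictionary from JSON
#'
#' Patterns are given as a plain JSON object mapping pattern names to
#' nucleotide sequences, e.g.
#' `{"foo": "CTGTCTCTTATACAC", "bar": "CCGAAAACACG", "baz": "TCGTCGGG"}`.
#' Key order is preserved and is significant: patterns are searched in
#' that order. Sequences are case-insensitive on input and canonicalized
#' to uppercase; only A/C/G/T are accepted (IUPAC ambiguity codes are
#' rejected). If `x` names an existing file it is read as a JSON file,
#' otherwise it is parsed as literal JSON text.
#'
#' @param x JSON text, or the path of a file containing JSON.
#' @return a [PatternSet-class] with reverse complements and palindrome
#'   flags precomputed and an empty warnings table.
#' @examples
#' ps <- parsePatternSet('{"foo":"CTGTCTCTTATACAC","bar":"CCGAAAACACG"}')
#' patternNames(ps)
#' @export
parsePatternSet <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  json <- if (file.exists(x)) paste(readLines(x, warn = FALSE), collapse = "\n") else x
  parsed <- tryCatch(
    jsonlite::fromJSON(json, simplifyVector = FALSE),
    error = function(e) stop(sprintf("pattern JSON parse error: %s",
                                     conditionMessage(e)), call. = FALSE)
  )
  if (!is.list(parsed) || length(parsed) == 0L)
    stop("pattern JSON must be a non-empty object of name: sequence pairs",
         call. = FALSE)
  nm <- names(parsed)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("pattern JSON must be an object with named entries", call. = FALSE)
  if (anyDuplicated(nm))
    stop(sprintf("duplicate pattern name(s): %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")),
         call. = FALSE)
  if (!all(vapply(parsed, function(v) is.character(v) && length(v) == 1L,
                  logical(1))))
    stop("all pattern values must be strings", call. = FALSE)
  seqs <- toupper(unlist(parsed, use.names = FALSE))
  names(seqs) <- nm
  badIdx <- grep("[^ACGT]", seqs)
  if (length(badIdx)) {
    i <- badIdx[1L]
    ch <- regmatches(seqs[i], regexpr("[^ACGT]", seqs[i]))
    stop(sprintf("pattern '%s' contains invalid character '%s' (alphabet is A/C/G/T)",
                 nm[i], ch), call. = FALSE)
  }
  if (any(!nzchar(seqs)))
    stop(sprintf("pattern '%s' has an empty sequence",
                 nm[which(!nzchar(seqs))[1L]]), call. = FALSE)
  rc <- reverseComplementStrings(seqs)
  new("PatternSet",
      sequences = seqs, revcomp = rc,
      palindromic = seqs == rc,
      warnings = emptyWarnings())
}

emptyWarnings <- function() {
  data.frame(kind = character(0), members = character(0),
             distance = integer(0), message = character(0),
             stringsAsFactors = FALSE)
}

makeWarning <- function(kind, members, distance, message) {
  data.frame(kind = kind, members = paste(members, collapse = ","),
             distance = if (is.null(distance)) NA_integer_ else as.integer(distance),
             message = message, stringsAsFactors = FALSE)
}

#' @describeIn PatternSet-accessors pattern names, in search order
#' @export
patternNames <- function(ps) names(ps@sequences)

#' Accessors for PatternSet
#'
#' @param ps a [PatternSet-class].
#' @return `patternNames`: character vector; `patternSequences` and
#'   `patternRevcomp`: named character vectors; `patternLengths`: named
#'   integer vector (bp); `isPalindromic`: named logical vector;
#'   `patternWarnings`: the accumulated warnings data.frame.
#' @name PatternSet-accessors
NULL

#' @describeIn PatternSet-accessors forward-strand sequences
#' @export
patternSequences <- function(ps) ps@sequences

#' @describeIn PatternSet-accessors reverse-complement sequences
#' @export
patternRevcomp <- function(ps) ps@revcomp

#' @describeIn PatternSet-accessors pattern lengths in bp
#' @export
patternLengths <- function(ps) {
  out <- nchar(ps@sequences)
  names(out) <- names(ps@sequences)
  out
}

#' @describeIn PatternSet-accessors reverse-complement palindrome flags
#' @export
isPalindromic <- function(ps) ps@palindromic

#' @describeIn PatternSet-accessors diagnostic warnings collected so far
#' @export
patternWarnings <- function(ps) ps@warnings

setMethod("show", "PatternSet", function(object) {
  cat(sprintf("PatternSet with %d pattern(s)\n", length(object@sequences)))
  df <- data.frame(
    name = names(object@sequences),
    length = unname(nchar(object@sequences)),
    sequence = unname(object@sequences),
    palindromic = unname(object@palindromic)
  )
  print(df, row.names = FALSE)
  if (nrow(object@warnings))
    cat(sprintf("%d warning(s); see patternWarnings()\n", nrow(object@warnings)))
})

#' Check that patterns are sorted from long to short
#'
#' Earlier patterns claim read bases first, so a short pattern listed
#' before a longer one can mask the longer one's occurrences. Long-to-short
#' order is the safe choice for overlapping or nested sequences; any other
#' order triggers a warning naming the first offending adjacent pair.
#' Ties (equal lengths) are allowed.
#'
#' @param ps a [PatternSet-class].
#' @return a warnings data.frame (zero rows when the order is fine).
#' @examples
#' ps <- parsePatternSet('{"short":"ACGTACGA","longer":"ACGTACGTACGT"}')
#' checkPatternOrder(ps)
#' @export
checkPatternOrder <- function(ps) {
  len <- patternLengths(ps)
  if (length(len) >= 2L) {
    inc <- which(len[-length(len)] < len[-1L])
    if (length(inc)) {
      i <- inc[1L]
      return(makeWarning(
        "not-sorted", names(len)[c(i, i + 1L)], NULL,
        sprintf("patterns are not sorted long to short: '%s' (%d bp) precedes '%s' (%d bp)",
                names(len)[i], len[i], names(len)[i + 1L], len[i + 1L])))
    }
  }
  emptyWarnings()
}

#' Pairwise Levenshtein distances between patterns
#'
#' Computes the full symmetric matrix of Levenshtein edit distances over
#' all pattern pairs, for all four strand combinations (forward-forward,
#' forward-revcomp, revcomp-forward, revcomp-revcomp), and reports the
#' per-pair minimum. Pairs whose minimum distance is at or below
#' `confusionThreshold` get a `near-match` warning: a few sequencing
#' errors could turn one pattern into the other and confuse the search.
#' A `nested` warning is emitted when one pattern's sequence (or its
#' reverse complement) is an exact substring of another's.
#'
#' @param ps a [PatternSet-class].
#' @param confusionThreshold non-negative integer; maximum edit distance
#'   at which two patterns are flagged as confusable. Default 2.
#' @return a list with elements `min`, `ff`, `fr`, `rf`, `rr` (integer
#'   matrices with pattern names as dimnames) and `warnings` (data.frame).
#' @examples
#' ps <- parsePatternSet('{"a":"ACGTACGT","b":"ACGTACGA"}')
#' patternDistances(ps, confusionThreshold = 2)$min
#' @export
patternDistances <- function(ps, confusionThreshold = 2L) {
  stopifnot(confusionThreshold >= 0)
  fwd <- patternSequences(ps)
  rc <- patternRevcomp(ps)
  ff <- levenshteinMatrix(fwd, fwd)
  fr <- levenshteinMatrix(fwd, rc)
  rf <- levenshteinMatrix(rc, fwd)
  rr <- levenshteinMatrix(rc, rc)
  dmin <- pmin(ff, fr, rf, rr)
  warn <- emptyWarnings()
  n <- length(fwd)
  nm <- names(fwd)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (dmin[i, j] <= confusionThreshold)
        warn <- rbind(warn, makeWarning(
          "near-match", nm[c(i, j)], dmin[i, j],
          sprintf("patterns '%s' and '%s' are within edit distance %d (minimum over strand combinations)",
                  nm[i], nm[j], dmin[i, j])))
    }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (nchar(fwd[i]) > nchar(fwd[j])) next
      if (grepl(fwd[i], fwd[j], fixed = TRUE) ||
          grepl(rc[i], fwd[j], fixed = TRUE))
        warn <- rbind(warn, makeWarning(
          "nested", nm[c(i, j)], NULL,
          sprintf("pattern '%s' is nested inside '%s' (exact substring on one strand)",
                  nm[i], nm[j])))
    }
  }
  list(min = dmin, ff = ff, fr = fr, rf = rf, rr = rr, warnings = warn)
}

#' Detect palindromic and near-palindromic patterns
#'
#' A reverse-complement palindrome (a sequence equal to its own reverse
#' complement, e.g. `GAATTC`) carries no meaningful strand label, and a
#' pattern within a few edits of its reverse complement can *become*
#' palindromic through sequencing errors; both distort forward/reverse
#' orientation statistics, so both are flagged.
#'
#' @param ps a [PatternSet-class].
#' @param palindromeRiskThreshold positive integer; patterns whose
#'   distance to their own reverse complement is in
#'   `(0, palindromeRiskThreshold]` get a `near-palindrome` warning.
#'   Default 2.
#' @return a warnings data.frame.
#' @examples
#' ps <- parsePatternSet('{"ecoRI":"GAATTC","risky":"GAATTA"}')
#' analyzePalindromes(ps)
#' @export
analyzePalindromes <- function(ps, palindromeRiskThreshold = 2L) {
  stopifnot(palindromeRiskThreshold >= 1)
  warn <- emptyWarnings()
  nm <- patternNames(ps)
  d <- levenshteinDistance(patternSequences(ps), patternRevcomp(ps))
  for (i in seq_along(nm)) {
    if (ps@palindromic[i]) {
      warn <- rbind(warn, makeWarning(
        "palindrome", nm[i], 0L,
        sprintf("pattern '%s' is a reverse-complement palindrome; strand orientation is undefined", nm[i])))
    } else if (d[i] <= palindromeRiskThreshold) {
      warn <- rbind(warn, makeWarning(
        "near-palindrome", nm[i], d[i],
        sprintf("pattern '%s' is within edit distance %d of its reverse complement and may appear palindromic under sequencing errors",
                nm[i], d[i])))
    }
  }
  warn
}

#' Run all pattern diagnostics
#'
#' Convenience wrapper running [checkPatternOrder()], [patternDistances()]
#' and [analyzePalindromes()] and collecting their warnings into the
#' pattern set.
#'
#' @param ps a [PatternSet-class].
#' @param confusionThreshold see [patternDistances()].
#' @param palindromeRiskThreshold see [analyzePalindromes()].
#' @return a list with `patternSet` (the input with its warnings slot
#'   filled) and `distances` (the [patternDistances()] result).
#' @export
diagnosePatterns <- function(ps, confusionThreshold = 2L,
                             palindromeRiskThreshold = 2L) {
  dist <- patternDistances(ps, confusionThreshold)
  warn <- rbind(checkPatternOrder(ps), dist$warnings,
                analyzePalindromes(ps, palindromeRiskThreshold))
  ps@warnings <- warn
  list(patternSet = ps, distances = dist)
}
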