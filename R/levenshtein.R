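#' Levenshtein edit distance
#'
#' Unit-cost edit distance (substitutions, insertions, deletions) between
#' pairs of strings, computed with [utils::adist()]. Inputs are recycled
#' to a common length.
#'
#' @param a,b character vectors.
#' @return integer vector of elementwise distances.
#' @examples
#' levenshteinDistance("ACGT", "AGT")   # 1
#' levenshteinDistance(c("ACGT", "AAAA"), "ACGT")
#' @export
levenshteinDistance <- function(a, b) {
  stopifnot(is.character(a), is.character(b))
  n <- max(length(a), length(b))
  if (n == 0L) return(integer(0))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- as.integer(utils::adist(a[i], b[i])[1L, 1L])
  out
}

#' Cross matrix of Levenshtein distances
#'
#' @param a,b character vectors.
#' @return integer matrix of dimension `length(a)` x `length(b)` with the
#'   input names as dimnames.
#' @export
levenshteinMatrix <- function(a, b) {
  m <- utils::adist(a, b)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(names(a), names(b))
  m
}

#' Compare unrecognized segments against the patterns by edit distance
#'
#' Optional per-read diagnostic: for every `kmer` or `unknown` segment of
#' a segmented read, compute the Levenshtein distance to every pattern on
#' both strands. A small distance suggests the segment is a corrupted
#' copy of that pattern, letting the user infer the real read structure
#' even when exact matching fails. Match segments are skipped (their
#' distance to the matched pattern is trivially zero). The distance is a
#' whole-segment vs whole-pattern comparison, a deliberately crude
#' similarity — no local alignment windowing is attempted.
#'
#' @param structure a [ReadStructure-class].
#' @param ps a [PatternSet-class].
#' @return data.frame with columns `segment` (row index into
#'   `segments(structure)`), `pattern`, `strand` (`"F"`/`"R"`), and
#'   `distance`. Zero rows when the read has no unrecognized segments.
#' @examples
#' ps <- parsePatternSet('{"foo":"CTGTCTCTTATACAC"}')
#' rs <- segmentRead("CTGTCTCTTATACAG", ps)  # one substitution: no match
#' analyzeReadSegments(rs, ps)
#' @export
analyzeReadSegments <- function(structure, ps) {
  stopifnot(is(structure, "ReadStructure"), is(ps, "PatternSet"))
  seg <- structure@segments
  idx <- which(seg$kind %in% c("kmer", "unknown"))
  out <- data.frame(segment = integer(0), pattern = character(0),
                    strand = character(0), distance = integer(0),
                    stringsAsFactors = FALSE)
  if (length(idx) == 0L) return(out)
  nm <- patternNames(ps)
  fwd <- patternSequences(ps)
  rc <- patternRevcomp(ps)
  for (i in idx) {
    s <- seg$sequence[i]
    df <- levenshteinMatrix(s, fwd)[1L, ]
    dr <- levenshteinMatrix(s, rc)[1L, ]
    out <- rbind(out, data.frame(
      segment = rep(i, 2L * length(nm)),
      pattern = rep(nm, 2L),
      strand = rep(c("F", "R"), each = length(nm)),
      distance = as.integer(c(df, dr)),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
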