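#' Segment a read into pattern matches, K-mers, and unknown stretches
#'
#' Core segmentation engine. Patterns are searched in dictionary order;
#' within each pattern the forward strand (the sequence itself) is
#' searched before the reverse strand (its reverse complement). Each pass
#' scans the currently unclaimed portions of the read left to right and
#' claims every exact occurrence greedily (leftmost first, non-overlapping);
#' an occurrence that overlaps any already-claimed base is skipped entirely
#' — matching is full-match only, so a planted pattern copy with even one
#' sequencing error is never matched. Palindromic patterns are searched
#' once, since both strands are identical. After all passes, each maximal
#' unclaimed region becomes a `kmer` segment when its length is at most
#' `maxKmerSize` (labelled with its length, so pattern copies one base
#' shorter or longer than expected — A-tailing and synthesis-error
#' products — are easy to spot), and an `unknown` segment otherwise.
#'
#' @param read the read sequence (character scalar), or a list/data.frame
#'   row with fields `id` and `sequence`.
#' @param ps a [PatternSet-class].
#' @param maxKmerSize integer; maximum length of an unclaimed region that
#'   still gets an explicit length label. Default: longest pattern length
#'   + 1, so the one-base-longer variants are always labelled.
#' @param readId identifier used when `read` is a bare sequence.
#' @return a [ReadStructure-class]; segment coordinates are 0-based,
#'   half-open.
#' @examples
#' ps <- parsePatternSet('{"foo":"CTGTCTCTTATACAC"}')
#' structureString(segmentRead("CTGTCTCTTATACAC", ps))  # "{foo:F}"
#' structureString(segmentRead("GTGTATAAGAGACAG", ps))  # "{foo:R}"
#' @export
segmentRead <- function(read, ps, maxKmerSize = NULL, readId = "read") {
  stopifnot(is(ps, "PatternSet"))
  if (is.list(read)) {
    readId <- read$id
    read <- read$sequence
  }
  stopifnot(is.character(read), length(read) == 1L)
  seq <- toupper(read)
  n <- nchar(seq)
  if (n == 0L) stop("cannot segment an empty read", call. = FALSE)
  if (length(ps@sequences) == 0L) stop("empty pattern set", call. = FALSE)
  if (is.null(maxKmerSize)) maxKmerSize <- defaultMaxKmerSize(ps)

  subject <- Biostrings::DNAString(seq)
  claimed <- logical(n)
  segKind <- character(0); segStart <- integer(0); segEnd <- integer(0)
  segPat <- character(0); segStrand <- character(0)

  nm <- patternNames(ps)
  for (i in seq_along(nm)) {
    strands <- if (ps@palindromic[i]) "F" else c("F", "R")
    for (strand in strands) {
      pat <- if (strand == "F") ps@sequences[i] else ps@revcomp[i]
      L <- nchar(pat)
      if (L > n) next
      starts <- Biostrings::start(Biostrings::matchPattern(pat, subject))
      for (s in starts) {           # 1-based, ascending
        span <- s:(s + L - 1L)
        if (any(claimed[span])) next
        claimed[span] <- TRUE
        segKind <- c(segKind, "match")
        segStart <- c(segStart, s - 1L)
        segEnd <- c(segEnd, s - 1L + L)
        segPat <- c(segPat, nm[i])
        segStrand <- c(segStrand, if (ps@palindromic[i]) NA_character_ else strand)
      }
    }
  }

  # maximal unclaimed runs become kmer/unknown segments
  r <- rle(claimed)
  pos <- cumsum(c(0L, r$lengths))
  for (k in seq_along(r$values)) {
    if (r$values[k]) next
    s0 <- pos[k]; e0 <- pos[k + 1L]
    segKind <- c(segKind, if (e0 - s0 <= maxKmerSize) "kmer" else "unknown")
    segStart <- c(segStart, s0)
    segEnd <- c(segEnd, e0)
    segPat <- c(segPat, NA_character_)
    segStrand <- c(segStrand, NA_character_)
  }

  ord <- order(segStart)
  segments <- data.frame(
    kind = segKind[ord], start = segStart[ord], end = segEnd[ord],
    pattern = segPat[ord], strand = segStrand[ord],
    sequence = substring(seq, segStart[ord] + 1L, segEnd[ord]),
    stringsAsFactors = FALSE)

  rs <- new("ReadStructure", readId = readId, sequence = seq,
            segments = segments, structureString = "")
  rs@structureString <- renderStructure(rs, ps)
  validObject(rs)
  rs
}

defaultMaxKmerSize <- function(ps) max(patternLengths(ps)) + 1L

#' Render the canonical structure string of a segmented read
#'
#' One token per segment, in read order: `{name:F}` or `{name:R}` for a
#' pattern match (`{name}` without a strand suffix when the pattern is
#' palindromic), `{kmer:Nbp}` for a short unknown of length N, and
#' `{unknown}` for longer unrecognized stretches.
#'
#' @param structure a [ReadStructure-class].
#' @param ps the [PatternSet-class] used for segmentation (supplies the
#'   palindrome flags).
#' @return character scalar, e.g. `"{unknown}{foo:F}{kmer:14bp}"`.
#' @export
renderStructure <- function(structure, ps) {
  seg <- structure@segments
  pal <- isPalindromic(ps)
  tokens <- character(nrow(seg))
  for (i in seq_len(nrow(seg))) {
    tokens[i] <- switch(seg$kind[i],
      match = if (isTRUE(pal[[seg$pattern[i]]])) sprintf("{%s}", seg$pattern[i])
              else sprintf("{%s:%s}", seg$pattern[i], seg$strand[i]),
      kmer = sprintf("{kmer:%dbp}", seg$end[i] - seg$start[i]),
      unknown = "{unknown}")
  }
  paste(tokens, collapse = "")
}

#' @describeIn ReadStructure-accessors the segment table (0-based,
#'   half-open coordinates)
#' @export
readSegments <- function(structure) structure@segments

#' Accessors for ReadStructure
#'
#' @param structure a [ReadStructure-class].
#' @name ReadStructure-accessors
NULL

#' @describeIn ReadStructure-accessors the canonical structure string
#' @export
structureString <- function(structure) structure@structureString

setMethod("show", "ReadStructure", function(object) {
  cat(sprintf("ReadStructure for '%s' (%d bp): %s\n",
              object@readId, nchar(object@sequence), object@structureString))
  print(object@segments, row.names = FALSE)
})

#' Segment a read pair
#'
#' Each mate is segmented independently — the reverse mate is analyzed in
#' machine orientation, never reverse-complemented, because both pattern
#' strands are searched anyway and the strand suffixes carry orientation.
#' The pair forms a single structure unit whose string is
#' `"R1:<structure1> R2:<structure2>"`.
#'
#' @param r1,r2 lists (or data.frame rows) with fields `id` and
#'   `sequence`; mate 1 and mate 2 of one fragment.
#' @param ps a [PatternSet-class].
#' @param maxKmerSize see [segmentRead()].
#' @return list with elements `r1`, `r2` (each a [ReadStructure-class])
#'   and `structureString` (the paired token string).
#' @examples
#' ps <- parsePatternSet('{"foo":"CTGTCTCTTATACAC"}')
#' p <- segmentPair(list(id = "a/1", sequence = "CTGTCTCTTATACAC"),
#'                  list(id = "a/2", sequence = "GTGTATAAGAGACAG"), ps)
#' p$structureString  # "R1:{foo:F} R2:{foo:R}"
#' @export
segmentPair <- function(r1, r2, ps, maxKmerSize = NULL) {
  id1 <- readIdStem(r1$id)
  id2 <- readIdStem(r2$id)
  if (!identical(id1, id2))
    stop(sprintf("mate ID mismatch: '%s' vs '%s'", r1$id, r2$id), call. = FALSE)
  s1 <- segmentRead(r1$sequence, ps, maxKmerSize, readId = r1$id)
  s2 <- segmentRead(r2$sequence, ps, maxKmerSize, readId = r2$id)
  list(r1 = s1, r2 = s2,
       structureString = sprintf("R1:%s R2:%s",
                                 s1@structureString, s2@structureString))
}

# Strip a trailing mate designator ("/1", "/2") or a space-delimited
# comment (Illumina "1:N:0:..." style) from a read ID.
readIdStem <- function(id) sub("/[12]$", "", sub(" .*$", "", id))
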